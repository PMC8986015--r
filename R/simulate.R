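# --- synthetic sacrum-like reference geometry ------------------------------
#
# The bundled template is SYNTHETIC: a deterministic parametric 3D shape —
# a tapering, sagittally curved trapezoidal body with bilateral alae flanges
# — that mirrors only the structure of a real sacrum digitization protocol
# (44 fixed landmarks, 56 sliding semilandmarks on 7 smooth curves,
# bilateral symmetry, and realistic SW > CW > CD measurement magnitudes).
# It is NOT an anatomical landmark definition.
#
# Axes: x mediolateral (left negative), y anteroposterior (anterior
# positive), z craniocaudal (cranial = 0, caudal negative).  Units: mm.

sacrum_profile <- function(s, length_mm = 110, curv = 30) {
  list(z = -length_mm * s,
       y = -curv * s^2,                     # sagittal curvature of the midline
       half_width = 8 + (56.5 - 8) * (1 - s)^1.5,
       depth = 30 * (1 - 0.6 * s))          # corpus depth taper
}

sacrum_reference <- function() {
  pr <- function(s) sacrum_profile(s)
  pts <- matrix(NA_real_, 100, 3)
  lab <- character(100)
  put <- function(i, p, l) { pts[i, ] <<- p; lab[i] <<- l }

  # 1-6: measurement endpoints (CD = 1-2, CW = 3-4, SW = 5-6)
  put(1, c(0, 15, 0), "promontory")
  put(2, c(0, -15, 0), "S1_posterior")
  put(3, c(-24.5, 0, 0), "corpus_lat_L")
  put(4, c(24.5, 0, 0), "corpus_lat_R")
  put(5, c(-56.5, 0, -5), "ala_tip_L")
  put(6, c(56.5, 0, -5), "ala_tip_R")
  # 7-11 anterior midline, 12-16 posterior midline (s = .2 .4 .6 .8 1)
  ss <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  for (j in seq_along(ss)) {
    p <- pr(ss[j])
    put(6 + j, c(0, p$y + p$depth / 2, p$z), paste0("ant_mid_", j))
    put(11 + j, c(0, p$y - p$depth / 2, p$z), paste0("post_mid_", j))
  }
  # 17-21 left, 22-26 right lateral border (s = .25 .40 .55 .70 .85)
  sl <- c(0.25, 0.40, 0.55, 0.70, 0.85)
  for (j in seq_along(sl)) {
    p <- pr(sl[j])
    put(16 + j, c(-p$half_width, p$y, p$z), paste0("lat_L_", j))
    put(21 + j, c(p$half_width, p$y, p$z), paste0("lat_R_", j))
  }
  # 27-30 superior articular processes
  put(27, c(-12, -18, 3), "sup_artic_L")
  put(28, c(12, -18, 3), "sup_artic_R")
  put(29, c(-20, -16, 1), "artic_lat_L")
  put(30, c(20, -16, 1), "artic_lat_R")
  # 31-38 auricular surface corners (4 per side)
  aur_l <- rbind(c(-45, 5, -10), c(-38, 8, -30), c(-48, -2, -35), c(-52, 2, -15))
  for (j in 1:4) {
    put(30 + j, aur_l[j, ], paste0("auric_L_", j))
    put(34 + j, aur_l[j, ] * c(-1, 1, 1), paste0("auric_R_", j))
  }
  # 39-42 sacral canal corners
  put(39, c(-8, -14, 1), "canal_sup_L")
  put(40, c(8, -14, 1), "canal_sup_R")
  put(41, c(-9, -16, -20), "canal_inf_L")
  put(42, c(9, -16, -20), "canal_inf_R")
  # 43-44 sacral cornua
  put(43, c(-6, -12, -95), "cornu_L")
  put(44, c(6, -12, -95), "cornu_R")

  # curve 1 (45-52): corpus superior rim, anchors corpus_lat_L -> corpus_lat_R
  th <- pi * (9 - 1:8) / 9
  for (j in 1:8) put(44 + j, c(24.5 * cos(th[j]), 15 * sin(th[j]), 0),
                     paste0("c1_rim_", j))
  # curves 2/3 (53-60, 61-68): lateral crests, anchors ala tip -> lat_*_5
  sc <- seq(0.15, 0.78, length.out = 8)
  for (j in 1:8) {
    p <- pr(sc[j])
    put(52 + j, c(-p$half_width, p$y, p$z), paste0("c2_crestL_", j))
    put(60 + j, c(p$half_width, p$y, p$z), paste0("c3_crestR_", j))
  }
  # curves 4/5 (69-76, 77-84): auricular boundary ellipses,
  # anchors auric_*_1 -> auric_*_3
  ctr_l <- c(-45, 3, -22.5)
  ph <- seq(0.35, 2 * pi - 0.35, length.out = 8)
  for (j in 1:8) {
    p <- ctr_l + c(4 * cos(ph[j]), 3 * sin(ph[j]), -11 * sin(ph[j] / 2))
    put(68 + j, p, paste0("c4_auricL_", j))
    put(76 + j, p * c(-1, 1, 1), paste0("c5_auricR_", j))
  }
  # curves 6/7 (85-92, 93-100): dorsal crests, anchors sup_artic -> cornu
  sd_ <- seq(0.15, 0.80, length.out = 8)
  for (j in 1:8) {
    p <- pr(sd_[j])
    put(84 + j, c(-10 * (1 - 0.3 * sd_[j]), p$y - p$depth / 2 - 2, p$z),
        paste0("c6_dorsL_", j))
    put(92 + j, c(10 * (1 - 0.3 * sd_[j]), p$y - p$depth / 2 - 2, p$z),
        paste0("c7_dorsR_", j))
  }
  list(coords = pts, labels = lab)
}

# left/right label permutation of the reference (for symmetry checks)
sacrum_symmetry_pairs <- function() {
  swap <- seq_len(100)
  pair <- function(a, b) { swap[a] <<- b; swap[b] <<- a }
  for (j in 0:4) pair(17 + j, 22 + j)
  pair(3, 4); pair(5, 6); pair(27, 28); pair(29, 30)
  for (j in 1:4) pair(30 + j, 34 + j)
  pair(39, 40); pair(41, 42); pair(43, 44)
  for (j in 1:8) { pair(52 + j, 60 + j); pair(68 + j, 76 + j); pair(84 + j, 92 + j) }
  for (j in 1:8) pair(44 + j, 44 + 9 - j)  # rim reverses left<->right
  swap
}

#' Bundled sacrum-like landmark template and reference configuration
#'
#' Deterministically constructs the synthetic sacrum-like template: 44 fixed
#' landmarks and 56 sliding semilandmarks on 7 smooth curves, bilaterally
#' symmetric, with registered SW/CW/CD measurement endpoints (default
#' distances 113, 49 and 30 mm) and the regional subsets `fixed_only`,
#' `auricular`, `S1`, `S1S2` and `corpus`.  The geometry is synthetic (see
#' the package vignette); anatomical fidelity is configuration, not code —
#' the index sets can be edited on the returned template.
#'
#' @param style Only `"sacrum-like"` is available.
#' @return List with `template` (a [landmark_template()]), `reference`
#'   (`100 x 3` mm coordinates) and `symmetry` (the left/right index
#'   permutation under reflection across the midsagittal plane).
#' @export
make_template <- function(style = "sacrum-like") {
  style <- match.arg(style)
  geo <- sacrum_reference()
  curves <- list(
    list(id = "corpus_rim", semis = 45:52, anchors = c(3L, 4L)),
    list(id = "lateral_crest_L", semis = 53:60, anchors = c(5L, 21L)),
    list(id = "lateral_crest_R", semis = 61:68, anchors = c(6L, 26L)),
    list(id = "auricular_L", semis = 69:76, anchors = c(31L, 33L)),
    list(id = "auricular_R", semis = 77:84, anchors = c(35L, 37L)),
    list(id = "dorsal_crest_L", semis = 85:92, anchors = c(27L, 43L)),
    list(id = "dorsal_crest_R", semis = 93:100, anchors = c(28L, 44L)))
  subsets <- list(
    fixed_only = 1:44,
    corpus = c(1:4, 45:52),
    S1 = c(1:6, 27:30, 39:40, 45:52),
    S1S2 = c(1:6, 7, 12, 17, 22, 27:30, 39:42, 45:52, 53:54, 61:62),
    auricular = c(31:38, 69:84))
  tpl <- landmark_template("sacrum-like", 100, curves = curves,
                           measurements = list(SW = c(5L, 6L),
                                               CW = c(3L, 4L),
                                               CD = c(1L, 2L)),
                           labels = geo$labels, subsets = subsets)
  list(template = tpl, reference = geo$coords,
       symmetry = sacrum_symmetry_pairs())
}

# --- deterministic effect fields -------------------------------------------

# project a centered displacement field into the shape tangent space at the
# unit-size reference: remove the scaling direction (the reference itself)
# and the three infinitesimal rotation generators, so Procrustes
# superimposition preserves the field's variance
project_shape_tangent <- function(f, ref_unit) {
  k <- nrow(ref_unit)
  rot <- list(cbind(0, -ref_unit[, 3], ref_unit[, 2]),
              cbind(ref_unit[, 3], 0, -ref_unit[, 1]),
              cbind(-ref_unit[, 2], ref_unit[, 1], 0))
  basis <- vapply(c(list(ref_unit), rot), function(b) {
    b <- b - matrix(colMeans(b), k, 3, byrow = TRUE)
    as.vector(b)
  }, numeric(3 * k))
  q <- qr.Q(qr(basis))
  f <- f - matrix(colMeans(f), k, 3, byrow = TRUE)
  fv <- as.vector(f) - q %*% crossprod(q, as.vector(f))
  matrix(fv, k, 3)
}

# sexual-dimorphism displacement field on the unit-size reference:
# broader alae relative to the corpus, shorter body, deeper sagittal
# curvature in one direction (the female end by convention); unit norm
sex_shape_field <- function(reference) {
  ref <- reference / centroid_size(reference)
  k <- nrow(ref)
  f <- matrix(0, k, 3)
  xr <- max(abs(ref[, 1]))
  zr <- max(abs(ref[, 3]))
  lateral <- abs(ref[, 1]) / xr
  f[, 1] <- f[, 1] + sign(ref[, 1]) * (lateral^2) * 0.6      # alae expansion
  corpus <- which(abs(ref[, 1]) < 0.3 * xr & ref[, 3] > -0.15 * zr)
  f[corpus, 1] <- f[corpus, 1] - 0.4 * ref[corpus, 1] / xr   # corpus narrowing
  f[, 3] <- f[, 3] - 0.35 * ref[, 3] / zr                    # shortening
  f[, 2] <- f[, 2] - 0.3 * (ref[, 3] / zr)^2                 # curvature change
  f <- project_shape_tangent(f, ref)
  f / sqrt(sum(f^2))
}

# allometric displacement field: larger sacra more sagittally curved, with a
# more protruding promontory; orthogonalized against the sex field, unit norm
allometric_field <- function(reference) {
  ref <- reference / centroid_size(reference)
  k <- nrow(ref)
  zr <- max(abs(ref[, 3]))
  f <- matrix(0, k, 3)
  f[, 2] <- -0.8 * (ref[, 3] / zr)^2         # bend: caudal part swings anterior
  f[1, 2] <- f[1, 2] + 0.3                   # promontory protrusion
  f <- project_shape_tangent(f, ref)
  fs <- sex_shape_field(reference)
  f <- f - sum(f * fs) * fs
  f / sqrt(sum(f^2))
}

# small deterministic per-group offset fields (flatter vs more curved,
# wider vs narrower), orthogonalized against sex and allometric fields
group_offset_fields <- function(reference, groups) {
  ref <- reference / centroid_size(reference)
  k <- nrow(ref)
  zr <- max(abs(ref[, 3])); xr <- max(abs(ref[, 1]))
  base1 <- matrix(0, k, 3); base1[, 2] <- (ref[, 3] / zr)^3      # curvature
  base2 <- matrix(0, k, 3); base2[, 1] <- ref[, 1] / xr * 0.5    # width
  norm_orth <- function(f, others) {
    f <- project_shape_tangent(f, ref)
    for (o in others) f <- f - sum(f * o) * o
    f / sqrt(sum(f^2))
  }
  fs <- sex_shape_field(reference); fa <- allometric_field(reference)
  b1 <- norm_orth(base1, list(fs, fa))
  b2 <- norm_orth(base2, list(fs, fa, b1))
  out <- list()
  for (i in seq_along(groups)) {
    ang <- 2 * pi * (i - 1) / max(1, length(groups))
    out[[groups[i]]] <- cos(ang) * b1 + sin(ang) * b2
  }
  # center the cell means so group effects are deviations, not a shift
  avg <- Reduce(`+`, out) / length(out)
  lapply(out, function(f) f - avg)
}

#' Specification of a synthetic landmark population
#'
#' Collects the generator parameters.  The defaults emulate the variance
#' structure reported for heterogeneous modern-human sacrum samples: a weak
#' sex-specific mean-shape offset (about 2% of total shape variance),
#' a weak allometric component (larger sacra more curved sagittally), small
#' geographic-group offsets, nearly size-monomorphic sexes (male/female
#' centroid-size ratio about 113.7/112.3), and independent isotropic
#' digitizing noise of 0.5% of centroid size per landmark coordinate.
#'
#' @param template Output of [make_template()] (template + reference), or
#'   `NULL` for the default.
#' @param n_per_cell Named-by-sex specimen counts per (sex x group) cell, or
#'   a single integer used for all cells.
#' @param groups Character vector of geographic group labels.
#' @param d_shape Magnitude of the sex mean-shape offset (units of the
#'   unit-size shape; the F and M means sit at -/+ `d_shape/2` along the
#'   unit sex field).
#' @param a_allometry Allometric slope (shape displacement per unit lnCS).
#' @param group_scale Magnitude of the per-group offsets.
#' @param size_log_mean Population mean of lnCS (mm scale); default is the
#'   reference centroid size.
#' @param size_log_sd SD of lnCS.
#' @param size_sex_shift Difference in mean lnCS (M - F).
#' @param landmark_noise_sd Digitizing noise SD as a fraction of centroid
#'   size, per landmark coordinate.
#' @param semi_jitter_sd Additional tangential jitter SD applied to the
#'   semilandmarks (exercises sliding).
#' @param seed Integer RNG seed (required at simulation time).
#' @return List of class `population_spec`.
#' @export
population_spec <- function(template = NULL, n_per_cell = 25,
                            groups = c("GroupA", "GroupB"),
                            d_shape = 0.027, a_allometry = 0.13,
                            group_scale = 0.017,
                            size_log_mean = NULL, size_log_sd = 0.09,
                            size_sex_shift = log(113.7 / 112.3),
                            landmark_noise_sd = 0.005,
                            semi_jitter_sd = 0.01, seed = NULL) {
  if (is.null(template)) template <- make_template()
  if (landmark_noise_sd < 0 || semi_jitter_sd < 0)
    stop("noise SDs must be non-negative")
  if (is.null(size_log_mean))
    size_log_mean <- log(centroid_size(template$reference))
  structure(list(template = template, n_per_cell = n_per_cell,
                 groups = groups, d_shape = d_shape,
                 a_allometry = a_allometry, group_scale = group_scale,
                 size_log_mean = size_log_mean, size_log_sd = size_log_sd,
                 size_sex_shift = size_sex_shift,
                 landmark_noise_sd = landmark_noise_sd,
                 semi_jitter_sd = semi_jitter_sd, seed = seed),
            class = "population_spec")
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c_ <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
           2 * (b * c_ + a * d), a^2 - b^2 + c_^2 - d^2, 2 * (c_ * d - a * b),
           2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 - b^2 - c_^2 + d^2),
         3, 3, byrow = TRUE)
}

#' Simulate a landmark population with known ground truth
#'
#' Per specimen the unit-size shape is
#' `reference + sign(sex) * d_shape * F_sex + G_group +
#'  a_allometry * F_allo * (lnCS - mean lnCS) + noise`,
#' with `sign = -1/2` for F and `+1/2` for M, unit-norm deterministic
#' effect fields built from the template geometry (so the F-to-M mean
#' difference field equals `d_shape * F_sex` exactly), lognormal centroid
#' sizes per sex, tangential semilandmark jitter, and isotropic Gaussian
#' landmark noise.  Each raw configuration is then scaled to its target
#' centroid size and placed in an arbitrary rigid position (random rotation
#' + translation), as digitized specimens would be.
#'
#' @param spec A [population_spec()].
#' @param seed Overrides `spec$seed`.
#' @return List with `data` (a [landmark_set()] of raw mm coordinates),
#'   `meta` (specimen_id, sex, group), and `truth` — a list holding the
#'   per-specimen true lnCS, the noise-free unit shapes, the effect fields,
#'   the realized variance shares of the sex / size / group / noise
#'   components (computed on the generated unit-shape matrix), and the seed.
#' @export
simulate_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  seed <- seed %||% spec$seed
  if (is.null(seed)) stop("a seed is required")
  set.seed(seed)
  tpl <- spec$template$template
  ref <- spec$template$reference
  ref_unit <- center_config(ref) / centroid_size(ref)
  k <- tpl$k
  f_sex <- sex_shape_field(ref)
  f_allo <- allometric_field(ref)
  g_fields <- group_offset_fields(ref, spec$groups)

  cells <- expand.grid(sex = c("F", "M"), group = spec$groups,
                       stringsAsFactors = FALSE)
  n_cell <- if (length(spec$n_per_cell) == 1L)
    rep(spec$n_per_cell, nrow(cells)) else spec$n_per_cell
  if (sum(n_cell) < 1L) stop("all simulation cells are empty")

  sex <- rep(cells$sex, n_cell)
  group <- rep(cells$group, n_cell)
  n <- length(sex)
  sign_sex <- ifelse(sex == "F", -0.5, 0.5)
  mu_ln <- spec$size_log_mean + sign_sex * spec$size_sex_shift
  lnCS <- stats::rnorm(n, mu_ln, spec$size_log_sd)

  comp_sex <- array(0, c(k, 3, n)); comp_size <- comp_sex
  comp_group <- comp_sex; comp_noise <- comp_sex
  raw <- array(NA_real_, c(k, 3, n))
  shapes_true <- array(NA_real_, c(k, 3, n))
  mean_lnCS <- spec$size_log_mean
  for (i in seq_len(n)) {
    cs_i <- comp_sex[, , i] <- sign_sex[i] * spec$d_shape * f_sex
    ca_i <- comp_size[, , i] <-
      spec$a_allometry * (lnCS[i] - mean_lnCS) * f_allo
    cg_i <- comp_group[, , i] <- spec$group_scale * g_fields[[group[i]]]
    shape <- ref_unit + cs_i + ca_i + cg_i
    shapes_true[, , i] <- shape
    noise <- matrix(stats::rnorm(k * 3, 0, spec$landmark_noise_sd), k, 3)
    if (spec$semi_jitter_sd > 0 && length(tpl$semis)) {
      tang <- semilandmark_tangents(shape, tpl)
      jit <- stats::rnorm(length(tpl$semis), 0, spec$semi_jitter_sd)
      noise[tpl$semis, ] <- noise[tpl$semis, ] + jit * tang
    }
    comp_noise[, , i] <- noise
    shape <- shape + noise
    cfg <- shape * exp(lnCS[i])
    cfg <- cfg %*% random_rotation()
    cfg <- sweep(cfg, 2, stats::rnorm(3, 0, 50), `+`)
    raw[, , i] <- cfg
  }
  ids <- sprintf("sim%03d", seq_len(n))
  shares <- component_shares(list(sex = comp_sex, size = comp_size,
                                  group = comp_group, noise = comp_noise))
  list(data = landmark_set(raw, tpl, ids = ids),
       meta = data.frame(specimen_id = ids, sex = sex, group = group,
                         stringsAsFactors = FALSE),
       truth = list(lnCS = lnCS, shapes = shapes_true,
                    sex_field = f_sex, allometric_field = f_allo,
                    group_fields = g_fields,
                    variance_shares = shares, seed = seed, spec = spec))
}

# realized share of total (centered) unit-shape variance per component
component_shares <- function(components) {
  mats <- lapply(components, flatten_coords)
  total <- Reduce(`+`, mats)
  ss <- function(m) sum(sweep(m, 2, colMeans(m))^2)
  ss_tot <- ss(total)
  c(vapply(mats, function(m) ss(m) / ss_tot, numeric(1)), total = ss_tot)
}

#' Simulate a linear-measurement table
#'
#' Per-sex trivariate Gaussian SW / CW / CD (mm) with the given means, SDs
#' and a common correlation structure.  The defaults emulate the complete-
#' sample structure of heterogeneous modern-human data: SW nearly
#' non-dimorphic (F 112.3 +/- 10.0 vs M 113.7 +/- 10.8), CW and CD strongly
#' dimorphic (F 46.1 +/- 4.3 vs M 51.5 +/- 4.7; F 28.3 +/- 2.9 vs
#' M 31.8 +/- 2.8), and a CW-CD correlation of 0.70 (SW-CW 0.42).  Indices
#' are computed downstream by [compute_indices()], not generated.
#'
#' @param n_f,n_m Specimens per sex.
#' @param means Named list with numeric `F` and `M` vectors `(SW, CW, CD)`.
#' @param sds Same structure for the SDs.
#' @param correlations 3x3 correlation matrix for `(SW, CW, CD)`.
#' @param seed Integer RNG seed (required).
#' @return List with `data` (data.frame `specimen_id`, `sex`, `SW`, `CW`,
#'   `CD`) and `truth` (the generating parameters).
#' @export
simulate_measurements <- function(n_f, n_m,
                                  means = list(F = c(SW = 112.3, CW = 46.1, CD = 28.3),
                                               M = c(SW = 113.7, CW = 51.5, CD = 31.8)),
                                  sds = list(F = c(SW = 10.0, CW = 4.3, CD = 2.9),
                                             M = c(SW = 10.8, CW = 4.7, CD = 2.8)),
                                  correlations = default_measurement_cor(),
                                  seed = NULL) {
  if (is.null(seed)) stop("a seed is required")
  set.seed(seed)
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) stop("correlation matrix is not positive definite")
  gen <- function(n, m, s) {
    sigma <- diag(s) %*% correlations %*% diag(s)
    MASS::mvrnorm(n, mu = m, Sigma = sigma)
  }
  xf <- gen(n_f, means$F, sds$F)
  xm <- gen(n_m, means$M, sds$M)
  d <- data.frame(specimen_id = sprintf("lm%03d", seq_len(n_f + n_m)),
                  sex = rep(c("F", "M"), c(n_f, n_m)),
                  rbind(xf, xm), stringsAsFactors = FALSE)
  names(d)[3:5] <- c("SW", "CW", "CD")
  list(data = d,
       truth = list(means = means, sds = sds, correlations = correlations,
                    seed = seed))
}

#' Default SW/CW/CD correlation structure
#'
#' CW-CD 0.70, SW-CW 0.42, SW-CD 0.45.
#' @return 3x3 correlation matrix.
#' @export
default_measurement_cor <- function() {
  m <- matrix(c(1, 0.42, 0.45,
                0.42, 1, 0.70,
                0.45, 0.70, 1), 3, 3,
              dimnames = list(c("SW", "CW", "CD"), c("SW", "CW", "CD")))
  m
}
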