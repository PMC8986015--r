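#' Thin-plate-spline bending-energy model for a reference configuration
#'
#' Assembles the TPS kernel matrix and the bending-energy matrix of a
#' reference configuration.  The kernel is the standard fundamental solution:
#' U(r) = r^2 log r^2 in 2D and U(r) = r in 3D.  The bending-energy matrix
#' `Bk` is the upper-left k x k block of the inverse of the bordered system
#' [[K, P], [P', 0]] with P = [1, X]; the quadratic form `d' Bk d` (summed
#' over coordinate axes) measures the non-affine part of a deformation and
#' vanishes exactly on affine displacement fields.
#'
#' @param reference `k x d` matrix (d = 2 or 3) with no coincident points.
#' @return Object of class `bending_energy_model`: `reference`,
#'   `kernel_matrix`, `bending_energy_matrix`, `dimension`.
#' @export
bending_energy_model <- function(reference) {
  x <- as.matrix(reference)
  d <- ncol(x)
  if (!d %in% c(2L, 3L)) stop("reference must be k x 2 or k x 3")
  k <- nrow(x)
  if (k < d + 2L) stop("too few landmarks for a TPS model")
  r <- as.matrix(stats::dist(x))
  if (any(r[upper.tri(r)] < 1e-12))
    stop("coincident reference landmarks: TPS kernel is singular")
  km <- tps_kernel(r, d)
  p <- affine_block(x)
  np <- ncol(p)
  l <- rbind(cbind(km, p), cbind(t(p), matrix(0, np, np)))
  li <- tryCatch(solve(l), error = function(e)
    stop("singular TPS system (degenerate reference): ", conditionMessage(e)))
  bk <- li[seq_len(k), seq_len(k), drop = FALSE]
  # the biharmonic fundamental solution carries a positive constant in 2D
  # (r^2 log r^2 convention) but a negative one in 3D (U = r), so the
  # positive-semidefinite energy form needs a sign flip in 3D
  if (d == 3L) bk <- -bk
  bk <- (bk + t(bk)) / 2
  structure(list(reference = x, kernel_matrix = km,
                 bending_energy_matrix = bk, dimension = d),
            class = "bending_energy_model")
}

# affine polynomial block [1, X], pruned to full column rank so that
# coplanar or collinear references (degenerate affine span) stay solvable
affine_block <- function(x) {
  p <- cbind(1, x)
  q <- qr(p)
  p[, q$pivot[seq_len(q$rank)], drop = FALSE]
}

tps_kernel <- function(r, d) {
  if (d == 2L) {
    u <- matrix(0, nrow(r), ncol(r))
    nz <- r > 0
    u[nz] <- r[nz]^2 * log(r[nz]^2)
    u
  } else r
}

#' @export
print.bending_energy_model <- function(x, ...) {
  cat("bending_energy_model:", nrow(x$reference), "landmarks,",
      x$dimension, "D\n")
  invisible(x)
}

#' Bending energy of a deformation
#'
#' Value of the TPS bending-energy quadratic form for the deformation
#' mapping the model's reference onto `target`, summed over coordinate axes.
#' Zero for the identity and for any affine transform of the reference.
#'
#' @param model A [bending_energy_model()].
#' @param target `k x d` matrix with the model's landmark count.
#' @return Non-negative numeric.
#' @export
bending_energy <- function(model, target) {
  stopifnot(inherits(model, "bending_energy_model"))
  target <- as.matrix(target)
  if (!all(dim(target) == dim(model$reference)))
    stop("target does not match the reference dimensions")
  # Bk annihilates affine functions of the reference, so using the target
  # coordinates directly equals using the displacement field
  sum(vapply(seq_len(ncol(target)),
             function(a) drop(crossprod(target[, a],
                                        model$bending_energy_matrix %*% target[, a])),
             numeric(1)))
}

#' Evaluate the TPS interpolant reference -> target at query points
#'
#' @param model A [bending_energy_model()].
#' @param target `k x d` matrix of target landmark positions.
#' @param query `m x d` matrix of evaluation points.
#' @return `m x d` matrix of warped points; landmarks are interpolated
#'   exactly.
#' @export
tps_warp <- function(model, target, query) {
  stopifnot(inherits(model, "bending_energy_model"))
  target <- as.matrix(target); query <- as.matrix(query)
  d <- model$dimension; k <- nrow(model$reference)
  if (!all(dim(target) == c(k, d))) stop("target does not match the model")
  if (ncol(query) != d) stop("query points must be m x ", d)
  pfull <- cbind(1, model$reference)
  qrp <- qr(pfull)
  piv <- qrp$pivot[seq_len(qrp$rank)]
  p <- pfull[, piv, drop = FALSE]
  np <- ncol(p)
  l <- rbind(cbind(model$kernel_matrix, p),
             cbind(t(p), matrix(0, np, np)))
  rhs <- rbind(target, matrix(0, np, d))
  coefs <- solve(l, rhs)
  w <- coefs[seq_len(k), , drop = FALSE]
  a <- coefs[(k + 1L):(k + np), , drop = FALSE]
  # distances query -> reference landmarks
  qr2 <- outer(rowSums(query^2), rowSums(model$reference^2), "+") -
    2 * query %*% t(model$reference)
  qr2[qr2 < 0] <- 0
  u <- tps_kernel(sqrt(qr2), d)
  cbind(1, query)[, piv, drop = FALSE] %*% a + u %*% w
}

# unit tangent directions at the semilandmarks of one configuration:
# central difference of the adjacent curve points, one-sided at free ends
semilandmark_tangents <- function(cfg, template) {
  semis <- template$semis
  tang <- matrix(NA_real_, length(semis), 3)
  pos_of <- match(seq_len(template$k), semis)  # landmark -> row in tang
  for (cv in template$curves) {
    seq_ <- curve_sequence(cv)
    if (length(seq_) < 2L)
      stop("curve '", cv$id, "' has fewer than 2 points; tangent undefined")
    if (length(seq_) < 3L && length(cv$semis) == length(seq_))
      stop("curve '", cv$id, "' has < 3 points and no anchors; tangent undefined")
    for (s in cv$semis) {
      j <- match(s, seq_)
      lo <- if (j > 1L) seq_[j - 1L] else s
      hi <- if (j < length(seq_)) seq_[j + 1L] else s
      v <- cfg[hi, ] - cfg[lo, ]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) stop("degenerate tangent on curve '", cv$id, "'")
      tang[pos_of[s], ] <- v / nv
    }
  }
  tang
}

# one joint bending-energy-minimizing sliding pass of one configuration
# against a fixed reference; returns the slid configuration
slide_one_pass <- function(cfg, tang, bk, semis) {
  m <- length(semis)
  if (!m) return(cfg)
  k <- nrow(cfg)
  amat <- matrix(0, m, m); bvec <- numeric(m)
  for (axis in 1:3) {
    ta <- matrix(0, k, m)
    ta[cbind(semis, seq_len(m))] <- tang[, axis]
    bta <- bk %*% ta
    amat <- amat + crossprod(ta, bta)
    bvec <- bvec - drop(crossprod(bta, cfg[, axis]))
  }
  s <- solve(amat + diag(1e-12 * max(diag(amat)), m), bvec)
  cfg[semis, ] <- cfg[semis, ] + s * tang
  cfg
}

#' Slide semilandmarks by bending-energy minimization
#'
#' Alternates generalized Procrustes superimposition with sliding passes.
#' Within a pass, every specimen's semilandmarks move only along their local
#' curve tangents (central differences of the adjacent curve points, one-
#' sided at free curve ends), and the sliding amounts for all semilandmarks
#' are solved jointly as one constrained quadratic program minimizing the
#' TPS bending energy of the deformation from the current reference (the
#' sample Procrustes consensus) to the specimen.  Fixed landmarks never
#' move during sliding.  After each pass the dataset is re-superimposed and
#' the reference updated.
#'
#' @param x A [landmark_set()] (raw coordinates) or a [gpa_align()] fit.
#' @param template Template; defaults to the one carried by `x`.
#' @param outer_iterations Number of slide/re-align passes (default 3, the
#'   conventional choice).
#' @param realign Re-superimpose after each pass (default `TRUE`).  With
#'   `FALSE` a single pass is performed in the initial Procrustes frame and
#'   fixed landmarks are returned bit-identical — useful for oracle checks.
#' @param tangents `"reference"` (default): tangent directions from the
#'   adjacent curve points of the current reference, identical for all
#'   specimens and stable under digitizing noise, making the constrained
#'   optimum an exact fixed point of the pass; `"specimen"`: tangents from
#'   each specimen's own current curve points.
#' @return Object of class `sliding_result`: `gpa` (final alignment of the
#'   slid data), `coords` (`k x 3 x n` slid aligned coordinates),
#'   `energy_before` / `energy_after` (per specimen, measured against the
#'   reference of the pass in which they were computed), `energy_path`
#'   (`n x 2 x passes` array of per-pass before/after energies),
#'   `outer_iterations`, `template`, `ids`.
#' @export
slide_semilandmarks <- function(x, template = NULL, outer_iterations = 3,
                                realign = TRUE,
                                tangents = c("reference", "specimen")) {
  tangents <- match.arg(tangents)
  if (inherits(x, "landmark_set")) {
    template <- template %||% x$template
    g <- gpa_align(x)
  } else if (inherits(x, "gpa_fit")) {
    template <- template %||% x$template
    g <- x
  } else stop("'x' must be a landmark_set or gpa_fit")
  if (is.null(template)) stop("a template is required")
  if (!length(template$curves)) stop("template declares no curves")
  n <- dim(g$coords)[3]
  semis <- template$semis
  passes <- max(1L, as.integer(outer_iterations))
  if (!realign) passes <- 1L
  energy_path <- array(NA_real_, c(n, 2, passes),
                       dimnames = list(g$ids, c("before", "after"), NULL))
  coords <- g$coords
  for (pass in seq_len(passes)) {
    ref <- g$consensus
    model <- bending_energy_model(ref)
    bk <- model$bending_energy_matrix
    tang_ref <- if (length(semis) && tangents == "reference")
      semilandmark_tangents(ref, template) else NULL
    for (i in seq_len(n)) {
      cfg <- coords[, , i]
      energy_path[i, 1, pass] <- bending_energy(model, cfg)
      if (length(semis)) {
        tang <- tang_ref %||% semilandmark_tangents(cfg, template)
        cfg <- slide_one_pass(cfg, tang, bk, semis)
      }
      energy_path[i, 2, pass] <- bending_energy(model, cfg)
      coords[, , i] <- cfg
    }
    if (realign) {
      g2 <- gpa_align(coords, scale = g$scale)
      g2$csize <- g$csize       # sizes refer to the raw digitized data
      g2$lnCS <- g$lnCS
      g2$ids <- g$ids; g2$template <- template
      g <- g2
      coords <- g$coords
    }
  }
  if (!realign) {
    g$coords <- coords
  }
  structure(list(gpa = g, coords = g$coords,
                 energy_before = energy_path[, 1, 1],
                 energy_after = energy_path[, 2, passes],
                 energy_path = energy_path,
                 outer_iterations = passes,
                 template = template, ids = g$ids),
            class = "sliding_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sliding_result <- function(x, ...) {
  cat("sliding_result:", dim(x$coords)[3], "specimens,",
      x$outer_iterations, "passes\n")
  cat(sprintf("  mean bending energy: %.4g (pass-1 start) -> %.4g (final)\n",
              mean(x$energy_path[, 1, 1]),
              mean(x$energy_path[, 2, x$outer_iterations])))
  invisible(x)
}

#' Group mean-difference displacement field
#'
#' The per-landmark displacement from the mean shape of `group_a` to that of
#' `group_b`, optionally exaggerated, plus the series of warped mean shapes
#' used for deformation visualizations (exaggerated-A, mean-A, grand mean
#' along the difference axis, mean-B, exaggerated-B).
#'
#' @param gpa A [gpa_align()] fit (or `sliding_result`).
#' @param labels Group label per specimen.
#' @param group_a,group_b Labels of the two groups.
#' @param exaggeration Multiplier applied to the reported field (default 1).
#' @param t_values Positions along the A->B axis at which shapes are
#'   returned; default `c(-exaggeration, 0, 0.5, 1, 1 + exaggeration)`.
#' @return List with `field` (`k x 3`, `exaggeration * (mean_b - mean_a)`),
#'   `mean_a`, `mean_b`, `shapes` (list of `k x 3` matrices named by t), and
#'   `t_values`.
#' @export
mean_difference_field <- function(gpa, labels, group_a, group_b,
                                  exaggeration = 1, t_values = NULL) {
  if (inherits(gpa, "sliding_result")) gpa <- gpa$gpa
  stopifnot(inherits(gpa, "gpa_fit"))
  labels <- as.character(labels)
  ia <- which(labels == group_a); ib <- which(labels == group_b)
  if (!length(ia)) stop("empty group: ", group_a)
  if (!length(ib)) stop("empty group: ", group_b)
  mean_a <- apply(gpa$coords[, , ia, drop = FALSE], c(1, 2), mean)
  mean_b <- apply(gpa$coords[, , ib, drop = FALSE], c(1, 2), mean)
  diff <- mean_b - mean_a
  if (is.null(t_values)) t_values <- c(-exaggeration, 0, 0.5, 1, 1 + exaggeration)
  shapes <- lapply(t_values, function(t) mean_a + t * diff)
  names(shapes) <- sprintf("t=%g", t_values)
  list(field = exaggeration * diff, mean_a = mean_a, mean_b = mean_b,
       shapes = shapes, t_values = t_values)
}
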