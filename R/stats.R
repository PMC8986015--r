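# coerce the various shape containers to an n x p data matrix
as_shape_matrix <- function(x) {
  if (inherits(x, "sliding_result")) x <- x$gpa
  if (inherits(x, "gpa_fit")) return(flatten_coords(x$coords))
  if (is.array(x) && length(dim(x)) == 3L) return(flatten_coords(x))
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  stop("cannot interpret 'x' as a shape data matrix")
}

#' Principal component analysis in shape or form space
#'
#' Centered PCA (no column scaling) of the flattened Procrustes shape
#' coordinates (`space = "shape"`) or of the coordinates augmented with the
#' lnCS column (`space = "form"`).  The number of retained components is
#' `min(n - 1, ncol)`.
#'
#' @param x A [gpa_align()] fit, [slide_semilandmarks()] result, or a data
#'   matrix.
#' @param space `"shape"` or `"form"`; ignored when `x` is already a matrix.
#' @return Object of class `shape_space`: `scores` (n x p), `eigenvalues`
#'   (descending), `percent` (summing to 100), `loadings` (p x ncol, rows =
#'   components), `mean_vector`, `space`.
#' @export
shape_pca <- function(x, space = c("shape", "form")) {
  space <- match.arg(space)
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
  } else {
    g <- if (inherits(x, "sliding_result")) x$gpa else x
    stopifnot(inherits(g, "gpa_fit"))
    m <- if (space == "form") to_form_space(g) else flatten_coords(g$coords)
  }
  n <- nrow(m)
  if (n < 2L) stop("PCA needs at least 2 specimens")
  pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  p <- min(n - 1L, ncol(m), length(pr$sdev))
  eig <- pr$sdev[seq_len(p)]^2
  structure(list(scores = pr$x[, seq_len(p), drop = FALSE],
                 eigenvalues = eig,
                 percent = 100 * eig / sum(pr$sdev^2),
                 loadings = t(pr$rotation[, seq_len(p), drop = FALSE]),
                 mean_vector = pr$center, space = space),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("shape_space (", x$space, " space): ", nrow(x$scores), " specimens, ",
      length(x$eigenvalues), " components\n", sep = "")
  cat("  variance explained (%):",
      paste(sprintf("%.1f", utils::head(x$percent, 5)), collapse = ", "),
      if (length(x$percent) > 5) "...", "\n")
  invisible(x)
}

build_predictor_matrix <- function(predictor, n) {
  if (is.data.frame(predictor)) {
    mm <- stats::model.matrix(~ ., data = predictor)
  } else if (is.factor(predictor) || is.character(predictor)) {
    f <- factor(predictor)
    if (nlevels(f) < 2L) stop("constant predictor")
    mm <- stats::model.matrix(~ f)
  } else {
    predictor <- as.numeric(predictor)
    if (stats::sd(predictor) < 1e-300) stop("constant predictor")
    mm <- cbind(`(Intercept)` = 1, predictor = predictor)
  }
  if (nrow(mm) != n) stop("predictor length does not match the data")
  mm
}

ss_explained <- function(y, mm) {
  yc <- sweep(y, 2, colMeans(y))
  ss_tot <- sum(yc^2)
  fit <- stats::lm.fit(mm, y)
  ss_res <- sum(fit$residuals^2)
  list(ss_tot = ss_tot, ss_model = ss_tot - ss_res, ss_res = ss_res)
}

#' Percent shape variance explained by one predictor block
#'
#' Multivariate least squares of all shape columns on a single predictor
#' (numeric lnCS, binary sex, or dummy-coded categorical origin); the
#' reported percentage is `100 * SS_model / SS_total` summed over all
#' columns.  An optional permutation test shuffles the predictor rows.
#'
#' @param x Shape data (matrix, `gpa_fit`, or `sliding_result`).
#' @param predictor Numeric vector, factor/character vector, or data.frame
#'   of predictors treated as one block.
#' @param n_perm Number of permutations for the optional test (0 = none).
#' @param seed RNG seed for the permutation test.
#' @return Object of class `regression_result`: `predictor`, `percent`,
#'   `coefficients`, `ss`, and `permutation_p` (NA if `n_perm = 0`, else the
#'   add-one estimator `(#{perm >= obs} + 1) / (n_perm + 1)`).
#' @export
variance_explained_regression <- function(x, predictor, n_perm = 0,
                                          seed = NULL) {
  y <- as_shape_matrix(x)
  mm <- build_predictor_matrix(predictor, nrow(y))
  fit <- stats::lm.fit(mm, y)
  ss <- ss_explained(y, mm)
  percent <- 100 * ss$ss_model / ss$ss_tot
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(y)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      mmp <- mm[sample.int(n), , drop = FALSE]
      mmp[, 1] <- 1  # keep the intercept
      sb <- ss_explained(y, mmp)
      if (sb$ss_model >= ss$ss_model - 1e-12) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(predictor = deparse(substitute(predictor)),
                 percent = percent, coefficients = fit$coefficients,
                 ss = ss, permutation_p = p),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("regression_result: %.2f%% of variance explained", x$percent))
  if (!is.na(x$permutation_p))
    cat(sprintf(" (permutation p = %.4g)", x$permutation_p))
  cat("\n")
  invisible(x)
}

#' Sex effect on shape after correcting for allometry
#'
#' Two-stage protocol: shape is first regressed on lnCS and the allometric
#' residuals are kept; the residuals are then regressed on sex in binary
#' form.  The stage-2 percentage is reported both relative to the residual
#' variance and relative to the original total variance.
#'
#' @param x Shape data (matrix, `gpa_fit`, or `sliding_result`).
#' @param lnCS Numeric vector of log centroid sizes (taken from `x` when it
#'   is a `gpa_fit` and `lnCS` is missing).
#' @param sex Two-level factor/character vector (e.g. F/M).
#' @return List with `percent_of_residual`, `percent_of_total`,
#'   `allometry_percent` (stage-1), and the two `regression_result`s.
#' @export
allometry_corrected_sex_effect <- function(x, lnCS = NULL, sex) {
  if (is.null(lnCS)) {
    g <- if (inherits(x, "sliding_result")) x$gpa else x
    if (!inherits(g, "gpa_fit")) stop("supply lnCS when 'x' is a plain matrix")
    lnCS <- g$lnCS
  }
  sex <- factor(as.character(sex))
  if (nlevels(sex) < 2L) stop("both sexes must be present")
  y <- as_shape_matrix(x)
  mm1 <- build_predictor_matrix(as.numeric(lnCS), nrow(y))
  fit1 <- stats::lm.fit(mm1, y)
  ss1 <- ss_explained(y, mm1)
  resid <- fit1$residuals
  mm2 <- build_predictor_matrix(sex, nrow(y))
  ss2 <- ss_explained(resid, mm2)
  list(percent_of_residual = 100 * ss2$ss_model / ss2$ss_tot,
       percent_of_total = 100 * ss2$ss_model / ss1$ss_tot,
       allometry_percent = 100 * ss1$ss_model / ss1$ss_tot)
}

#' Permutation test of the distance between two group mean shapes
#'
#' Observed statistic: the Procrustes (Euclidean) distance between the two
#' group mean vectors in the common superimposition frame.  Group labels are
#' randomly permuted `n_perm` times (default 10000); the p-value uses the
#' add-one estimator `(#{perm >= obs} + 1) / (n_perm + 1)`.  With
#' `exact = TRUE` all label assignments are enumerated instead and the
#' p-value is the exact proportion of assignments (including the observed
#' one) with a distance at least as large.
#'
#' @param x Shape data (matrix, `gpa_fit`, or `sliding_result`).
#' @param labels Two-group label vector.
#' @param n_perm Number of random permutations.
#' @param seed RNG seed.
#' @param exact Enumerate all assignments (feasible for small n only).
#' @return Object of class `group_comparison`: `observed`, `p_value`,
#'   `n_perm`, `groups`, `n_per_group`, `exact`.
#' @export
permutation_mean_difference <- function(x, labels, n_perm = 10000,
                                        seed = NULL, exact = FALSE) {
  y <- as_shape_matrix(x)
  labels <- as.character(labels)
  gr <- sort(unique(labels))
  if (length(gr) != 2L) stop("exactly two groups are required (got ",
                             length(gr), ")")
  ia <- labels == gr[1]
  na <- sum(ia); nb <- sum(!ia)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 specimens")
  dist_for <- function(sel) {
    sqrt(sum((colMeans(y[sel, , drop = FALSE]) -
              colMeans(y[!sel, , drop = FALSE]))^2))
  }
  obs <- dist_for(ia)
  n <- nrow(y)
  if (exact) {
    combos <- utils::combn(n, na)
    if (ncol(combos) > 2e5) stop("too many assignments for exact enumeration")
    ds <- apply(combos, 2, function(idx) {
      sel <- rep(FALSE, n); sel[idx] <- TRUE; dist_for(sel)
    })
    p <- mean(ds >= obs - 1e-12)
    n_perm <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      sel <- rep(FALSE, n); sel[sample.int(n, na)] <- TRUE
      if (dist_for(sel) >= obs - 1e-12) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(observed = obs, p_value = p, n_perm = n_perm,
                 groups = gr, n_per_group = c(na, nb), exact = exact),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: %s (n=%d) vs %s (n=%d)\n",
              x$groups[1], x$n_per_group[1], x$groups[2], x$n_per_group[2]))
  cat(sprintf("  distance between means = %.6g, p = %.4g (%s, B = %d)\n",
              x$observed, x$p_value,
              if (x$exact) "exact" else "permutation", x$n_perm))
  invisible(x)
}

#' Procrustes ANOVA with residual randomization
#'
#' Sequential (type-I) sums of squares of the shape data over a series of
#' model terms, with p-values by residual randomization (RRPP): for each
#' term, the residuals of the reduced model (all preceding terms) are
#' permuted, added back to the reduced fit, and the term's F-ratio is
#' recomputed.
#'
#' @param x Shape data (matrix, `gpa_fit`, or `sliding_result`).
#' @param data data.frame of predictors.
#' @param terms Character vector of column names of `data`, in the order the
#'   sequential decomposition should use.
#' @param include_interaction Add all pairwise interactions of `terms` after
#'   the main effects.
#' @param n_perm Number of RRPP permutations.
#' @param seed RNG seed.
#' @return data.frame (class `procrustes_anova`) with one row per term plus
#'   `Residuals` and `Total`: `df`, `SS`, `percent`, `F`, `p`.
#' @export
procrustes_anova <- function(x, data, terms, include_interaction = FALSE,
                             n_perm = 999, seed = NULL) {
  y <- as_shape_matrix(x)
  n <- nrow(y)
  stopifnot(is.data.frame(data), nrow(data) == n)
  if (!all(terms %in% names(data)))
    stop("terms not found in data: ",
         paste(setdiff(terms, names(data)), collapse = ", "))
  term_labels <- terms
  if (include_interaction && length(terms) >= 2L) {
    combs <- utils::combn(terms, 2)
    term_labels <- c(terms, apply(combs, 2, paste, collapse = ":"))
  }
  # cumulative model matrices
  mm_list <- vector("list", length(term_labels) + 1L)
  mm_list[[1]] <- matrix(1, n, 1)
  for (j in seq_along(term_labels)) {
    f <- stats::as.formula(paste("~", paste(term_labels[seq_len(j)],
                                            collapse = " + ")))
    mm_list[[j + 1L]] <- stats::model.matrix(f, data = data)
  }
  ranks <- vapply(mm_list, function(m) qr(m)$rank, integer(1))
  dfs <- diff(ranks)
  if (any(dfs == 0L))
    stop("rank-deficient design; aliased term(s): ",
         paste(term_labels[dfs == 0L], collapse = ", "))
  full_rank <- ranks[length(ranks)]
  if (n <= full_rank) stop("n must exceed the model rank")

  hat <- lapply(mm_list, function(m) {
    q <- qr.Q(qr(m)); tcrossprod(q)
  })
  yc <- sweep(y, 2, colMeans(y))
  ss_tot <- sum(yc^2)
  nt <- length(term_labels)
  fit_full <- hat[[nt + 1L]] %*% y
  ss_res_full <- sum((y - fit_full)^2)
  df_res <- n - full_rank

  ss_term <- numeric(nt); f_term <- numeric(nt); p_term <- numeric(nt)
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_len(nt)) {
    h_red <- hat[[j]]; h_ful <- hat[[j + 1L]]
    ss_term[j] <- sum(((h_ful - h_red) %*% y)^2)
    f_obs <- (ss_term[j] / dfs[j]) / (ss_res_full / df_res)
    f_term[j] <- f_obs
    if (n_perm > 0) {
      r0 <- y - h_red %*% y
      h_last <- hat[[nt + 1L]]
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        rp <- r0[sample.int(n), , drop = FALSE]
        ss_j <- sum(((h_ful - h_red) %*% rp)^2)
        ss_r <- sum(((diag(n) - h_last) %*% rp)^2)
        f_b <- (ss_j / dfs[j]) / (ss_r / df_res)
        if (f_b >= f_obs - 1e-12) exceed <- exceed + 1L
      }
      p_term[j] <- (exceed + 1) / (n_perm + 1)
    } else p_term[j] <- NA_real_
  }
  out <- data.frame(
    term = c(term_labels, "Residuals", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(ss_term, ss_res_full, ss_tot),
    percent = 100 * c(ss_term, ss_res_full, ss_tot) / ss_tot,
    F = c(f_term, NA, NA),
    p = c(p_term, NA, NA),
    stringsAsFactors = FALSE)
  class(out) <- c("procrustes_anova", "data.frame")
  out
}

#' Two-sample t-test and Cohen's D for one linear measurement
#'
#' Independent two-sided t-test with pooled variance, plus Cohen's D in two
#' conventions: (a) `pooled` — mean difference over the pooled within-group
#' SD (n-1 denominators); (b) `total` — mean difference over the total-
#' sample SD reconstructed from the group summaries (group-size-weighted
#' within + between variance).  Convention (b) is the one that reproduces
#' published summary-table effect sizes computed on the full sample.
#'
#' @param values Numeric vector of measurements.
#' @param sex Two-level label vector; the first sorted level is treated as
#'   the reference for signs but the reported average difference is absolute.
#' @return Object of class `univariate_stats` (see [summary_from_groups()]).
#' @export
ttest_and_effect <- function(values, sex) {
  sex <- factor(as.character(sex))
  if (nlevels(sex) != 2L) stop("exactly two sexes are required")
  v1 <- values[sex == levels(sex)[1]]
  v2 <- values[sex == levels(sex)[2]]
  if (length(v1) < 2L || length(v2) < 2L)
    stop("each sex needs at least 2 observations")
  tt <- stats::t.test(v2, v1, var.equal = TRUE)
  out <- summary_from_groups(length(v1), mean(v1), stats::sd(v1),
                             length(v2), mean(v2), stats::sd(v2))
  out$groups <- levels(sex)
  out$group_stats$min <- c(min(v1), min(v2))
  out$group_stats$max <- c(max(v1), max(v2))
  out$t_statistic <- unname(tt$statistic)
  out$p_value <- tt$p.value
  out
}

#' Univariate statistics and Cohen's D from group summaries
#'
#' Reconstructs the combined-sample statistics from per-group n / mean / SD:
#' the absolute mean difference, the pooled within-group SD (n-1 weights),
#' the total-sample SD (group-size-weighted within variance `sum(n_g sd_g^2)/N`
#' plus between-group variance `sum(n_g (m_g - m)^2)/N`), and Cohen's D in
#' both conventions (`pooled`: difference / pooled SD; `total`: difference /
#' total-sample SD).  Also performs the pooled-variance t-test from the
#' summaries.
#'
#' @param n_f,mean_f,sd_f Female group size, mean, SD.
#' @param n_m,mean_m,sd_m Male group size, mean, SD.
#' @return Object of class `univariate_stats`: `group_stats` (data.frame),
#'   `average_difference`, `pooled_sd`, `total_sd`, `cohens_d_pooled`,
#'   `cohens_d_total`, `t_statistic`, `p_value`.
#' @export
summary_from_groups <- function(n_f, mean_f, sd_f, n_m, mean_m, sd_m) {
  n_f <- as.integer(n_f); n_m <- as.integer(n_m)
  if (n_f < 2L || n_m < 2L) stop("each group needs n >= 2")
  if (sd_f < 0 || sd_m < 0) stop("SDs must be non-negative")
  n <- n_f + n_m
  diff <- abs(mean_m - mean_f)
  pooled_var <- ((n_f - 1) * sd_f^2 + (n_m - 1) * sd_m^2) / (n - 2)
  grand <- (n_f * mean_f + n_m * mean_m) / n
  within_var <- (n_f * sd_f^2 + n_m * sd_m^2) / n
  between_var <- (n_f * (mean_f - grand)^2 + n_m * (mean_m - grand)^2) / n
  total_sd <- sqrt(within_var + between_var)
  pooled_sd <- sqrt(pooled_var)
  t_stat <- (mean_m - mean_f) / (pooled_sd * sqrt(1 / n_f + 1 / n_m))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  structure(list(
    groups = c("F", "M"),
    group_stats = data.frame(group = c("F", "M"), n = c(n_f, n_m),
                             mean = c(mean_f, mean_m), sd = c(sd_f, sd_m),
                             min = NA_real_, max = NA_real_),
    average_difference = diff,
    pooled_sd = pooled_sd, total_sd = total_sd,
    cohens_d_pooled = if (pooled_sd > 0) diff / pooled_sd else 0,
    cohens_d_total = if (total_sd > 0) diff / total_sd else 0,
    t_statistic = t_stat, p_value = p),
    class = "univariate_stats")
}

#' @export
print.univariate_stats <- function(x, ...) {
  print(x$group_stats, row.names = FALSE)
  cat(sprintf("  average difference = %.4g; t = %.3f, p = %.4g\n",
              x$average_difference, x$t_statistic, x$p_value))
  cat(sprintf("  Cohen's D = %.2f (total-sample SD), %.2f (pooled SD)\n",
              x$cohens_d_total, x$cohens_d_pooled))
  invisible(x)
}
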