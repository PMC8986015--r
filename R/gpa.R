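#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid — the standard size measure of geometric morphometrics.
#'
#' @param config `k x 3` numeric matrix (k >= 2), or a [landmark_set()]
#'   (a vector of sizes is then returned).
#' @return Positive numeric (mm if the input is in mm).
#' @export
centroid_size <- function(config) {
  if (inherits(config, "landmark_set"))
    return(apply(config$coords, 3, centroid_size))
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop("centroid size needs at least 2 landmarks")
  sqrt(sum(sweep(config, 2, colMeans(config))^2))
}

center_config <- function(cfg) sweep(cfg, 2, colMeans(cfg))

# optimal proper rotation R minimizing ||a %*% R - b||_F
optimal_rotation <- function(a, b, allow_reflection = FALSE) {
  m <- crossprod(a, b)
  sv <- svd(m)
  r <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(r) < 0) {
    u <- sv$u; u[, 3] <- -u[, 3]
    r <- u %*% t(sv$v)
  }
  r
}

#' Generalized Procrustes analysis
#'
#' Iterative least-squares superimposition: translation is removed by
#' centering, each configuration is (optionally) scaled to unit centroid
#' size, and each is rotated by the proper rotation that best fits the
#' current consensus; the consensus is re-estimated (and rescaled to unit
#' centroid size) until its root-mean-square change falls below `tol`.
#' The first configuration initializes the consensus, making the algorithm
#' deterministic.
#'
#' @param x A [landmark_set()] or a `k x 3 x n` array.
#' @param scale Scale each configuration to unit centroid size (default
#'   `TRUE`; the standard shape-space construction).
#' @param tol Convergence tolerance on the consensus RMS change.
#' @param max_iter Iteration cap.
#' @param allow_reflection Permit improper (reflecting) fits; off by default,
#'   the standard convention.
#' @return An object of class `gpa_fit`: `coords` (`k x 3 x n` aligned),
#'   `consensus` (`k x 3`, unit centroid size), `csize` (original centroid
#'   sizes, mm), `lnCS` (their natural logs), `iterations`, `converged`,
#'   `scale`, `ids`, `template` (if the input carried one).
#' @export
gpa_align <- function(x, scale = TRUE, tol = 1e-10, max_iter = 200,
                      allow_reflection = FALSE) {
  template <- NULL; ids <- NULL
  if (inherits(x, "landmark_set")) {
    template <- x$template; ids <- x$ids; arr <- x$coords
  } else if (is.array(x) && length(dim(x)) == 3L) {
    arr <- x; ids <- dimnames(x)[[3]]
  } else stop("'x' must be a landmark_set or a k x 3 x n array")
  k <- dim(arr)[1]; n <- dim(arr)[3]
  if (n < 1L) stop("need at least one configuration")
  if (is.null(ids)) ids <- paste0("spec", seq_len(n))

  csize <- numeric(n)
  aligned <- array(NA_real_, dim(arr))
  for (i in seq_len(n)) {
    cfg <- center_config(arr[, , i])
    cs <- sqrt(sum(cfg^2))
    if (cs < 1e-12)
      stop("degenerate configuration (all landmarks coincident): ", ids[i])
    csize[i] <- cs
    aligned[, , i] <- if (scale) cfg / cs else cfg
  }

  # initialize the consensus from the mean shape when it is non-degenerate
  # (this makes re-alignment of already-aligned data a fixed point); fall
  # back to the first configuration when the raw orientations cancel out
  consensus <- apply(aligned, c(1, 2), mean)
  if (sqrt(sum(consensus^2)) < 0.1 * mean(apply(aligned, 3, function(m) sqrt(sum(m^2)))))
    consensus <- aligned[, , 1]
  consensus <- consensus / sqrt(sum(consensus^2))
  iterations <- 0L; converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    for (i in seq_len(n)) {
      r <- optimal_rotation(aligned[, , i], consensus, allow_reflection)
      aligned[, , i] <- aligned[, , i] %*% r
    }
    new_consensus <- apply(aligned, c(1, 2), mean)
    new_consensus <- center_config(new_consensus)
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  dimnames(aligned) <- dimnames(arr)
  structure(list(coords = aligned, consensus = consensus, csize = csize,
                 lnCS = log(csize), iterations = iterations,
                 converged = converged, scale = scale, ids = ids,
                 template = template),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("gpa_fit:", dim(x$coords)[3], "specimens x", dim(x$coords)[1],
      "landmarks;", x$iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  centroid size (mm): ", sprintf("%.2f", mean(x$csize)), " (mean), ",
      sprintf("%.2f", stats::sd(x$csize)), " (sd)\n", sep = "")
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' By default the root summed squared coordinate difference of two
#' configurations already expressed in a common superimposition frame (the
#' metric used by the permutation tests).  With `fit = TRUE` a fresh pairwise
#' Procrustes fit (center, unit-scale, optimal proper rotation of `b` onto
#' `a`) is performed first; this variant serves as an independent two-
#' configuration oracle.
#'
#' @param a,b `k x 3` matrices.
#' @param fit Perform a pairwise superimposition before measuring.
#' @param allow_reflection Passed to the pairwise fit.
#' @return Non-negative numeric.
#' @export
procrustes_distance <- function(a, b, fit = FALSE, allow_reflection = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("configurations must have identical dimensions")
  if (fit) {
    a <- center_config(a); a <- a / sqrt(sum(a^2))
    b <- center_config(b); b <- b / sqrt(sum(b^2))
    b <- b %*% optimal_rotation(b, a, allow_reflection)
  }
  sqrt(sum((a - b)^2))
}

# flatten k x 3 x n -> n x 3k (x1 y1 z1 x2 ...); inverse below
flatten_coords <- function(arr) {
  if (inherits(arr, "gpa_fit")) arr <- arr$coords
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  out <- t(apply(arr, 3, function(cfg) as.vector(t(cfg))))
  k <- dim(arr)[1]
  colnames(out) <- paste0(rep(c("x", "y", "z"), k), rep(seq_len(k), each = 3))
  out
}

unflatten_coords <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  k <- ncol(m) / 3L
  arr <- array(NA_real_, c(k, 3, nrow(m)))
  for (i in seq_len(nrow(m))) arr[, , i] <- matrix(m[i, ], ncol = 3, byrow = TRUE)
  arr
}

#' Form-space data matrix
#'
#' Augments the flattened Procrustes shape coordinates with a final column
#' holding the natural logarithm of centroid size (lnCS), converting shape
#' space into form (size-and-shape) space.  The lnCS column is appended
#' unweighted; centering happens inside the PCA, not here.
#'
#' @param gpa A [gpa_align()] fit computed with `scale = TRUE`.
#' @return `n x (3k + 1)` matrix; last column named `lnCS`.
#' @export
to_form_space <- function(gpa) {
  stopifnot(inherits(gpa, "gpa_fit"))
  if (!gpa$scale) stop("form space requires a scaled (shape-space) alignment")
  if (any(gpa$csize <= 0)) stop("nonpositive centroid size")
  m <- cbind(flatten_coords(gpa$coords), lnCS = gpa$lnCS)
  rownames(m) <- gpa$ids
  m
}
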