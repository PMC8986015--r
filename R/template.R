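#' Landmark template definition
#'
#' A template describes the fixed-landmark / semilandmark structure of a
#' configuration: which indices are semilandmarks, how they are ordered along
#' curves (with optional fixed-landmark anchors at the curve ends), which
#' landmark pairs define the registered linear measurements (sacral width SW,
#' corpus width CW, corpus depth CD), and named index subsets used for
#' regional analyses.
#'
#' @param name Template name.
#' @param k Total number of landmarks.
#' @param curves List of curves.  Each curve is a list with elements
#'   `id` (character), `semis` (ordered integer indices of the sliding
#'   semilandmarks along the curve) and `anchors` (integer vector of length 2:
#'   fixed-landmark indices adjacent to the first and last semilandmark, `NA`
#'   where the curve has a free end).
#' @param measurements Named list mapping measurement names (`SW`, `CW`, `CD`,
#'   ...) to integer index pairs (the measurement endpoints).
#' @param labels Character vector of length `k` of landmark labels, or `NULL`
#'   (labels `L1..Lk` are generated).
#' @param subsets Named list of integer index vectors defining regional
#'   subsets (e.g. `fixed_only`, `auricular`, `S1`, `S1S2`, `corpus`).
#'
#' @return An object of class `landmark_template` with components `name`,
#'   `k`, `fixed`, `semis`, `n_fixed`, `n_semi`, `curves`, `measurements`,
#'   `labels`, `subsets`.
#' @seealso [make_template()] for the bundled sacrum-like template,
#'   [subset_landmarks()] for deriving regional templates.
#' @export
landmark_template <- function(name, k, curves = list(), measurements = list(),
                              labels = NULL, subsets = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  k <- as.integer(k)
  if (k < 1L) stop("template must have at least one landmark")
  all_semis <- integer(0)
  for (cv in curves) {
    if (is.null(cv$id) || is.null(cv$semis))
      stop("each curve needs an 'id' and ordered 'semis' indices")
    semis <- as.integer(cv$semis)
    if (any(semis < 1L | semis > k))
      stop("curve '", cv$id, "' has semilandmark indices outside 1..k")
    if (any(semis %in% all_semis))
      stop("curve '", cv$id, "' reuses semilandmarks of another curve; ",
           "curves must be disjoint")
    all_semis <- c(all_semis, semis)
    anchors <- cv$anchors
    if (!is.null(anchors)) {
      anchors <- as.integer(anchors)
      if (length(anchors) != 2L)
        stop("curve '", cv$id, "' anchors must have length 2 (use NA for a free end)")
      ok <- is.na(anchors) | (anchors >= 1L & anchors <= k)
      if (!all(ok)) stop("curve '", cv$id, "' anchor index out of range")
    }
  }
  semis <- sort(unique(all_semis))
  fixed <- setdiff(seq_len(k), semis)
  for (cv in curves) {
    a <- cv$anchors
    if (!is.null(a) && any(stats::na.omit(as.integer(a)) %in% semis))
      stop("curve '", cv$id, "' uses a semilandmark as anchor; anchors must be fixed landmarks")
  }
  for (nm in names(measurements)) {
    ep <- as.integer(measurements[[nm]])
    if (length(ep) != 2L || any(ep < 1L | ep > k) || ep[1] == ep[2])
      stop("measurement '", nm, "' must name two distinct landmark indices in 1..k")
  }
  for (nm in names(subsets)) {
    idx <- as.integer(subsets[[nm]])
    if (any(idx < 1L | idx > k) || anyDuplicated(idx))
      stop("subset '", nm, "' has invalid or duplicated indices")
  }
  if (is.null(labels)) labels <- paste0("L", seq_len(k))
  if (length(labels) != k) stop("labels must have length k")
  structure(
    list(name = name, k = k, fixed = fixed, semis = semis,
         n_fixed = length(fixed), n_semi = length(semis),
         curves = curves, measurements = measurements,
         labels = as.character(labels), subsets = subsets),
    class = "landmark_template")
}

#' @export
print.landmark_template <- function(x, ...) {
  cat("landmark_template '", x$name, "': ", x$k, " landmarks (",
      x$n_fixed, " fixed + ", x$n_semi, " sliding on ",
      length(x$curves), " curves)\n", sep = "")
  if (length(x$measurements))
    cat("  measurements:", paste(names(x$measurements), collapse = ", "), "\n")
  if (length(x$subsets))
    cat("  subsets:", paste(names(x$subsets), collapse = ", "), "\n")
  invisible(x)
}

# ordered point sequence of a curve: anchor, semis..., anchor (NAs dropped)
curve_sequence <- function(curve) {
  a <- if (is.null(curve$anchors)) c(NA_integer_, NA_integer_) else as.integer(curve$anchors)
  seq_ <- c(a[1], as.integer(curve$semis), a[2])
  seq_[!is.na(seq_)]
}

#' Landmark dataset
#'
#' Container for a sample of landmark configurations sharing a template:
#' a `k x 3 x n` coordinate array (mm) with specimen ids, following the
#' array convention of the geometric-morphometrics literature.
#'
#' @param coords `k x 3 x n` numeric array, or a `k x 3` matrix for a single
#'   specimen.
#' @param template A [landmark_template()].
#' @param ids Character vector of specimen ids (defaults to `spec1..specn`).
#' @return An object of class `landmark_set` with components `coords`,
#'   `ids`, `template`.
#' @export
landmark_set <- function(coords, template, ids = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (!inherits(template, "landmark_template"))
    stop("'template' must be a landmark_template")
  if (dim(coords)[1] != template$k)
    stop("coordinate array has ", dim(coords)[1], " landmarks but template '",
         template$name, "' declares ", template$k)
  n <- dim(coords)[3]
  if (n < 1L) stop("cannot build an empty landmark set")
  if (is.null(ids)) ids <- paste0("spec", seq_len(n))
  if (length(ids) != n) stop("'ids' must have one entry per specimen")
  dimnames(coords) <- list(template$labels, c("x", "y", "z"), ids)
  structure(list(coords = coords, ids = as.character(ids), template = template),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:", dim(x$coords)[3], "specimens x", dim(x$coords)[1],
      "landmarks (template '", x$template$name, "')\n", sep = " ")
  invisible(x)
}

#' Number of specimens in a landmark set
#' @param x A `landmark_set`, `gpa_fit` or coordinate array.
#' @return Integer count.
#' @export
n_specimens <- function(x) {
  if (inherits(x, c("landmark_set", "gpa_fit"))) return(dim(x$coords)[3])
  if (is.array(x) && length(dim(x)) == 3L) return(dim(x)[3])
  stop("cannot determine specimen count for this object")
}

#' Restrict a landmark dataset to a named or explicit landmark subset
#'
#' Returns the configurations restricted to the requested landmarks together
#' with a consistently re-indexed template.  Curve memberships are re-indexed;
#' a surviving semilandmark is demoted to a fixed landmark when both of its
#' neighbours along the curve were removed (a tangent direction is then
#' undefined, so sliding would be ill-posed).  Measurements whose endpoints
#' are both retained are kept.
#'
#' @param x A [landmark_set()].
#' @param subset Either the name of a subset registered in the template
#'   (e.g. `"fixed_only"`, `"S1"`) or an integer index vector.
#' @return A new `landmark_set` with a derived template.
#' @export
subset_landmarks <- function(x, subset) {
  stopifnot(inherits(x, "landmark_set"))
  tpl <- x$template
  if (is.character(subset)) {
    if (length(subset) != 1L || !subset %in% names(tpl$subsets))
      stop("unknown subset '", paste(subset, collapse = ","),
           "'; available subsets: ",
           paste(names(tpl$subsets), collapse = ", "))
    keep <- tpl$subsets[[subset]]
    new_name <- paste0(tpl$name, ":", subset)
  } else {
    keep <- as.integer(subset)
    if (any(keep < 1L | keep > tpl$k) || anyDuplicated(keep))
      stop("subset indices must be distinct values in 1..k")
    new_name <- paste0(tpl$name, ":custom")
  }
  keep <- sort(keep)
  new_index <- match(seq_len(tpl$k), keep)  # old -> new (NA if dropped)
  kept <- function(i) !is.na(new_index[i])

  new_curves <- list()
  for (cv in tpl$curves) {
    seq_old <- curve_sequence(cv)
    surv_semis <- integer(0)
    for (s in cv$semis) {
      if (!kept(s)) next
      pos <- match(s, seq_old)
      nb <- c(if (pos > 1L) seq_old[pos - 1L],
              if (pos < length(seq_old)) seq_old[pos + 1L])
      # demote if every original neighbour was removed
      if (length(nb) && any(vapply(nb, kept, logical(1))))
        surv_semis <- c(surv_semis, s)
    }
    if (!length(surv_semis)) next
    a <- if (is.null(cv$anchors)) c(NA_integer_, NA_integer_) else as.integer(cv$anchors)
    a_new <- vapply(a, function(i) if (!is.na(i) && kept(i)) new_index[i] else NA_integer_,
                    integer(1))
    new_curves[[length(new_curves) + 1L]] <-
      list(id = cv$id, semis = new_index[surv_semis], anchors = a_new)
  }
  new_meas <- list()
  for (nm in names(tpl$measurements)) {
    ep <- tpl$measurements[[nm]]
    if (all(vapply(ep, kept, logical(1)))) new_meas[[nm]] <- new_index[ep]
  }
  new_subsets <- list()
  for (nm in names(tpl$subsets)) {
    idx <- intersect(tpl$subsets[[nm]], keep)
    if (length(idx)) new_subsets[[nm]] <- new_index[idx]
  }
  tpl2 <- landmark_template(new_name, length(keep), curves = new_curves,
                            measurements = new_meas,
                            labels = tpl$labels[keep], subsets = new_subsets)
  landmark_set(x$coords[keep, , , drop = FALSE], tpl2, ids = x$ids)
}
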