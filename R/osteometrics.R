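#' Osteometric indices of the first sacral vertebra
#'
#' From the three base measurements — sacral width SW, corpus width CW and
#' corpus depth CD (mm) — computes the corporo-basal index
#' `CBI = 100 * CW / SW`, the corpus-area index
#' `CAI = 100 * sqrt(CW * CD) / SW`, and the superior corpus surface area
#' `CW * CD` (mm^2).  CBI and CAI are scale-invariant; the area scales with
#' the square of size.
#'
#' @param SW,CW,CD Positive numeric vectors (recycled to a common length).
#' @return data.frame with columns `CBI`, `CAI`, `corpus_area`.
#' @export
compute_indices <- function(SW, CW, CD) {
  if (any(c(SW, CW, CD) <= 0)) stop("all measurements must be positive")
  if (any(CW >= SW))
    warning("CW >= SW for some specimens: anatomically implausible sacra")
  data.frame(CBI = 100 * CW / SW,
             CAI = 100 * sqrt(CW * CD) / SW,
             corpus_area = CW * CD)
}

#' Linear measurements from landmark configurations
#'
#' Each registered measurement (SW, CW, CD) is the Euclidean distance between
#' its template-registered landmark pair, evaluated on the raw (unscaled)
#' coordinates in mm; the derived indices are appended.  Chord distances
#' between landmarks approximate the corresponding caliper measurements; the
#' endpoint registry lives in the template so the mapping can be refined.
#'
#' @param x A [landmark_set()] (raw, unaligned coordinates).
#' @param template Template with a measurement registry; defaults to the one
#'   carried by `x`.
#' @return data.frame with `specimen_id`, `SW`, `CW`, `CD`, `CBI`, `CAI`,
#'   `corpus_area`.
#' @export
measure_from_landmarks <- function(x, template = NULL) {
  stopifnot(inherits(x, "landmark_set"))
  template <- template %||% x$template
  need <- c("SW", "CW", "CD")
  missing_m <- setdiff(need, names(template$measurements))
  if (length(missing_m))
    stop("template lacks measurement registry entries: ",
         paste(missing_m, collapse = ", "))
  n <- n_specimens(x)
  vals <- sapply(need, function(nm) {
    ep <- template$measurements[[nm]]
    vapply(seq_len(n), function(i)
      sqrt(sum((x$coords[ep[1], , i] - x$coords[ep[2], , i])^2)), numeric(1))
  })
  vals <- matrix(vals, nrow = n,
                 dimnames = list(NULL, need))
  cbind(data.frame(specimen_id = x$ids, stringsAsFactors = FALSE),
        as.data.frame(vals),
        compute_indices(vals[, "SW"], vals[, "CW"], vals[, "CD"]))
}
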