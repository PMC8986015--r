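#' Read a TPS landmark file
#'
#' Parses the classic TPS interchange format used throughout morphometrics:
#' each record starts with `LM3=<k>` (3D) followed by `k` whitespace-separated
#' coordinate lines, optionally followed by `ID=<specimen id>`.  Records
#' without an `ID=` line receive sequential ids.
#'
#' @param path Path to a TPS file.
#' @param template A [landmark_template()]; the landmark count of every record
#'   is checked against it.
#' @return A [landmark_set()] with one configuration per record, in file
#'   order.
#' @export
read_tps <- function(path, template) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  configs <- list(); ids <- character(0)
  i <- 1L; n_lines <- length(lines)
  while (i <= n_lines) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    m <- regmatches(line, regexec("^LM3?=([0-9]+)$", line, ignore.case = TRUE))[[1]]
    if (!length(m))
      stop("TPS parse error at line ", i, ": expected 'LM3=<count>', got '", line, "'")
    k <- as.integer(m[2])
    if (i + k > n_lines)
      stop("TPS parse error at line ", i, ": record declares ", k,
           " landmarks but the file ends early")
    coords <- matrix(NA_real_, k, 3)
    for (j in seq_len(k)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + j]), "[ \t]+")[[1]]))
      if (length(vals) != 3L || anyNA(vals))
        stop("TPS parse error at line ", i + j,
             ": expected three numeric coordinates")
      coords[j, ] <- vals
    }
    i <- i + k + 1L
    id <- NA_character_
    while (i <= n_lines) {
      nxt <- trimws(lines[i])
      if (nxt == "") { i <- i + 1L; next }
      if (grepl("^ID=", nxt, ignore.case = TRUE)) {
        id <- sub("^ID=", "", nxt, ignore.case = TRUE); i <- i + 1L
      } else if (grepl("^(IMAGE|SCALE|CURVES|POINTS)=", nxt, ignore.case = TRUE)) {
        i <- i + 1L  # tolerated auxiliary keys
      } else break
    }
    configs[[length(configs) + 1L]] <- coords
    ids <- c(ids, id)
  }
  if (!length(configs)) stop("no TPS records found in ", path)
  ids[is.na(ids)] <- paste0("spec", which(is.na(ids)))
  ks <- vapply(configs, nrow, integer(1))
  bad <- which(ks != template$k)
  if (length(bad))
    stop("landmark-count mismatch with template '", template$name, "' (k=",
         template$k, ") for specimen(s): ",
         paste0(ids[bad], " (k=", ks[bad], ")", collapse = ", "))
  arr <- array(unlist(configs), dim = c(template$k, 3, length(configs)))
  landmark_set(arr, template, ids = ids)
}

#' Write a landmark dataset to a TPS file
#'
#' @param x A [landmark_set()] (non-empty).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tps <- function(x, path) {
  stopifnot(inherits(x, "landmark_set"))
  n <- n_specimens(x)
  if (n < 1L) stop("cannot write an empty landmark set")
  k <- x$template$k
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(sprintf("LM3=%d", k), con)
    writeLines(apply(x$coords[, , i, drop = FALSE], 1,
                     function(r) paste(sprintf("%.15g", r), collapse = " ")), con)
    writeLines(paste0("ID=", x$ids[i]), con)
  }
  invisible(path)
}

#' Read specimen metadata
#'
#' Reads a CSV with columns `specimen_id`, `sex` (one of F/M/U), `group`
#' and optionally `collection`.
#'
#' @param path CSV file path.
#' @return A data.frame with validated columns.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "sex", "group")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$specimen_id))
    stop("duplicated specimen_id in metadata")
  if (!all(meta$sex %in% c("F", "M", "U")))
    stop("sex must be one of F, M, U")
  meta
}

#' Read an observer sex-rating table
#'
#' CSV with columns `specimen_id`, `observer`, `round` (1 or 2) and
#' `rating` (F or M).
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_ratings <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "observer", "round", "rating")
  if (!all(need %in% names(r)))
    stop("rating table must have columns: ", paste(need, collapse = ", "))
  if (!all(r$round %in% c(1L, 2L))) stop("round must be 1 or 2")
  if (!all(r$rating %in% c("F", "M"))) stop("rating must be F or M")
  if (anyDuplicated(r[c("specimen_id", "observer", "round")]))
    stop("duplicate (specimen, observer, round) rows in rating table")
  r
}

#' Write / read landmark coordinates as wide CSV
#'
#' One specimen per row, columns `specimen_id, x1, y1, z1, x2, ...`.
#'
#' @param x A [landmark_set()].
#' @param path CSV path.
#' @return Invisibly, `path` (write) or a `landmark_set` (read).
#' @export
write_coords_csv <- function(x, path) {
  stopifnot(inherits(x, "landmark_set"))
  k <- x$template$k; n <- n_specimens(x)
  m <- t(apply(x$coords, 3, function(cfg) as.vector(t(cfg))))
  colnames(m) <- paste0(rep(c("x", "y", "z"), k), rep(seq_len(k), each = 3))
  utils::write.csv(data.frame(specimen_id = x$ids, m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coords_csv
#' @param template A [landmark_template()] for the read direction.
#' @export
read_coords_csv <- function(path, template) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(d)) stop("wide CSV needs a specimen_id column")
  m <- as.matrix(d[setdiff(names(d), "specimen_id")])
  if (ncol(m) != 3L * template$k)
    stop("wide CSV has ", ncol(m), " coordinate columns; template needs ",
         3L * template$k)
  arr <- array(NA_real_, c(template$k, 3, nrow(d)))
  for (i in seq_len(nrow(d))) arr[, , i] <- matrix(m[i, ], ncol = 3, byrow = TRUE)
  landmark_set(arr, template, ids = d$specimen_id)
}

#' Structural validation of a landmark dataset against its metadata
#'
#' Report-only checks: specimens with non-finite coordinates, exactly
#' coincident landmarks (within 1e-9 mm), missing metadata rows, and
#' specimens of unknown sex (`U`), which are retained in shape analyses but
#' excluded from classification-accuracy computations.
#'
#' @param x A [landmark_set()].
#' @param meta Metadata data.frame (see [read_metadata()]); optional.
#' @return A data.frame with columns `specimen_id` and `issue` (zero rows if
#'   clean); inputs are never modified.
#' @export
validate_dataset <- function(x, meta = NULL) {
  stopifnot(inherits(x, "landmark_set"))
  issues <- list()
  add <- function(id, what) issues[[length(issues) + 1L]] <<-
    data.frame(specimen_id = id, issue = what, stringsAsFactors = FALSE)
  for (i in seq_len(n_specimens(x))) {
    cfg <- x$coords[, , i]
    if (!all(is.finite(cfg))) add(x$ids[i], "non-finite coordinates")
    else {
      d <- stats::dist(cfg)
      if (any(d < 1e-9)) add(x$ids[i], "coincident landmarks")
    }
  }
  if (!is.null(meta)) {
    missing_meta <- setdiff(x$ids, meta$specimen_id)
    for (id in missing_meta) add(id, "missing metadata")
    u <- meta$specimen_id[meta$sex == "U" & meta$specimen_id %in% x$ids]
    for (id in u) add(id, "sex unknown: excluded from classification")
  }
  if (!length(issues))
    return(data.frame(specimen_id = character(0), issue = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
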