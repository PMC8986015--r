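#' Demo pipeline configuration on synthetic data
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_per_cell Specimens per (sex x group) cell.
#' @return A configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir, seed = 1L, n_per_cell = 12) {
  list(simulate = list(n_per_cell = n_per_cell,
                       groups = c("GroupA", "GroupB")),
       slide_iterations = 2,
       spaces = c("shape", "form"),
       n_perm = 199,
       alpha = 0.05,
       seed = as.integer(seed),
       out_dir = out_dir)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("pipeline config requires a seed")
  config$n_perm <- config$n_perm %||% 199
  config$alpha <- config$alpha %||% 0.05
  config$spaces <- config$spaces %||% c("shape", "form")
  config$slide_iterations <- config$slide_iterations %||% 3
  if (is.null(config$out_dir)) stop("pipeline config requires out_dir")
  config
}

#' Run the full sex-classification analysis pipeline
#'
#' Orchestrates the analysis graph: load (or simulate) landmark data and
#' metadata; slide semilandmarks and superimpose; PCA in shape and form
#' space with variance-explained regressions on lnCS, sex and group (a
#' Table-3-style layout); permutation test of the F vs M mean-shape
#' distance; linear measurements with univariate statistics and both
#' Cohen's D conventions (Table-4 style); leave-one-out LDA for shape PCs,
#' PCs + lnCS, lnCS alone and every linear measurement/index (Table-6
#' style), with ROC points and AUC per feature set; and a machine-readable
#' JSON manifest carrying the seed and all parameters.  All stochastic
#' stages derive their seeds from `config$seed`, so a rerun with the same
#' configuration reproduces every number.
#'
#' @param config A list or the path of a YAML file.  Fields: either
#'   `simulate` (a list of [population_spec()] arguments) or `input`
#'   (`tps` + `meta` file paths); optional `subset` (a template subset
#'   name); `slide_iterations`; `spaces`; `n_perm`; `alpha`; mandatory
#'   `seed` and `out_dir`.
#' @return Invisibly, a list with the fitted objects and the written file
#'   paths (`files`).
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  files <- character(0)
  out <- function(name) file.path(config$out_dir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- data -----------------------------------------------------------------
  dataset <- stage("data", {
    if (!is.null(config$simulate)) {
      spec <- do.call(population_spec, config$simulate)
      simulate_dataset(spec, seed = seed)
    } else if (!is.null(config$input)) {
      tplset <- make_template()
      set <- read_tps(config$input$tps, tplset$template)
      meta <- read_metadata(config$input$meta)
      list(data = set, meta = meta, truth = NULL)
    } else stop("config needs either 'simulate' or 'input'")
  })
  set <- dataset$data; meta <- dataset$meta
  if (!is.null(config$subset))
    set <- stage("subset", subset_landmarks(set, config$subset))
  validation <- validate_dataset(set, meta)

  # --- measurements (raw coordinates, before alignment) ---------------------
  measurements <- stage("measurements", measure_from_landmarks(set))

  # --- superimposition + sliding -------------------------------------------
  slid <- stage("slide",
                slide_semilandmarks(set, outer_iterations = config$slide_iterations))
  g <- slid$gpa
  sex <- meta$sex[match(g$ids, meta$specimen_id)]
  grp <- meta$group[match(g$ids, meta$specimen_id)]
  known <- sex %in% c("F", "M")

  # --- PCA + variance-explained regressions (Table 3 layout) ----------------
  pca_rows <- list(); reg_rows <- list()
  pcas <- list()
  for (space in config$spaces) {
    p <- stage(paste0("pca_", space), shape_pca(g, space = space))
    pcas[[space]] <- p
    pca_rows[[space]] <- data.frame(
      space = space, component = paste0("PC", 1:3),
      percent = round(p$percent[1:3], 1))
  }
  y <- flatten_coords(g$coords)
  preds <- list(lnCS = g$lnCS, sex = factor(sex), group = factor(grp))
  for (nm in names(preds)) {
    if (nm == "sex" && !all(known)) next
    if (is.factor(preds[[nm]]) && nlevels(preds[[nm]]) < 2L) next
    r <- stage(paste0("regress_", nm),
               variance_explained_regression(y, preds[[nm]]))
    reg_rows[[nm]] <- data.frame(predictor = nm,
                                 percent = round(r$percent, 1))
  }
  allo <- if (all(known))
    stage("allometry", allometry_corrected_sex_effect(g, sex = sex)) else NULL

  # --- permutation test + Procrustes ANOVA ----------------------------------
  perm <- NULL; panova <- NULL
  if (all(known) && length(unique(sex)) == 2L) {
    perm <- stage("permutation",
                  permutation_mean_difference(g, sex, n_perm = config$n_perm,
                                              seed = seed + 1L))
    anova_terms <- c("lnCS", "sex",
                     if (length(unique(grp)) > 1L) "group")
    panova <- stage("anova",
                    procrustes_anova(g, data.frame(lnCS = g$lnCS,
                                                   sex = factor(sex),
                                                   group = factor(grp)),
                                     terms = anova_terms,
                                     n_perm = config$n_perm,
                                     seed = seed + 2L))
  }

  # --- univariate statistics (Table 4 layout) -------------------------------
  meas_vars <- c("SW", "CW", "CD", "CBI", "CAI", "corpus_area")
  uni_rows <- lapply(meas_vars, function(v) {
    u <- ttest_and_effect(measurements[[v]][known], sex[known])
    data.frame(measurement = v,
               mean_F = u$group_stats$mean[1], mean_M = u$group_stats$mean[2],
               sd_F = u$group_stats$sd[1], sd_M = u$group_stats$sd[2],
               average_difference = u$average_difference,
               t = u$t_statistic, p = u$p_value,
               cohens_d_total = u$cohens_d_total,
               cohens_d_pooled = u$cohens_d_pooled)
  })
  univariate <- do.call(rbind, uni_rows)

  # --- classification (Table 6 layout) --------------------------------------
  cls_labels <- sex[known]
  shape_scores <- pcas[["shape"]]$scores[known, , drop = FALSE]
  sel <- stage("pc_selection",
               select_significant_pcs(shape_scores, cls_labels,
                                      alpha = config$alpha))
  feature_sets <- list()
  if (length(sel)) {
    feature_sets[["PC scores shape space"]] <-
      shape_scores[, sel, drop = FALSE]
    feature_sets[["PC scores shape space & lnCS"]] <-
      cbind(shape_scores[, sel, drop = FALSE], lnCS = g$lnCS[known])
  }
  feature_sets[["lnCS"]] <- matrix(g$lnCS[known], ncol = 1)
  for (v in meas_vars)
    feature_sets[[v]] <- matrix(measurements[[v]][known], ncol = 1)

  reports <- list(); cls_rows <- list(); roc_rows <- list()
  for (nm in names(feature_sets)) {
    rep_ <- stage(paste0("classify_", nm),
                  lda_loo_cv(feature_sets[[nm]], cls_labels,
                             ids = g$ids[known]))
    reports[[nm]] <- rep_
    cls_rows[[nm]] <- data.frame(
      features = nm, n = length(cls_labels),
      correct_F_pct = unname(rep_$per_class_percent["F"]),
      correct_M_pct = unname(rep_$per_class_percent["M"]),
      weighted_accuracy_pct = 100 * rep_$accuracy_weighted,
      auc = rep_$auc)
    roc_rows[[nm]] <- cbind(features = nm, rep_$roc)
  }
  classification <- do.call(rbind, cls_rows)
  roc_points <- do.call(rbind, roc_rows)

  # --- write the report bundle ----------------------------------------------
  wr <- function(obj, name) {
    utils::write.csv(obj, out(name), row.names = FALSE)
    files <<- c(files, out(name))
  }
  wr(do.call(rbind, pca_rows), "pca_variance.csv")
  if (length(reg_rows)) wr(do.call(rbind, reg_rows), "regression_variance.csv")
  wr(univariate, "univariate_stats.csv")
  wr(classification, "classification.csv")
  wr(roc_points, "roc_points.csv")
  if (!is.null(panova)) wr(as.data.frame(panova), "procrustes_anova.csv")
  if (nrow(validation)) wr(validation, "validation_issues.csv")
  write_tps(landmark_set(slid$coords, set$template, ids = g$ids),
            out("slid_aligned.tps"))
  files <- c(files, out("slid_aligned.tps"))

  manifest <- list(
    package = "morphosex",
    version = as.character(utils::packageVersion("morphosex")),
    seed = seed,
    parameters = config[setdiff(names(config), "out_dir")],
    n_specimens = n_specimens(set),
    n_landmarks = set$template$k,
    gpa = list(iterations = g$iterations, converged = g$converged),
    selected_pcs = as.integer(sel),
    permutation = if (!is.null(perm))
      list(observed = perm$observed, p = perm$p_value,
           n_perm = perm$n_perm, seed = seed + 1L),
    allometry_corrected_sex_percent =
      if (!is.null(allo)) allo$percent_of_total,
    files = basename(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, out("manifest.json"))

  invisible(list(data = set, meta = meta, slid = slid, gpa = g,
                 pca = pcas, univariate = univariate,
                 classification = classification, reports = reports,
                 permutation = perm, anova = panova, allometry = allo,
                 validation = validation, manifest = manifest,
                 files = files))
}
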