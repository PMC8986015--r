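#' Select principal components with a significant sex difference
#'
#' Tests every PC score column for a group mean difference between the two
#' sexes and returns the indices of the components with `p < alpha`, in PC
#' order.  This mirrors the common practice of restricting LDA features to
#' sex-informative components.  Note that selecting on the full sample
#' before cross-validation is optimistic; pair with `lda_loo_cv(...,
#' honest = TRUE)` features selected inside folds to quantify the optimism.
#'
#' @param scores A `shape_space` object or a numeric score matrix.
#' @param labels Two-level sex labels.
#' @param alpha Significance level (default 0.05).
#' @param method `"t"` (two-sided pooled-variance t-test, default) or
#'   `"wilcox"` (rank-sum).
#' @return Integer vector of selected column indices (possibly empty).
#' @export
select_significant_pcs <- function(scores, labels, alpha = 0.05,
                                   method = c("t", "wilcox")) {
  method <- match.arg(method)
  if (inherits(scores, "shape_space")) scores <- scores$scores
  scores <- as.matrix(scores)
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("exactly two groups are required")
  pvals <- apply(scores, 2, function(col) {
    if (method == "t")
      stats::t.test(col ~ labels, var.equal = TRUE)$p.value
    else
      suppressWarnings(stats::wilcox.test(col ~ labels)$p.value)
  })
  which(pvals < alpha)
}

resolve_priors <- function(priors, n_pos, n_neg) {
  if (is.character(priors)) {
    priors <- match.arg(priors, c("equal", "proportional"))
    if (priors == "equal") c(0.5, 0.5)
    else c(n_pos, n_neg) / (n_pos + n_neg)
  } else {
    priors <- as.numeric(priors)
    if (length(priors) != 2L || any(priors <= 0) ||
        abs(sum(priors) - 1) > 1e-8)
      stop("numeric priors must be two positives summing to 1")
    priors
  }
}

#' Two-group linear discriminant analysis
#'
#' Gaussian equal-covariance (Fisher) discriminant fitted from the group
#' means and the pooled covariance.  The discriminant score of a specimen x
#' is `w'(x - (m_pos + m_neg)/2) + log(prior_pos / prior_neg)` with
#' `w = S_pooled^{-1} (m_pos - m_neg)`; positive scores classify into the
#' positive class (females by default, which are represented by positive
#' values throughout).  A ridge fallback (`lambda = 1e-8 * trace(S)/p`)
#' handles numerically singular pooled covariances with a warning.
#'
#' @param x Feature matrix (n x p) or vector.
#' @param labels Two-level class labels.
#' @param priors `"equal"` (default), `"proportional"`, or a numeric pair
#'   (positive class first).
#' @param positive Label of the positive class (default `"F"`; falls back to
#'   the first sorted level if absent).
#' @param ridge Allow the ridge fallback for singular covariances.
#' @return Object of class `lda_model`: `weights`, `threshold` (the additive
#'   constant), `means`, `pooled_cov`, `priors`, `positive`, `negative`.
#' @export
lda_fit <- function(x, labels, priors = "equal", positive = "F",
                    ridge = TRUE) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes are required")
  if (!positive %in% lev) positive <- lev[1]
  negative <- setdiff(lev, positive)
  xp <- x[labels == positive, , drop = FALSE]
  xn <- x[labels == negative, , drop = FALSE]
  if (nrow(xp) < 2L || nrow(xn) < 2L)
    stop("each class needs at least 2 specimens")
  mp <- colMeans(xp); mn <- colMeans(xn)
  s <- ((nrow(xp) - 1) * stats::cov(xp) + (nrow(xn) - 1) * stats::cov(xn)) /
    (nrow(xp) + nrow(xn) - 2)
  pr <- resolve_priors(priors, nrow(xp), nrow(xn))
  w <- tryCatch(solve(s, mp - mn), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w))) {
    if (!ridge) stop("singular pooled covariance (enable ridge = TRUE)")
    lambda <- 1e-8 * sum(diag(s)) / ncol(x)
    warning("singular pooled covariance: ridge regularization applied")
    w <- solve(s + diag(lambda, ncol(x)), mp - mn)
  }
  threshold <- -sum(w * (mp + mn) / 2) + log(pr[1] / pr[2])
  structure(list(weights = w, threshold = threshold,
                 means = rbind(positive = mp, negative = mn),
                 pooled_cov = s, priors = pr,
                 positive = positive, negative = negative),
            class = "lda_model")
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  score <- drop(newdata %*% object$weights) + object$threshold
  data.frame(score = score,
             class = ifelse(score > 0, object$positive, object$negative),
             stringsAsFactors = FALSE)
}

#' Prevalence-weighted classification accuracy
#'
#' `sensitivity * prevalence + specificity * (1 - prevalence)`, where
#' sensitivity and specificity are the per-class correct rates of the
#' positive and negative class and `prevalence` is the positive-class
#' prevalence.  When `prevalence` equals the sample prevalence this is
#' exactly the raw proportion correct.
#'
#' @param sensitivity,specificity,prevalence Numerics in `[0, 1]`.
#' @return Numeric in `[0, 1]`.
#' @export
weighted_accuracy <- function(sensitivity, specificity, prevalence) {
  vals <- c(sensitivity, specificity, prevalence)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("all inputs must lie in [0, 1]")
  sensitivity * prevalence + specificity * (1 - prevalence)
}

#' ROC curve and rank-based AUC
#'
#' The ROC staircase over all score thresholds (midpoints between
#' consecutive distinct scores plus infinite endpoints; a specimen is
#' predicted positive when its score is at or above the threshold), and the
#' AUC computed as the two-sample rank-sum statistic — the probability that
#' a randomly chosen positive outranks a randomly chosen negative, ties
#' counted one half.  The trapezoidal area under the staircase equals the
#' rank AUC and is returned as an internal cross-check.
#'
#' @param scores Numeric scores (larger = more positive-like).
#' @param labels Class labels.
#' @param positive Positive-class label (default `"F"`).
#' @return List of class `roc_curve`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`), `auc` (rank statistic), `auc_trapezoid`, `positive`.
#' @export
roc_auc <- function(scores, labels, positive = "F") {
  labels <- as.character(labels)
  if (!positive %in% labels) stop("positive class absent from labels")
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_neg == 0L) stop("negative class absent from labels")
  r <- rank(scores)
  auc <- (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  uq <- sort(unique(scores), decreasing = TRUE)
  thresholds <- c(Inf, if (length(uq) > 1) (uq[-1] + uq[-length(uq)]) / 2,
                  -Inf)
  pts <- t(vapply(thresholds, function(th) {
    pred_pos <- scores >= th
    c(fpr = sum(pred_pos & !is_pos) / n_neg,
      tpr = sum(pred_pos & is_pos) / n_pos)
  }, numeric(2)))
  points <- data.frame(threshold = thresholds, fpr = pts[, "fpr"],
                       tpr = pts[, "tpr"])
  auc_trap <- sum(diff(points$fpr) *
                  (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, auc_trapezoid = auc_trap,
                 positive = positive),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f (positive class '%s', %d thresholds)\n",
              x$auc, x$positive, nrow(x$points)))
  invisible(x)
}

build_report <- function(truth, pred, scores, positive, negative,
                         prevalence = NULL, priors = NULL, cv = TRUE,
                         ids = NULL) {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred == negative)
  tn <- sum(truth == negative & pred == negative)
  fp <- sum(truth == negative & pred == positive)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  if (is.null(prevalence)) prevalence <- (tp + fn) / length(truth)
  roc <- roc_auc(scores, truth, positive = positive)
  per_class <- c(100 * sens, 100 * spec)
  names(per_class) <- c(positive, negative)
  structure(list(
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    sensitivity = sens, specificity = spec, precision = prec,
    prevalence = prevalence,
    accuracy_weighted = weighted_accuracy(sens, spec, prevalence),
    per_class_percent = per_class,
    predictions = data.frame(
      specimen_id = ids %||% seq_along(truth),
      truth = truth, predicted = pred, score = scores,
      cross_validated = cv, stringsAsFactors = FALSE),
    roc = roc$points, auc = roc$auc, positive = positive,
    priors = priors),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("classification_report (positive class '", x$positive, "')\n", sep = "")
  cat(sprintf("  correct: %s %.1f%% | %s %.1f%%; weighted accuracy %.1f%% (prevalence %.3f)\n",
              names(x$per_class_percent)[1], x$per_class_percent[1],
              names(x$per_class_percent)[2], x$per_class_percent[2],
              100 * x$accuracy_weighted, x$prevalence))
  cat(sprintf("  confusion TP=%d FP=%d TN=%d FN=%d; AUC = %.3f\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"], x$auc))
  invisible(x)
}

#' Leave-one-out cross-validated LDA
#'
#' Each specimen is predicted by a discriminant fitted on the remaining
#' n - 1 specimens; the report collects the cross-validated confusion
#' counts, per-class correct percentages, prevalence-weighted accuracy,
#' ROC points and AUC on the cross-validated scores, and the per-specimen
#' predictions.
#'
#' @inheritParams lda_fit
#' @param prevalence Positive-class prevalence used for the weighted
#'   accuracy; defaults to the sample prevalence (making the weighted
#'   accuracy equal to the raw proportion correct).
#' @param ids Optional specimen ids for the per-specimen table.
#' @return Object of class `classification_report`.
#' @export
lda_loo_cv <- function(x, labels, priors = "equal", positive = "F",
                       prevalence = NULL, ridge = TRUE, ids = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (n < 3L) stop("leave-one-out needs at least 3 specimens")
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes are required")
  if (!positive %in% lev) positive <- lev[1]
  negative <- setdiff(lev, positive)
  scores <- numeric(n); pred <- character(n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      lda_fit(x[-i, , drop = FALSE], labels[-i], priors = priors,
              positive = positive, ridge = ridge))
    pr <- predict(fit, x[i, , drop = FALSE])
    scores[i] <- pr$score; pred[i] <- pr$class
  }
  build_report(labels, pred, scores, positive, negative,
               prevalence = prevalence, priors = priors, cv = TRUE, ids = ids)
}

#' Box's M test for homogeneity of covariance matrices
#'
#' `M = (N - g) log|S_pooled| - sum_i (n_i - 1) log|S_i|`, with the standard
#' chi-square approximation `X2 = M (1 - c1)`,
#' `c1 = (2p^2 + 3p - 1) / (6 (p + 1)(g - 1)) * (sum_i 1/(n_i - 1) - 1/(N - g))`,
#' on `(g - 1) p (p + 1) / 2` degrees of freedom.
#'
#' @param x Feature matrix (n x p).
#' @param labels Group labels (>= 2 groups, each with n > p).
#' @return Object of class `boxm_result`: `M`, `chi_square`, `df`, `p_value`,
#'   `log_determinants` (per group and pooled).
#' @export
boxs_m <- function(x, labels) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels))
  g <- nlevels(labels); p <- ncol(x)
  if (g < 2L) stop("at least two groups are required")
  ns <- table(labels)
  if (any(ns <= p))
    stop("each group needs n > p observations for Box's M")
  n <- nrow(x)
  covs <- lapply(levels(labels), function(l) stats::cov(x[labels == l, , drop = FALSE]))
  pooled <- Reduce(`+`, Map(function(s, ni) (ni - 1) * s, covs, as.list(as.numeric(ns)))) /
    (n - g)
  logdets <- vapply(covs, function(s) determinant(s, logarithm = TRUE)$modulus[1],
                    numeric(1))
  logdet_pooled <- determinant(pooled, logarithm = TRUE)$modulus[1]
  m_stat <- (n - g) * logdet_pooled - sum((as.numeric(ns) - 1) * logdets)
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1)) *
    (sum(1 / (as.numeric(ns) - 1)) - 1 / (n - g))
  chi2 <- m_stat * (1 - c1)
  df <- (g - 1) * p * (p + 1) / 2
  structure(list(M = m_stat, chi_square = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 log_determinants = c(stats::setNames(logdets, levels(labels)),
                                      pooled = logdet_pooled)),
            class = "boxm_result")
}

#' @export
print.boxm_result <- function(x, ...) {
  cat(sprintf("Box's M = %.4f, X2 = %.4f on %d df, p = %.4g\n",
              x$M, x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Observer agreement and accuracy statistics for sex ratings
#'
#' From a long-format rating table (columns `specimen_id`, `observer`,
#' `round`, `rating`) computes: per-observer intra-observer agreement
#' (round 1 vs round 2, % identical), pairwise inter-observer disagreement
#' (round-1 ratings on shared specimens, % different), and — when `truth`
#' is supplied — each observer's round-1 per-class correct percentages and
#' prevalence-weighted accuracy.
#'
#' @param ratings data.frame as from [read_ratings()].
#' @param truth Optional data.frame with columns `specimen_id` and `sex`
#'   (F/M).
#' @param positive Positive class for the accuracy block (default `"F"`).
#' @return List with data.frames `intra_observer`, `inter_observer`,
#'   `accuracy` (NULL without truth).
#' @export
observer_agreement <- function(ratings, truth = NULL, positive = "F") {
  need <- c("specimen_id", "observer", "round", "rating")
  stopifnot(all(need %in% names(ratings)))
  obs <- sort(unique(ratings$observer))

  intra <- lapply(obs, function(o) {
    r1 <- ratings[ratings$observer == o & ratings$round == 1, ]
    r2 <- ratings[ratings$observer == o & ratings$round == 2, ]
    common <- intersect(r1$specimen_id, r2$specimen_id)
    if (!length(common)) {
      warning("observer ", o, " has a single round; intra-observer metric omitted")
      return(NULL)
    }
    agree <- r1$rating[match(common, r1$specimen_id)] ==
      r2$rating[match(common, r2$specimen_id)]
    data.frame(observer = o, n = length(common),
               intra_agreement_pct = 100 * mean(agree))
  })
  intra <- do.call(rbind, intra[!vapply(intra, is.null, logical(1))])

  inter <- NULL
  if (length(obs) >= 2L) {
    pairs <- utils::combn(obs, 2)
    inter <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- ratings[ratings$observer == pairs[1, j] & ratings$round == 1, ]
      b <- ratings[ratings$observer == pairs[2, j] & ratings$round == 1, ]
      common <- intersect(a$specimen_id, b$specimen_id)
      dis <- a$rating[match(common, a$specimen_id)] !=
        b$rating[match(common, b$specimen_id)]
      data.frame(observer_a = pairs[1, j], observer_b = pairs[2, j],
                 n = length(common), disagreement_pct = 100 * mean(dis))
    }))
  }

  acc <- NULL
  if (!is.null(truth)) {
    stopifnot(all(c("specimen_id", "sex") %in% names(truth)))
    acc <- do.call(rbind, lapply(obs, function(o) {
      r1 <- ratings[ratings$observer == o & ratings$round == 1, ]
      tr <- truth$sex[match(r1$specimen_id, truth$specimen_id)]
      keep <- tr %in% c("F", "M")
      r1 <- r1[keep, ]; tr <- tr[keep]
      neg <- setdiff(c("F", "M"), positive)
      sens <- mean(r1$rating[tr == positive] == positive)
      spec <- mean(r1$rating[tr == neg] == neg)
      prev <- mean(tr == positive)
      data.frame(observer = o, n = length(tr),
                 correct_pos_pct = 100 * sens, correct_neg_pct = 100 * spec,
                 weighted_accuracy_pct =
                   100 * weighted_accuracy(sens, spec, prev))
    }))
  }
  list(intra_observer = intra, inter_observer = inter, accuracy = acc)
}
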