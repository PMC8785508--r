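# Development/validation computations: Fisher-z sample size, Mann-Whitney
# AUC, nearest-to-ideal ROC cutoffs, cutoff derivation against CMDQ bands,
# R-squared comparison, and measurement-quality indices.

#' Fisher z-transform
#'
#' `w = 0.5 * log((1 + r) / (1 - r))`.
#'
#' @param r Correlation in (-1, 1).
#' @return Transformed value.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r) | abs(r) >= 1)) {
    stop("`r` must lie strictly inside (-1, 1)", call. = FALSE)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Minimum sample size for detecting a correlation
#'
#' Standard Fisher-z formula `n = ((z_alpha + z_beta) / w)^2 + 3`, where
#' `w` is the z-transformed minimum correlation of interest. With
#' `z_alpha = 1.96` (95% confidence), `z_beta = 1.29` (90% power) and
#' `w = 0.203` (r = 0.2 rounded to three decimals) this gives 259.
#'
#' @param r_min Minimum correlation to detect, in (0, 1).
#' @param z_alpha Two-sided confidence quantile; default 1.96.
#' @param z_beta Power quantile; default 1.29.
#' @param w Optional pre-computed z-transform of `r_min` (e.g. a rounded
#'   value); defaults to `fisher_z(r_min)`.
#' @return Integer sample size (rounded).
#' @examples
#' sample_size(0.2, w = 0.203)  # 259
#' @export
sample_size <- function(r_min, z_alpha = 1.96, z_beta = 1.29, w = NULL) {
  if (!is.numeric(r_min) || length(r_min) != 1 ||
      !is.finite(r_min) || r_min <= 0 || r_min >= 1) {
    stop("`r_min` must be a single value in (0, 1)", call. = FALSE)
  }
  w <- w %||% fisher_z(r_min)
  as.integer(round(((z_alpha + z_beta) / w)^2 + 3))
}

check_binary <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (any(!labels %in% c(0L, 1L))) {
    stop("`labels` must be binary (0/1)", call. = FALSE)
  }
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("both classes must be present (degenerate single-class labels)",
         call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("`scores` must be finite", call. = FALSE)
  labels
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counted half — computed from midranks, equivalent to the
#' normalized Wilcoxon statistic.
#'
#' @param scores Numeric predictor.
#' @param labels Binary outcome (0/1).
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(1, 3, 2, 4), c(0, 1, 0, 1))  # 0.75
#' @export
auc <- function(scores, labels) {
  labels <- check_binary(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' scores; a prediction is positive when `score >= threshold`. Sentinel
#' thresholds below and above the score range complete the curve at
#' (1, 1) and (0, 0) in (sensitivity, specificity) space.
#'
#' @param scores Numeric predictor.
#' @param labels Binary outcome (0/1).
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity` and `fpr`, ordered by increasing threshold.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_binary(scores, labels)
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  thr <- c(u[1] - 1, mids, u[length(u)] + 1)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), 0)
  data.frame(threshold = thr, sensitivity = sens, specificity = spec,
             fpr = 1 - spec)
}

#' Nearest-to-ideal ROC cutoff
#'
#' Selects the threshold minimizing the Euclidean distance to the ideal
#' corner (sensitivity = specificity = 1); ties broken toward the lower
#' cutoff. Youden's J (maximizing sensitivity + specificity - 1) is
#' available as an alternative.
#'
#' @param roc Data frame from [roc_points()], or a numeric score vector
#'   (then `labels` must be given).
#' @param labels Binary outcome, when `roc` is a score vector.
#' @param method `"closest"` (default) or `"youden"`.
#' @return List with `cutoff`, `sensitivity`, `specificity`.
#' @export
optimal_cutoff <- function(roc, labels = NULL,
                           method = c("closest", "youden")) {
  method <- match.arg(method)
  if (is.numeric(roc) && !is.null(labels)) roc <- roc_points(roc, labels)
  stopifnot(is.data.frame(roc),
            all(c("threshold", "sensitivity", "specificity") %in% names(roc)))
  # interior candidates only: the sentinel ends classify everything into
  # one class and are not usable cutoffs
  cand <- roc[is.finite(roc$threshold), , drop = FALSE]
  if (nrow(cand) > 2) cand <- cand[-c(1, nrow(cand)), , drop = FALSE]
  crit <- switch(method,
    closest = sqrt((1 - cand$sensitivity)^2 + (1 - cand$specificity)^2),
    youden = -(cand$sensitivity + cand$specificity - 1))
  best <- which(crit <= min(crit) + 1e-12)[1]  # ties -> lower cutoff
  list(cutoff = cand$threshold[best],
       sensitivity = cand$sensitivity[best],
       specificity = cand$specificity[best])
}

#' Derive MOREBA risk cutoffs from CMDQ outcomes
#'
#' Reproduces the cutoff-derivation procedure: for each CMDQ band boundary
#' the outcome is binarized (positive when the total reaches the boundary)
#' and the nearest-to-ideal ROC cutoff of the score is taken; the three
#' cutoffs must come out strictly increasing.
#'
#' @param scores MOREBA scores.
#' @param cmdq_totals CMDQ totals, same length.
#' @param boundaries CMDQ band boundaries; default `c(450, 900, 1350)`.
#' @param method Passed to [optimal_cutoff()].
#' @return A [moreba_thresholds()] object with attribute `operating`
#'   (per-boundary sensitivity/specificity/AUC).
#' @export
derive_thresholds <- function(scores, cmdq_totals,
                              boundaries = c(450, 900, 1350),
                              method = "closest") {
  if (length(scores) != length(cmdq_totals)) {
    stop("`scores` and `cmdq_totals` must have equal length", call. = FALSE)
  }
  if (length(unique(scores)) < 2) {
    stop("scores are constant; no discrimination possible", call. = FALSE)
  }
  ops <- lapply(boundaries, function(b) {
    labels <- as.integer(cmdq_totals >= b)
    if (sum(labels) == 0 || sum(labels) == length(labels)) {
      stop(sprintf(paste0("CMDQ boundary %g yields a single outcome class; ",
                          "cannot derive a cutoff for this band"), b),
           call. = FALSE)
    }
    c(optimal_cutoff(scores, labels, method = method),
      auc = auc(scores, labels))
  })
  cut <- vapply(ops, function(o) o$cutoff, 0)
  if (any(!is.finite(cut)) || is.unsorted(cut, strictly = TRUE)) {
    stop("derived cutoffs are not strictly increasing: ",
         paste(signif(cut, 6), collapse = ", "), call. = FALSE)
  }
  th <- moreba_thresholds(cut[1], cut[2], cut[3])
  attr(th, "operating") <- data.frame(
    boundary = boundaries,
    cutoff = cut,
    sensitivity = vapply(ops, function(o) o$sensitivity, 0),
    specificity = vapply(ops, function(o) o$specificity, 0),
    auc = vapply(ops, function(o) o$auc, 0))
  th
}

#' Coefficient of determination of a simple linear regression
#'
#' Squared Pearson correlation (identical to OLS R-squared with one
#' predictor). By convention 0, with a warning, when either variable has
#' zero variance.
#'
#' @param x Predictor.
#' @param y Response.
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero-variance input; returning R-squared of 0 by convention",
            call. = FALSE)
    return(0)
  }
  stats::cor(x, y)^2
}

#' Frequency distribution over the four risk levels
#'
#' @param levels Ordered factor of risk levels (as from [classify_risk()]
#'   or [reba_action_level()]) or integers 1-4 (as from [cmdq_band()]).
#' @return Data frame with columns `level`, `count`, `proportion`
#'   (proportions sum to 1; all-zero for empty input).
#' @export
risk_distribution <- function(levels) {
  lev <- risk_levels()
  if (is.numeric(levels)) {
    if (length(levels) && any(!levels %in% 1:4)) {
      stop("numeric levels must be integers 1-4", call. = FALSE)
    }
    levels <- factor(lev[levels], levels = lev, ordered = TRUE)
  }
  levels <- factor(levels, levels = lev, ordered = TRUE)
  n <- as.integer(table(levels))
  data.frame(level = lev, count = n,
             proportion = if (sum(n) > 0) n / sum(n) else rep(0, 4))
}

#' Measurement-quality indices from standardized loadings
#'
#' Average variance extracted, `AVE = mean(lambda^2)`, and composite
#' reliability, `CR = (sum lambda)^2 / ((sum lambda)^2 + sum(1 - lambda^2))`.
#' Conventional acceptability floors are 0.5 (AVE) and 0.7 (CR).
#'
#' @param loadings Numeric vector of standardized factor loadings in
#'   (0, 1].
#' @return List with `ave` and `composite_reliability`.
#' @examples
#' measurement_quality(default_direct_effects())
#' @export
measurement_quality <- function(loadings) {
  loadings <- unlist(loadings)
  if (any(!is.finite(loadings) | loadings <= 0 | loadings > 1)) {
    stop("loadings must lie in (0, 1]", call. = FALSE)
  }
  s <- sum(loadings)
  list(ave = mean(loadings^2),
       composite_reliability = s^2 / (s^2 + sum(1 - loadings^2)))
}
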