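# build a raw profile row; unnamed fields default to the rubric floor
make_profile <- function(..., n = 1) {
  base <- as.list(stats::setNames(rep(0, 16), moreba:::profile_columns()))
  base$posture_a <- 1
  base$posture_b <- 1
  override <- list(...)
  base[names(override)] <- override
  df <- as.data.frame(base)
  df[rep(1, n), , drop = FALSE]
}

# random valid profiles (posture_b kept <= 8 to stay in the observed range)
random_profiles <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(
    posture_a = sample(1:9, n, TRUE),
    posture_b = sample(1:8, n, TRUE))
  for (f in setdiff(moreba:::profile_columns(), c("posture_a", "posture_b"))) {
    df[[f]] <- sample(0:4, n, TRUE)
  }
  df
}

# printed coefficient table frozen for closure checks
printed_effects <- data.frame(
  factor = moreba_factors(),
  direct = c(0.937, 0.912, 0.743, 0.348, 0.840, 0.815, 0.747,
             0.748, 0.670, 0.751, 0.446, 0.328, 0.442, 0.614),
  indirect = c(0.734, 0.714, 0.582, 0.272, 0.658, 0.638, 0.585,
               0.586, 0.525, 0.588, 0.349, 0.257, 0.346, 0.481))

# exhaustive pairwise AUC oracle (ties counted half)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
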