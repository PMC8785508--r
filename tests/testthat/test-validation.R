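test_that("Fisher-z sample size reproduces the textbook values", {
  expect_equal(fisher_z(0.2), 0.20273, tolerance = 1e-4)
  expect_equal(sample_size(0.2, w = 0.203), 259L)
  expect_equal(sample_size(0.9), 8L)
  expect_error(sample_size(0), "r_min")
  expect_error(sample_size(1.1), "r_min")
  expect_error(fisher_z(1), "inside")
})

test_that("AUC equals the exhaustive pairwise oracle", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(c(1, 3, 2, 4), c(0, 1, 0, 1)), 1)   # positives dominate
  expect_equal(auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)  # constant score
  for (s in 1:25) {
    set.seed(s)
    n <- sample(4:12, 1)
    scores <- sample(1:6, n, TRUE)  # heavy ties
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    expect_equal(auc(scores, labels), auc_bruteforce(scores, labels))
  }
  expect_error(auc(1:4, c(1, 1, 1, 1)), "single-class")
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(99)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, plogis(scores))
  expect_equal(auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
})

test_that("ROC cutoff selection is nearest-to-ideal with low-tie-break", {
  scores <- c(1, 2, 3, 4, 5, 6)
  labels <- c(0, 0, 0, 1, 1, 1)
  opt <- optimal_cutoff(scores, labels)
  expect_equal(opt$cutoff, 3.5)  # perfect separation: sens = spec = 1
  expect_equal(opt$sensitivity, 1)
  expect_equal(opt$specificity, 1)
  # two-candidate curve, distances enumerated by hand:
  # scores 1,2,3 labels 0,1,1; cutoff 1.5 -> sens 1, spec 1 (dist 0);
  # cutoff 2.5 -> sens .5, spec 1 (dist .5)
  expect_equal(optimal_cutoff(c(1, 2, 3), c(0, 1, 1))$cutoff, 1.5)
  # cutoffs 1.5 and 3.5 tie at distance 0.5; the lower one wins
  expect_equal(optimal_cutoff(c(1, 2, 3, 4), c(0, 1, 0, 1))$cutoff, 1.5)
  expect_error(optimal_cutoff(1:4, c(0, 0, 0, 0)), "single-class")
  # Youden alternative agrees here
  expect_equal(optimal_cutoff(scores, labels, method = "youden")$cutoff, 3.5)
})

test_that("cutoff derivation recovers generating cluster boundaries", {
  set.seed(10)
  n <- 40
  score <- c(runif(n, 4, 6), runif(n, 14, 16), runif(n, 21, 23),
             runif(n, 29, 31))
  cmdq <- c(runif(n, 0, 400), runif(n, 500, 850), runif(n, 950, 1300),
            runif(n, 1400, 1600))
  th <- derive_thresholds(score, cmdq)
  expect_true(th[["low_moderate"]] > 6 && th[["low_moderate"]] < 14)
  expect_true(th[["moderate_high"]] > 16 && th[["moderate_high"]] < 21)
  expect_true(th[["high_very_high"]] > 23 && th[["high_very_high"]] < 29)
  op <- attr(th, "operating")
  expect_equal(op$sensitivity, rep(1, 3))
  expect_equal(op$auc, rep(1, 3))
})

test_that("degenerate cutoff derivations fail loudly", {
  expect_error(derive_thresholds(1:10, rep(100, 10)),
               "boundary 450")
  expect_error(derive_thresholds(rep(5, 10), seq(0, 1600, length.out = 10)),
               "constant")
})

test_that("R-squared matches lm() and handles zero variance", {
  x <- c(1, 2, 3, 4)
  expect_equal(r_squared(x, 2 * x + 1), 1)
  y <- c(2, 1, 4, 3)
  expect_equal(r_squared(x, y), summary(stats::lm(y ~ x))$r.squared)
  expect_equal(r_squared(x, y), 0.36)  # hand Pearson: cov 1, var 5/3 each
  expect_warning(r0 <- r_squared(x, rep(2, 4)), "zero-variance")
  expect_equal(r0, 0)
})

test_that("risk distributions count and normalize", {
  empty <- risk_distribution(classify_risk(numeric(0)))
  expect_equal(empty$count, rep(0L, 4))
  expect_equal(empty$proportion, rep(0, 4))
  all_low <- risk_distribution(classify_risk(rep(1.5, 5)))
  expect_equal(all_low$proportion, c(1, 0, 0, 0))
  mixed <- risk_distribution(c(1L, 1L, 2L, 4L))
  expect_equal(mixed$count, c(2L, 1L, 0L, 1L))
  expect_equal(sum(mixed$proportion), 1)
  expect_error(risk_distribution(5L), "1-4")
})

test_that("AVE and composite reliability follow their closed forms", {
  expect_equal(measurement_quality(rep(1, 5)),
               list(ave = 1, composite_reliability = 1))
  expect_equal(measurement_quality(0.6)$ave, 0.36)
  mq <- measurement_quality(default_direct_effects())
  # published rounded values 0.50 and 0.91; loadings are printed to 3 dp
  expect_lt(abs(mq$ave - 0.50), 0.03)
  expect_lt(abs(mq$composite_reliability - 0.91), 0.03)
  expect_error(measurement_quality(c(0.5, 1.2)), "loadings")
})
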