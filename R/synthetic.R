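# Synthetic worker cohorts: a Gaussian copula with the published
# inter-factor correlation structure, each margin discretized onto its
# integer rating scale, plus a latent-strain CMDQ outcome model.

#' Default factor marginals of the development cohort
#'
#' Mean, standard deviation and integer range of each of the 14 factors as
#' observed in the 300-worker development cohort (posture group B was
#' observed only up to 8 although the REBA table can emit 9).
#'
#' @return Data frame with columns `factor`, `mean`, `sd`, `lo`, `hi`.
#' @export
default_marginals <- function() {
  data.frame(
    factor = moreba_factors(),
    mean = c(4.76, 4.66, 1.29, 0.52, 0.94, 1.27, 2.29,
             2.09, 1.24, 1.14, 1.14, 1.01, 1.24, 2.78),
    sd = c(1.93, 2.02, 1.28, 0.28, 0.69, 1.20, 1.06,
           1.19, 1.21, 0.98, 0.65, 0.47, 1.15, 0.77),
    lo = c(1, 1, rep(0, 12)),
    hi = c(9, 8, rep(4, 12)))
}

#' Default inter-factor correlation matrix
#'
#' Pearson correlations among the 14 factors as observed in the
#' development cohort (the occupational block of the published matrix).
#'
#' @return Symmetric 14 x 14 matrix with unit diagonal.
#' @export
default_correlation <- function() {
  f <- moreba_factors()
  low <- list(
    c(0.843),
    c(0.698, 0.734),
    c(0.327, 0.301, 0.119),
    c(0.760, 0.793, 0.590, 0.315),
    c(0.746, 0.765, 0.583, 0.281, 0.695),
    c(0.653, 0.705, 0.523, 0.364, 0.646, 0.600),
    c(0.687, 0.727, 0.512, 0.361, 0.589, 0.606, 0.581),
    c(0.610, 0.635, 0.450, 0.224, 0.580, 0.536, 0.517, 0.491),
    c(0.703, 0.692, 0.506, 0.290, 0.673, 0.633, 0.587, 0.531, 0.483),
    c(0.397, 0.404, 0.325, 0.143, 0.383, 0.387, 0.353, 0.325, 0.291, 0.280),
    c(0.260, 0.357, 0.257, 0.076, 0.298, 0.260, 0.191, 0.184, 0.165, 0.273,
      0.192),
    c(0.394, 0.394, 0.368, 0.103, 0.383, 0.319, 0.343, 0.281, 0.297, 0.316,
      0.333, 0.173),
    c(0.550, 0.572, 0.440, 0.203, 0.501, 0.534, 0.442, 0.526, 0.438, 0.458,
      0.504, 0.175, 0.333))
  R <- diag(14)
  dimnames(R) <- list(f, f)
  for (i in 2:14) {
    R[i, 1:(i - 1)] <- low[[i - 1]]
    R[1:(i - 1), i] <- low[[i - 1]]
  }
  R
}

#' Repair a correlation matrix to the nearest positive semi-definite one
#'
#' Eigenvalue clipping: negative eigenvalues are raised to a small positive
#' floor and the matrix is rescaled back to unit diagonal. Intended to
#' absorb the slight indefiniteness a rounded, hand-typed correlation
#' matrix can carry; a matrix that is badly indefinite is rejected.
#'
#' @param mat Symmetric matrix with unit diagonal.
#' @param repair_limit Most negative eigenvalue that will be repaired
#'   rather than rejected (default -0.05).
#' @return Positive semi-definite correlation matrix.
#' @export
nearest_psd <- function(mat, repair_limit = -0.05) {
  if (!isSymmetric(unname(mat), tol = 1e-8)) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(mat) - 1) > 1e-8)) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  e <- eigen(mat, symmetric = TRUE)
  lam <- e$values
  if (min(lam) >= -1e-10) return(mat)
  if (min(lam) < repair_limit) {
    stop(sprintf(paste0("correlation matrix is not positive semi-definite ",
                        "beyond repair tolerance (smallest eigenvalue %.4f)"),
                 min(lam)), call. = FALSE)
  }
  lam <- pmax(lam, 1e-8)
  m <- e$vectors %*% diag(lam) %*% t(e$vectors)
  m <- stats::cov2cor(m)
  dimnames(m) <- dimnames(mat)
  (m + t(m)) / 2
}

#' Specification of a synthetic worker cohort
#'
#' Defaults emulate the development cohort: marginal means/SDs and ranges
#' from [default_marginals()], latent correlation from
#' [default_correlation()], and a CMDQ outcome calibrated so that the
#' MOREBA score explains `target_r2` of its variance before flooring.
#'
#' @param n Number of workers.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param marginals Data frame as returned by [default_marginals()].
#' @param correlation Latent 14 x 14 correlation matrix.
#' @param target_r2 Fraction of outcome variance explained by the score in
#'   the generating model; default 0.67.
#' @param outcome_mean,outcome_sd Target CMDQ mean and SD; defaults 536.82
#'   and 511.51.
#' @param floor_at_zero Floor generated CMDQ values at 0 (the instrument's
#'   minimum); default `TRUE`.
#' @param inflate_latent Iteratively pre-inflate the latent correlations to
#'   compensate for discretization attenuation; off by default.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n = 300, seed = NULL,
                            marginals = default_marginals(),
                            correlation = default_correlation(),
                            target_r2 = 0.67,
                            outcome_mean = 536.82, outcome_sd = 511.51,
                            floor_at_zero = TRUE, inflate_latent = FALSE) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 0, n == round(n))
  if (!is.numeric(target_r2) || target_r2 <= 0 || target_r2 > 1) {
    stop("`target_r2` must lie in (0, 1]", call. = FALSE)
  }
  need <- c("factor", "mean", "sd", "lo", "hi")
  if (!is.data.frame(marginals) || !all(need %in% names(marginals))) {
    stop("`marginals` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  check_factor_names(marginals$factor)
  marginals <- marginals[match(moreba_factors(), marginals$factor), ]
  if (!identical(dim(correlation), c(14L, 14L))) {
    stop("`correlation` must be 14 x 14", call. = FALSE)
  }
  correlation <- nearest_psd(correlation)
  structure(
    list(n = as.integer(n), seed = seed, marginals = marginals,
         correlation = correlation, target_r2 = target_r2,
         outcome_mean = outcome_mean, outcome_sd = outcome_sd,
         floor_at_zero = isTRUE(floor_at_zero),
         inflate_latent = isTRUE(inflate_latent)),
    class = "population_spec")
}

# cell probabilities of the discretized truncated normal on lo..hi
cell_probs <- function(mu, sd, lo, hi) {
  ks <- lo:hi
  up <- stats::pnorm(ks + 0.5, mu, sd)
  lw <- stats::pnorm(ks - 0.5, mu, sd)
  up[length(ks)] <- 1
  lw[1] <- 0
  p <- up - lw
  p / sum(p)
}

# latent location such that the discretized margin has the target mean
match_location <- function(target_mean, sd, lo, hi) {
  if (target_mean <= lo || target_mean >= hi) {
    stop("marginal mean must lie strictly inside its integer range",
         call. = FALSE)
  }
  f <- function(mu) sum((lo:hi) * cell_probs(mu, sd, lo, hi)) - target_mean
  stats::uniroot(f, lower = lo - 6 * sd, upper = hi + 6 * sd,
                 tol = 1e-10)$root
}

# draw the integer factor matrix (n x 14) from the Gaussian copula
draw_factors <- function(spec) {
  m <- spec$marginals
  R <- spec$correlation
  if (spec$inflate_latent) R <- inflate_correlation(spec)
  L <- chol(R + diag(1e-10, 14))
  Z <- matrix(stats::rnorm(spec$n * 14), spec$n, 14) %*% L
  U <- stats::pnorm(Z)
  X <- matrix(0L, spec$n, 14, dimnames = list(NULL, moreba_factors()))
  for (j in seq_len(14)) {
    mu <- match_location(m$mean[j], m$sd[j], m$lo[j], m$hi[j])
    p <- cell_probs(mu, m$sd[j], m$lo[j], m$hi[j])
    X[, j] <- m$lo[j] +
      findInterval(U[, j], cumsum(p)[-length(p)], left.open = TRUE)
  }
  X
}

# crude iterative attenuation compensation on the latent scale
inflate_correlation <- function(spec, iter = 4, n_cal = 20000) {
  target <- spec$correlation
  latent <- target
  cal <- spec
  cal$inflate_latent <- FALSE
  cal$n <- n_cal
  for (k in seq_len(iter)) {
    cal$correlation <- nearest_psd(latent, repair_limit = -1)
    X <- draw_factors(cal)
    obs <- stats::cor(X)
    latent <- latent + (target - obs)
    latent[latent > 0.999] <- 0.999
    latent[latent < -0.999] <- -0.999
    diag(latent) <- 1
  }
  nearest_psd(latent, repair_limit = -1)
}

#' Generate synthetic worker exposure profiles
#'
#' Draws latent multivariate-normal scores with the spec's correlation
#' matrix, maps each margin onto its integer rating scale by quantile
#' discretization against a truncated normal whose location is
#' moment-matched to the target mean, then decomposes the load and force
#' factors into raw components (carry/work time pegged at the top rating
#' whenever the factor is non-zero, so the sub-score reproduces the drawn
#' factor value exactly).
#'
#' @param spec A [population_spec()].
#' @return Data frame of `spec$n` raw profiles (16 columns plus
#'   `worker_id`) suitable for [moreba_score()].
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  generate_profiles_impl(spec)
}

generate_profiles_impl <- function(spec) {
  if (spec$n == 0) {
    X <- matrix(integer(0), 0, 14, dimnames = list(NULL, moreba_factors()))
  } else {
    X <- draw_factors(spec)
  }
  df <- as.data.frame(X[, setdiff(moreba_factors(), c("load", "force")),
                        drop = FALSE])
  df$load_weight <- as.integer(X[, "load"])
  df$load_time <- ifelse(df$load_weight > 0, 4L, 0L)
  df$force_value <- as.integer(X[, "force"])
  df$work_time <- ifelse(df$force_value > 0, 4L, 0L)
  cbind(worker_id = seq_len(spec$n), df[, profile_columns()])
}

#' Residual noise SD for a target coefficient of determination
#'
#' Closed form: with outcome `y = a + b * s + e`, the infinite-sample OLS
#' R-squared equals `target_r2` exactly when
#' `sd(e) = sqrt(b^2 * var(s) * (1 - R2) / R2)`.
#'
#' @param score_variance Variance of the score `s`.
#' @param target_r2 Desired R-squared in (0, 1].
#' @param slope Regression slope `b`; default 1.
#' @return Residual standard deviation.
#' @examples
#' calibrate_outcome(1, 0.5)   # 1
#' calibrate_outcome(1, 1.0)   # 0
#' @export
calibrate_outcome <- function(score_variance, target_r2, slope = 1) {
  if (!is.numeric(target_r2) || target_r2 <= 0 || target_r2 > 1) {
    stop("`target_r2` must lie in (0, 1]", call. = FALSE)
  }
  if (score_variance < 0) stop("`score_variance` must be >= 0", call. = FALSE)
  sqrt(slope^2 * score_variance * (1 - target_r2) / target_r2)
}

#' Generate CMDQ outcomes from a latent-strain model
#'
#' The MOREBA score acts as the latent strain; the outcome is an affine
#' function of it plus Gaussian noise, with slope and intercept chosen to
#' hit the spec's outcome mean/SD and noise calibrated via
#' [calibrate_outcome()] so the score explains `target_r2` of the outcome
#' variance (before flooring). Negative values are floored at 0 when
#' `spec$floor_at_zero` is set.
#'
#' @param profiles Raw profile data frame.
#' @param weights A `moreba_weights` object.
#' @param spec A [population_spec()].
#' @param seed Optional integer seed (set `NULL` to continue the current
#'   RNG stream).
#' @param slope Override the auto-calibrated slope (e.g. 0 to sever the
#'   score-outcome link).
#' @return Numeric vector of synthetic CMDQ totals.
#' @export
generate_cmdq <- function(profiles, weights = moreba_weights(), spec,
                          seed = NULL, slope = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  generate_cmdq_impl(profiles, weights, spec, slope)
}

generate_cmdq_impl <- function(profiles, weights, spec, slope = NULL) {
  s <- moreba_score(profiles, weights)
  if (length(s) == 0) return(numeric(0))
  v <- stats::var(s)
  if (!is.finite(v) || v == 0) {
    stop("score variance is zero; cannot calibrate the outcome model",
         call. = FALSE)
  }
  b_cal <- spec$outcome_sd * sqrt(spec$target_r2) / sqrt(v)
  b <- slope %||% b_cal
  a <- spec$outcome_mean - b * mean(s)
  # noise stays at the calibrated magnitude even when the slope is
  # overridden, so slope = 0 gives pure noise rather than a constant
  sde <- calibrate_outcome(v, spec$target_r2, b_cal)
  y <- a + b * s + stats::rnorm(length(s), 0, sde)
  if (spec$floor_at_zero) y <- pmax(y, 0)
  y
}

#' Simulate a full cohort (profiles plus CMDQ outcome)
#'
#' Seeds the RNG once from `spec$seed` and draws profiles and outcomes in
#' one stream, so a given spec is bit-for-bit reproducible.
#'
#' @param spec A [population_spec()].
#' @param weights A `moreba_weights` object.
#' @return Profile data frame with an additional `cmdq_total` column.
#' @export
simulate_cohort <- function(spec, weights = moreba_weights()) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  profiles <- generate_profiles_impl(spec)
  profiles$cmdq_total <- generate_cmdq_impl(profiles, weights, spec)
  profiles
}
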