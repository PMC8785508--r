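# raw profile columns: the two REBA posture table scores, ten 0-4 Likert
# ratings, and the four components of the load and force sub-scores
profile_columns <- function() {
  c("posture_a", "posture_b", "coupling", "contact_stress",
    "static_activity", "repetitive_activity", "rapid_movement",
    "throwing_motion", "hand_arm_vibration", "whole_body_vibration",
    "air_temperature", "work_rest_cycle",
    "load_weight", "load_time", "force_value", "work_time")
}

check_ordinal <- function(x, field, lo, hi, row = NULL) {
  bad <- !is.finite(x) | x != round(x) | x < lo | x > hi
  if (any(bad)) {
    where <- if (is.null(row)) which(bad) else row[bad]
    stop(sprintf("`%s` must be an integer in %d..%d (row %s has %s)",
                 field, lo, hi, where[1],
                 format(x[bad][1])), call. = FALSE)
  }
  invisible(x)
}

#' Load sub-score
#'
#' Combines the load-carrying time rating and the maximum load weight
#' rating (both 0-4 Likert scores) into the load factor entering the MOREBA
#' equation: `L = (t_L * W_L) / 4`, so that load only contributes when a
#' non-trivial weight is carried for a non-trivial time.
#'
#' @param load_time Load-carrying time score, integer 0-4
#'   (0 never ... 4 more than 6 h).
#' @param load_weight Maximum load weight score, integer 0-4
#'   (0 under 5 kg ... 4 over 20 kg).
#' @return Numeric in \[0, 4\].
#' @examples
#' load_subscore(2, 3)  # 1.5
#' @export
load_subscore <- function(load_time, load_weight) {
  check_ordinal(load_time, "load_time", 0, 4)
  check_ordinal(load_weight, "load_weight", 0, 4)
  (load_time * load_weight) / 4
}

#' Force sub-score
#'
#' Combines the work time rating and the maximum force value rating into
#' the force factor of the MOREBA equation: `F = (t_w * V_F) / 4`.
#'
#' Note the work-time rubric: 0 under 2 h, 1 for 2-4 h, 2 for 4-6 h, 3 for
#' 6-8 h, 4 over 8 h.
#'
#' @param work_time Work time score, integer 0-4.
#' @param force_value Maximum force value score, integer 0-4
#'   (0 under 1 kg ... 4 over 6 kg).
#' @return Numeric in \[0, 4\].
#' @examples
#' force_subscore(3, 2)  # 1.5
#' @export
force_subscore <- function(work_time, force_value) {
  check_ordinal(work_time, "work_time", 0, 4)
  check_ordinal(force_value, "force_value", 0, 4)
  (work_time * force_value) / 4
}

# validate a raw profile data frame; returns it invisibly
validate_profiles <- function(profiles) {
  if (!is.data.frame(profiles)) {
    stop("`profiles` must be a data frame", call. = FALSE)
  }
  missing <- setdiff(profile_columns(), names(profiles))
  if (length(missing)) {
    stop("profile data is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(profiles) == 0) return(invisible(profiles))
  row <- seq_len(nrow(profiles))
  check_ordinal(profiles$posture_a, "posture_a", 1, 9, row)
  check_ordinal(profiles$posture_b, "posture_b", 1, 9, row)
  if (any(profiles$posture_b > 8)) {
    warning("posture_b of 9 is above the range observed in the ",
            "development cohort (1-8); the REBA table itself can emit 9",
            call. = FALSE)
  }
  for (f in setdiff(profile_columns(), c("posture_a", "posture_b"))) {
    check_ordinal(profiles[[f]], f, 0, 4, row)
  }
  invisible(profiles)
}

# 16 raw columns -> 14 factor values (matrix, equation order)
factor_matrix <- function(profiles) {
  validate_profiles(profiles)
  m <- cbind(
    posture_a = as.numeric(profiles$posture_a),
    posture_b = as.numeric(profiles$posture_b),
    coupling = as.numeric(profiles$coupling),
    contact_stress = as.numeric(profiles$contact_stress),
    load = load_subscore(profiles$load_time, profiles$load_weight),
    force = force_subscore(profiles$work_time, profiles$force_value),
    static_activity = as.numeric(profiles$static_activity),
    repetitive_activity = as.numeric(profiles$repetitive_activity),
    rapid_movement = as.numeric(profiles$rapid_movement),
    throwing_motion = as.numeric(profiles$throwing_motion),
    hand_arm_vibration = as.numeric(profiles$hand_arm_vibration),
    whole_body_vibration = as.numeric(profiles$whole_body_vibration),
    air_temperature = as.numeric(profiles$air_temperature),
    work_rest_cycle = as.numeric(profiles$work_rest_cycle))
  m[, moreba_factors(), drop = FALSE]
}

#' MOREBA score
#'
#' Weighted sum of the 14 factor values: the two REBA posture table scores,
#' the ten 0-4 Likert ratings, and the load and force sub-scores computed
#' internally from their raw components. With the default weights the score
#' of a valid profile lies in \[1.448, 36.5\].
#'
#' @param profiles Data frame with the 16 raw columns listed in
#'   [read_profiles()]; one row per worker.
#' @param weights A `moreba_weights` object; default [moreba_weights()].
#' @return Numeric vector of scores, one per row.
#' @examples
#' p <- data.frame(posture_a = 1, posture_b = 1, coupling = 0,
#'                 contact_stress = 0, static_activity = 0,
#'                 repetitive_activity = 0, rapid_movement = 0,
#'                 throwing_motion = 0, hand_arm_vibration = 0,
#'                 whole_body_vibration = 0, air_temperature = 0,
#'                 work_rest_cycle = 0, load_weight = 0, load_time = 0,
#'                 force_value = 0, work_time = 0)
#' moreba_score(p)  # 1.448
#' @export
moreba_score <- function(profiles, weights = moreba_weights()) {
  if (!inherits(weights, "moreba_weights")) {
    stop("`weights` must be a `moreba_weights` object", call. = FALSE)
  }
  w <- weights$indirect_effects[moreba_factors()]
  if (any(!is.finite(w))) stop("non-finite weight(s)", call. = FALSE)
  drop(factor_matrix(profiles) %*% w)
}

#' Risk level cutoffs for the MOREBA score
#'
#' The three score cutoffs partitioning MOREBA scores into four risk
#' levels. Defaults are the published ROC-derived optimal cutoff points.
#'
#' @param low_moderate,moderate_high,high_very_high Strictly increasing
#'   cutoffs; defaults 12.37, 16.51, 24.35.
#' @return An object of class `moreba_thresholds` (named numeric length 3).
#' @export
moreba_thresholds <- function(low_moderate = 12.37, moderate_high = 16.51,
                              high_very_high = 24.35) {
  x <- c(low_moderate = low_moderate, moderate_high = moderate_high,
         high_very_high = high_very_high)
  if (any(!is.finite(x)) || is.unsorted(x, strictly = TRUE)) {
    stop("thresholds must be finite and strictly increasing", call. = FALSE)
  }
  structure(x, class = "moreba_thresholds")
}

#' Classify a MOREBA score into a risk level
#'
#' The published cutoff table gives "moderate 12.37 to 16.50" and
#' "high 16.51 to 24.35"; for continuous scores the partition is realized
#' as: low below the first cutoff, moderate in \[12.37, 16.51), high in
#' \[16.51, 24.35\], very high above 24.35 — total and disjoint over the
#' real line.
#'
#' @param score Numeric vector of MOREBA scores (finite).
#' @param thresholds A [moreba_thresholds()] object.
#' @return Ordered factor with levels [risk_levels()].
#' @examples
#' classify_risk(c(10, 16.51, 24.36))
#' @export
classify_risk <- function(score, thresholds = moreba_thresholds()) {
  if (!inherits(thresholds, "moreba_thresholds")) {
    thresholds <- do.call(moreba_thresholds, as.list(thresholds))
  }
  if (any(!is.finite(score))) {
    stop("`score` must be finite (NaN/NA/Inf not classifiable)", call. = FALSE)
  }
  lev <- risk_levels()
  out <- ifelse(score < thresholds[["low_moderate"]], lev[1],
         ifelse(score < thresholds[["moderate_high"]], lev[2],
         ifelse(score <= thresholds[["high_very_high"]], lev[3], lev[4])))
  factor(out, levels = lev, ordered = TRUE)
}
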