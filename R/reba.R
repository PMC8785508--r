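# Classic REBA scoring. The three lookup tables ship as plain-text CSV
# fixtures under inst/extdata (transcribed from the original REBA
# publication) and are cached per session.

reba_env <- new.env(parent = emptyenv())

reba_table <- function(which) {
  key <- paste0("table_", which)
  if (is.null(reba_env[[key]])) {
    path <- system.file("extdata", paste0("reba_table_", which, ".csv"),
                        package = "moreba")
    reba_env[[key]] <- utils::read.csv(path, comment.char = "#")
  }
  reba_env[[key]]
}

lookup_cells <- function(tab, idx, joints) {
  for (j in joints) {
    check_ordinal(idx[[j]], j, min(tab[[j]]), max(tab[[j]]))
  }
  key <- do.call(paste, c(tab[joints], sep = "\r"))
  query <- do.call(paste, c(idx[joints], sep = "\r"))
  tab$score[match(query, key)]
}

#' REBA table A score (trunk, neck, legs)
#'
#' @param trunk Trunk posture score, 1-5.
#' @param neck Neck posture score, 1-3.
#' @param legs Legs posture score, 1-4.
#' @return Integer score 1-9.
#' @export
reba_table_a <- function(trunk, neck, legs) {
  lookup_cells(reba_table("a"),
               list(trunk = trunk, neck = neck, legs = legs),
               c("trunk", "neck", "legs"))
}

#' REBA table B score (upper arm, lower arm, wrist)
#'
#' @param upper_arm Upper arm posture score, 1-6.
#' @param lower_arm Lower arm posture score, 1-2.
#' @param wrist Wrist posture score, 1-3.
#' @return Integer score 1-9.
#' @export
reba_table_b <- function(upper_arm, lower_arm, wrist) {
  lookup_cells(reba_table("b"),
               list(upper_arm = upper_arm, lower_arm = lower_arm,
                    wrist = wrist),
               c("upper_arm", "lower_arm", "wrist"))
}

#' REBA table C score
#'
#' Combines score A (table A plus load/force, 1-12) and score B (table B
#' plus coupling, 1-12).
#'
#' @param score_a,score_b Integers 1-12.
#' @return Integer score 1-12.
#' @export
reba_table_c <- function(score_a, score_b) {
  lookup_cells(reba_table("c"),
               list(score_a = score_a, score_b = score_b),
               c("score_a", "score_b"))
}

#' Classic REBA final score
#'
#' Full REBA scoring chain: table A plus the load/force adjustment gives
#' score A; table B plus the coupling adjustment gives score B; table C
#' combines them; the activity adjustment is added on top.
#'
#' @param observations Data frame with columns `trunk` (1-5), `neck` (1-3),
#'   `legs` (1-4), `upper_arm` (1-6), `lower_arm` (1-2), `wrist` (1-3),
#'   `load_force` (0-3), `coupling` (0-3), `activity` (0-3).
#' @return Data frame with columns `score_a`, `score_b`, `score_c` and
#'   `reba` (the final score, 1-15).
#' @examples
#' obs <- data.frame(trunk = 3, neck = 2, legs = 2, upper_arm = 4,
#'                   lower_arm = 2, wrist = 2, load_force = 1,
#'                   coupling = 2, activity = 1)
#' reba_score(obs)
#' @export
reba_score <- function(observations) {
  need <- c("trunk", "neck", "legs", "upper_arm", "lower_arm", "wrist",
            "load_force", "coupling", "activity")
  missing <- setdiff(need, names(observations))
  if (length(missing)) {
    stop("observation data is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (adj in c("load_force", "coupling", "activity")) {
    check_ordinal(observations[[adj]], adj, 0, 3)
  }
  a <- reba_table_a(observations$trunk, observations$neck, observations$legs)
  b <- reba_table_b(observations$upper_arm, observations$lower_arm,
                    observations$wrist)
  score_a <- a + observations$load_force
  score_b <- b + observations$coupling
  score_c <- reba_table_c(score_a, score_b)
  data.frame(score_a = score_a, score_b = score_b, score_c = score_c,
             reba = score_c + observations$activity)
}

#' Condense a REBA final score to four risk levels
#'
#' REBA's published action levels are five (negligible, low, medium, high,
#' very high, at scores 1, 2-3, 4-7, 8-10, 11-15). For side-by-side
#' comparison with four-level classifications the two lowest are merged by
#' default; the breakpoints are configurable.
#'
#' @param final Integer REBA final score(s), 1-15.
#' @param breaks Three increasing upper bounds of the first three levels;
#'   default `c(3, 7, 10)` (so 1-3 low, 4-7 moderate, 8-10 high, 11-15
#'   very high).
#' @return Ordered factor with levels [risk_levels()].
#' @export
reba_action_level <- function(final, breaks = c(3, 7, 10)) {
  check_ordinal(final, "final", 1, 15)
  if (length(breaks) != 3 || is.unsorted(breaks, strictly = TRUE)) {
    stop("`breaks` must be three strictly increasing values", call. = FALSE)
  }
  lev <- risk_levels()
  idx <- findInterval(final, breaks + 0.5) + 1L
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Approximate classic REBA from a MOREBA factor profile
#'
#' When only the 16-column factor profile is available (as for synthetic
#' cohorts), classic REBA is reconstructed from it: the posture table
#' scores are used directly as the table A/B outputs, the REBA load/force
#' adjustment is mapped from the maximum load weight rating (under 5 kg ->
#' 0, 5-10 kg -> 1, over 10 kg -> 2, plus 1 for frequent rapid or sudden
#' movement as shock), coupling is capped at 3, and the activity adjustment
#' adds one point each for marked static, repetitive, or rapid activity.
#'
#' @param profiles Data frame of raw factor profiles (see
#'   [read_profiles()]).
#' @return Integer vector of REBA final scores (1-15).
#' @export
reba_from_profile <- function(profiles) {
  validate_profiles(profiles)
  if (nrow(profiles) == 0) return(integer(0))
  load_force <- pmin(ifelse(profiles$load_weight >= 2, 2,
                            profiles$load_weight) +
                       (profiles$rapid_movement >= 3), 3)
  coupling <- pmin(profiles$coupling, 3)
  activity <- (profiles$static_activity >= 2) +
    (profiles$repetitive_activity >= 2) + (profiles$rapid_movement >= 2)
  score_a <- profiles$posture_a + load_force
  score_b <- profiles$posture_b + coupling
  reba_table_c(score_a, score_b) + activity
}
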