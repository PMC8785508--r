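# CSV/JSON input-output and the end-to-end validation pipeline.
# CSV dialect is fixed: comma-separated, UTF-8, "." decimal mark; lines
# starting with "#" are metadata headers.

#' Read worker exposure profiles from CSV
#'
#' Expects one row per worker and the 16 raw columns
#' `posture_a, posture_b, coupling, contact_stress, static_activity,
#' repetitive_activity, rapid_movement, throwing_motion,
#' hand_arm_vibration, whole_body_vibration, air_temperature,
#' work_rest_cycle, load_weight, load_time, force_value, work_time`
#' (a `worker_id` column is optional and synthesized from row numbers when
#' absent). All ratings are validated against their rubric ranges; errors
#' name the offending column and row.
#'
#' @param path CSV file path.
#' @return Validated profile data frame.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", fileEncoding = "UTF-8")
  if (!"worker_id" %in% names(df)) {
    df <- cbind(worker_id = seq_len(nrow(df)), df)
  }
  validate_profiles(df)
  df
}

output_header <- function(seed = NULL, config = NULL) {
  c(sprintf("# generated by moreba %s",
            as.character(utils::packageVersion("moreba"))),
    if (!is.null(seed)) sprintf("# seed: %s", format(seed)),
    if (!is.null(config)) sprintf("# config_hash: %s", config_hash(config)))
}

config_hash <- function(config) {
  # dependency-free stable fingerprint (polynomial rolling hash over the
  # serialized config); for provenance headers, not cryptographic use
  bytes <- as.integer(charToRaw(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                 digits = NA)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write profiles (or any data frame) as annotated CSV
#'
#' Prepends metadata comment lines (package version, seed, config hash) so
#' every output records how it was produced; [read_profiles()] skips them.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param seed,config Optional metadata recorded in the header.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-format CMDQ responses from CSV
#'
#' @param path CSV with columns `worker_id`, `region`, `frequency`,
#'   `severity`, `interference`.
#' @return Data frame (categories validated on scoring, see
#'   [score_cmdq()]).
#' @export
read_cmdq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", fileEncoding = "UTF-8")
}

#' Score a profile table end to end
#'
#' @param profiles Profile data frame (see [read_profiles()]).
#' @param weights A `moreba_weights` object.
#' @param thresholds A [moreba_thresholds()] object.
#' @return Data frame with `worker_id`, `load` (L), `force` (F), `moreba`
#'   (score, reported to 3 decimals) and `risk_level`.
#' @export
score_profiles <- function(profiles, weights = moreba_weights(),
                           thresholds = moreba_thresholds()) {
  validate_profiles(profiles)
  id <- profiles$worker_id %||% seq_len(nrow(profiles))
  s <- moreba_score(profiles, weights)
  data.frame(
    worker_id = id,
    load = load_subscore(profiles$load_time, profiles$load_weight),
    force = force_subscore(profiles$work_time, profiles$force_value),
    moreba = round(s, 3),
    risk_level = classify_risk(s, thresholds))
}

#' Run the full synthetic validation pipeline
#'
#' Simulates a cohort, scores it with MOREBA and (reconstructed) classic
#' REBA, derives ROC cutoffs against the CMDQ bands, and compares the two
#' methods: per-band AUC and operating points, R-squared of each method
#' against the CMDQ total, and the three risk-level frequency
#' distributions.
#'
#' @param spec A [population_spec()]; its `seed` drives all randomness.
#' @param weights A `moreba_weights` object.
#' @param boundaries CMDQ band boundaries.
#' @param reba_breaks Breakpoints for [reba_action_level()].
#' @return List (JSON-serializable) with elements `n`, `seed`,
#'   `config_hash`, `cutoffs`, `operating`, `r_squared`, and
#'   `distributions`.
#' @export
run_validate <- function(spec = population_spec(),
                         weights = moreba_weights(),
                         boundaries = c(450, 900, 1350),
                         reba_breaks = c(3, 7, 10)) {
  cohort <- simulate_cohort(spec, weights)
  s <- moreba_score(cohort[profile_columns()], weights)
  reba <- reba_from_profile(cohort[profile_columns()])
  th <- derive_thresholds(s, cohort$cmdq_total, boundaries)
  list(
    n = spec$n,
    seed = spec$seed,
    package_version = as.character(utils::packageVersion("moreba")),
    config_hash = config_hash(list(boundaries = boundaries,
                                   target_r2 = spec$target_r2,
                                   n = spec$n, seed = spec$seed)),
    cutoffs = as.list(unclass(th)),
    operating = attr(th, "operating"),
    r_squared = list(moreba = r_squared(s, cohort$cmdq_total),
                     reba = r_squared(reba, cohort$cmdq_total)),
    distributions = list(
      cmdq = risk_distribution(cmdq_band(cohort$cmdq_total, boundaries)),
      moreba = risk_distribution(classify_risk(s, th)),
      reba = risk_distribution(reba_action_level(reba, reba_breaks))))
}
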