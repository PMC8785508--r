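# Cornell Musculoskeletal Discomfort Questionnaire (CMDQ) scoring.
# Per body region the instrument asks how often discomfort occurred last
# week, how severe it was, and how much it interfered with work; the three
# answers are weighted and multiplied, and region products are summed.

cmdq_frequency_weights <- c("never" = 0, "1-2/week" = 1.5, "3-4/week" = 3.5,
                            "daily" = 5, "several/day" = 10)
cmdq_severity_weights <- c("slight" = 1, "moderate" = 2, "very" = 3)
cmdq_interference_weights <- c("none" = 1, "slight" = 2, "substantial" = 3)

#' Default CMDQ body regions
#'
#' The standard questionnaire maps 12 body regions; the bilateral layout
#' splits shoulder, forearm, wrist, thigh, knee and lower leg into
#' left/right items (18 items), which is why observed totals can exceed
#' `12 * 90`.
#'
#' @param layout `"12"` (aggregated) or `"18"` (bilateral).
#' @return Character vector of region identifiers.
#' @export
cmdq_regions <- function(layout = c("12", "18")) {
  layout <- match.arg(layout)
  base <- c("neck", "shoulder", "upper_back", "upper_arm", "lower_back",
            "forearm", "wrist", "hip_buttocks", "thigh", "knee",
            "lower_leg", "foot")
  if (layout == "12") return(base)
  bilateral <- c("shoulder", "forearm", "wrist", "thigh", "knee", "lower_leg")
  unlist(lapply(base, function(r) {
    if (r %in% bilateral) paste(r, c("left", "right"), sep = "_") else r
  }))
}

match_category <- function(x, weights, what) {
  if (is.numeric(x)) {
    ok <- x %in% unname(weights)
    if (!all(ok)) {
      stop(sprintf("unknown %s weight: %s (allowed: %s)", what,
                   format(x[!ok][1]),
                   paste(unname(weights), collapse = ", ")), call. = FALSE)
    }
    return(as.numeric(x))
  }
  key <- tolower(trimws(as.character(x)))
  m <- match(key, names(weights))
  if (anyNA(m)) {
    stop(sprintf("unknown %s category: \"%s\" (allowed: %s)", what,
                 x[is.na(m)][1],
                 paste(names(weights), collapse = ", ")), call. = FALSE)
  }
  unname(weights[m])
}

#' CMDQ item score for one body region
#'
#' Product of the frequency weight (0, 1.5, 3.5, 5, 10), the severity
#' weight (1-3) and the work-interference weight (1-3); ranges 0 to 90 per
#' region.
#'
#' @param frequency `"never"`, `"1-2/week"`, `"3-4/week"`, `"daily"`,
#'   `"several/day"` (case-insensitive), or the numeric weight itself.
#' @param severity `"slight"`, `"moderate"`, `"very"`, or 1-3.
#' @param interference `"none"`, `"slight"`, `"substantial"`, or 1-3.
#' @return Numeric vector of item scores.
#' @examples
#' cmdq_item_score("several/day", "very", "substantial")  # 90
#' @export
cmdq_item_score <- function(frequency, severity, interference) {
  match_category(frequency, cmdq_frequency_weights, "frequency") *
    match_category(severity, cmdq_severity_weights, "severity") *
    match_category(interference, cmdq_interference_weights, "interference")
}

#' CMDQ total discomfort score
#'
#' Sum of per-region item scores for one respondent. Additive and
#' order-invariant; 0 when every region reports "never".
#'
#' @param frequency,severity,interference Parallel vectors of per-region
#'   answers (see [cmdq_item_score()]).
#' @return Single numeric total.
#' @export
cmdq_total <- function(frequency, severity = NULL, interference = NULL) {
  if (is.null(severity) && is.null(interference)) {
    return(sum(frequency))  # pre-computed item scores
  }
  sum(cmdq_item_score(frequency, severity, interference))
}

#' Score a long-format CMDQ table
#'
#' @param responses Data frame with columns `worker_id`, `region`,
#'   `frequency`, `severity`, `interference` (one row per worker-region).
#' @param boundaries Passed to [cmdq_band()].
#' @return Data frame with one row per worker: `worker_id`, `cmdq_total`,
#'   `band`.
#' @export
score_cmdq <- function(responses, boundaries = c(450, 900, 1350)) {
  need <- c("worker_id", "region", "frequency", "severity", "interference")
  missing <- setdiff(need, names(responses))
  if (length(missing)) {
    stop("CMDQ data is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  item <- cmdq_item_score(responses$frequency, responses$severity,
                          responses$interference)
  tot <- tapply(item, responses$worker_id, sum)
  out <- data.frame(worker_id = names(tot), cmdq_total = as.numeric(tot),
                    row.names = NULL)
  out$band <- cmdq_band(out$cmdq_total, boundaries)
  out
}

#' Band a CMDQ total into four risk levels
#'
#' Discomfort totals are banded at 450, 900 and 1350. Boundaries are
#' left-closed: band 2 starts at exactly 450, band 4 at exactly 1350.
#'
#' @param total Non-negative numeric vector of CMDQ totals.
#' @param boundaries Three increasing band boundaries.
#' @return Integer vector of bands (1-4).
#' @examples
#' cmdq_band(c(0, 536.82, 1400))  # 1 2 4
#' @export
cmdq_band <- function(total, boundaries = c(450, 900, 1350)) {
  if (length(boundaries) != 3 || is.unsorted(boundaries, strictly = TRUE)) {
    stop("`boundaries` must be three strictly increasing values",
         call. = FALSE)
  }
  if (any(!is.finite(total) | total < 0)) {
    stop("CMDQ totals must be finite and non-negative", call. = FALSE)
  }
  findInterval(total, boundaries) + 1L
}
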