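#' Default standardized factor loadings (direct effects)
#'
#' Direct effect coefficients of the 14 physical risk factors on the latent
#' strain construct, as estimated by the structural equation model behind
#' the MOREBA method. These are the loadings multiplied by the
#' strain-to-symptoms path coefficient (0.783) to obtain the weights of the
#' scoring equation.
#'
#' @return Named numeric vector over [moreba_factors()].
#' @export
default_direct_effects <- function() {
  cfg <- default_weight_config()
  unlist(cfg$direct_effects)[moreba_factors()]
}

default_weight_config <- function() {
  path <- system.file("extdata", "moreba_weights.json", package = "moreba")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Derive MOREBA equation weights from direct effects
#'
#' Each factor's weight (indirect effect on musculoskeletal symptoms) is its
#' direct effect on the latent strain multiplied by the strain-to-symptoms
#' coefficient, rounded half-up to three decimals to match the printed
#' coefficient convention.
#'
#' @param direct_effects Named numeric vector of standardized loadings in
#'   (0, 1], one per factor in [moreba_factors()].
#' @param strain_coefficient Path coefficient of strain on musculoskeletal
#'   symptoms; default 0.783.
#' @return An object of class `moreba_weights`: a list with elements
#'   `strain_coefficient`, `direct_effects` and `indirect_effects` (the 14
#'   equation coefficients).
#' @examples
#' w <- derive_weights()
#' w$indirect_effects[["posture_a"]]  # 0.734
#' @export
derive_weights <- function(direct_effects = default_direct_effects(),
                           strain_coefficient = 0.783) {
  if (!is.numeric(strain_coefficient) || length(strain_coefficient) != 1 ||
      !is.finite(strain_coefficient) || strain_coefficient <= 0 ||
      strain_coefficient > 1) {
    stop("`strain_coefficient` must be a single finite value in (0, 1]",
         call. = FALSE)
  }
  check_factor_names(names(direct_effects))
  direct_effects <- direct_effects[moreba_factors()]
  if (any(!is.finite(direct_effects)) ||
      any(direct_effects <= 0 | direct_effects > 1)) {
    bad <- names(direct_effects)[!is.finite(direct_effects) |
                                   direct_effects <= 0 | direct_effects > 1]
    stop("direct effects must lie in (0, 1]; offending factor(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(strain_coefficient = strain_coefficient,
         direct_effects = direct_effects,
         indirect_effects = round_half_up(direct_effects * strain_coefficient, 3)),
    class = "moreba_weights")
}

check_factor_names <- function(nms) {
  want <- moreba_factors()
  missing <- setdiff(want, nms)
  extra <- setdiff(nms, want)
  if (length(missing) || length(extra)) {
    stop("factor set mismatch",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  invisible(nms)
}

#' Default MOREBA weight set
#'
#' Loads the packaged coefficient configuration (or an alternative JSON
#' file with the same schema) and derives the equation weights. The
#' packaged defaults reproduce the published scoring equation, e.g. 0.734
#' for posture group A and 0.257 for whole-body vibration.
#'
#' @param path Optional path to a JSON file with fields
#'   `strain_coefficient` and `direct_effects`; defaults to the
#'   configuration shipped with the package.
#' @return A `moreba_weights` object (see [derive_weights()]).
#' @export
moreba_weights <- function(path = NULL) {
  cfg <- if (is.null(path)) default_weight_config() else {
    if (!file.exists(path)) stop("weights file not found: ", path, call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  de <- unlist(cfg$direct_effects)
  check_factor_names(names(de))
  derive_weights(de[moreba_factors()],
                 strain_coefficient = cfg$strain_coefficient)
}

#' @export
print.moreba_weights <- function(x, ...) {
  cat("MOREBA weight set (strain coefficient ",
      format(x$strain_coefficient), ")\n", sep = "")
  print(data.frame(direct = x$direct_effects,
                   indirect = x$indirect_effects))
  invisible(x)
}
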