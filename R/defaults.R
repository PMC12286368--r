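#' Element vocabulary
#'
#' The twelve elements measured in the bakery survey. All parsers reject
#' symbols outside this closed set.
#'
#' @return Character vector of element symbols.
#' @export
bread_elements <- function() {
  c("Fe", "Zn", "Cu", "Co", "Cr", "V", "Al", "Ni", "As", "Hg", "Pb", "Cd")
}

#' Production stages and bread types recognised in concentration tables
#' @return Character vector.
#' @export
bread_stages <- function() c("flour", "dough", "bread")

#' @rdname bread_stages
#' @export
bread_types <- function() c("sangak", "barbari", "taftoon", "lavash", "unknown")

# Instrument detection limits, mg/kg dry weight.
element_lods <- function() {
  c(Fe = 0.06, Zn = 0.1, Cu = 0.1, Co = 0.02, Cr = 0.06, V = 0.06,
    Al = 0.18, Ni = 0.012, As = 0.02, Hg = 0.01, Pb = 0.01, Cd = 0.01)
}

#' Cohort exposure parameters
#'
#' Constructor and built-in defaults for the ingestion-exposure parameter
#' bundle used by [chronic_daily_intake()]: ingestion rate IR (kg/day),
#' exposure frequency EF (days/year), exposure duration ED (years), body
#' weight BW (kg) and averaging time AT (days).
#'
#' @param cohort `"adult"` or `"child"` (free labels allowed).
#' @param IR ingestion rate, kg/day.
#' @param EF exposure frequency, days/year (at most 366).
#' @param ED exposure duration, years.
#' @param BW body weight, kg.
#' @param AT averaging time, days.
#' @return An object of class `exposure_params`.
#' @examples
#' default_exposure_params()$adult$IR  # 0.42 kg/day
#' @export
exposure_params <- function(cohort, IR, EF, ED, BW, AT) {
  vals <- c(IR = IR, EF = EF, ED = ED, BW = BW, AT = AT)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("exposure parameters must all be strictly positive", call. = FALSE)
  }
  if (EF > 366) stop("EF cannot exceed 366 days/year", call. = FALSE)
  structure(list(cohort = cohort, IR = IR, EF = EF, ED = ED, BW = BW, AT = AT),
            class = "exposure_params")
}

#' @rdname exposure_params
#' @export
default_exposure_params <- function() {
  list(
    adult = exposure_params("adult", IR = 0.420, EF = 365, ED = 70, BW = 70, AT = 10550),
    child = exposure_params("child", IR = 0.210, EF = 365, ED = 6,  BW = 20, AT = 2100)
  )
}

#' Toxicological reference values
#'
#' Per-element oral reference dose (RfD, mg/kg/day) for non-carcinogenic
#' hazard and oral slope factor (OSF, per mg/kg/day) for carcinogenic risk.
#' Defaults are the EPA screening values used in the survey.
#'
#' @return A data frame with columns `element`, `rfd`, `osf` (NA where a
#'   value is not defined for the element).
#' @examples
#' tox <- default_tox_profiles()
#' tox$osf[tox$element == "As"]  # 1.5
#' @export
default_tox_profiles <- function() {
  data.frame(
    element = c("As", "Cd", "Al", "Co", "Cu", "Fe", "Hg", "V", "Zn", "Cr", "Ni", "Pb"),
    rfd = c(0.003, 0.001, 0.7, 0.0004, 0.04, 0.7, 0.0004, 0.009, 0.3, 0.003, 0.2, 0.0035),
    osf = c(1.5, 0.38, NA, NA, NA, NA, NA, NA, NA, NA, NA, 0.0085),
    stringsAsFactors = FALSE
  )
}

#' Risk classification thresholds
#'
#' Non-carcinogenic risk is flagged when HQ or HI exceeds `hq_limit`
#' (EPA convention: concern above 1). Carcinogenic risk is classified as
#' `de_minimis` below `cr_de_minimis`, `unacceptable` above
#' `cr_unacceptable`, and `acceptable_range` in between.
#'
#' @param hq_limit HQ/HI flag threshold (default 1).
#' @param cr_de_minimis lower CR bound (default 1e-6).
#' @param cr_unacceptable upper CR bound (default 1e-4).
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(hq_limit = 1.0, cr_de_minimis = 1e-6,
                             cr_unacceptable = 1e-4) {
  if (hq_limit <= 0) stop("hq_limit must be positive", call. = FALSE)
  if (!(cr_de_minimis < cr_unacceptable)) {
    stop("cr_de_minimis must be below cr_unacceptable", call. = FALSE)
  }
  structure(list(hq_limit = hq_limit, cr_de_minimis = cr_de_minimis,
                 cr_unacceptable = cr_unacceptable),
            class = "threshold_policy")
}

#' @rdname threshold_policy
#' @export
default_threshold_policy <- function() threshold_policy()

#' All built-in defaults in one bundle
#'
#' @return List with components `exposure` (adult and child
#'   [exposure_params()]), `tox` ([default_tox_profiles()]), `policy`
#'   ([default_threshold_policy()]) and `carcinogens` (elements entering
#'   TCR; arsenic and cadmium — lead carries a slope factor but is fully
#'   left-censored in the survey).
#' @export
builtin_defaults <- function() {
  list(exposure = default_exposure_params(),
       tox = default_tox_profiles(),
       policy = default_threshold_policy(),
       carcinogens = c("As", "Cd"))
}
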