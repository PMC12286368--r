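#' Chronic daily intake
#'
#' Ingested dose per unit body weight, `CDI = C * IR * EF * ED / (BW * AT)`
#' in mg/kg/day. Linear and homogeneous in the concentration `c`, and
#' invariant under scaling ED and AT by a common factor.
#'
#' @param c concentration in the consumed food, mg/kg dry weight
#'   (vectorised, non-negative).
#' @param params an [exposure_params()] bundle.
#' @return CDI in mg/kg/day.
#' @examples
#' chronic_daily_intake(1, default_exposure_params()$adult)  # 0.0145308
#' @export
chronic_daily_intake <- function(c, params) {
  stopifnot(inherits(params, "exposure_params"))
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("concentration must be finite and non-negative", call. = FALSE)
  }
  c * exposure_factor(params)
}

#' @rdname chronic_daily_intake
#' @return `exposure_factor()` returns the cohort's intake-per-unit-
#'   concentration multiplier `IR*EF*ED/(BW*AT)` in 1/day per (mg/kg of
#'   concentration basis), i.e. CDI for C = 1 mg/kg.
#' @export
exposure_factor <- function(params) {
  stopifnot(inherits(params, "exposure_params"))
  params$IR * params$EF * params$ED / (params$BW * params$AT)
}

#' Censoring policy
#'
#' How below-detection-limit cells enter the analysis: `exclude` drops
#' censored cells (and elements censored in every record vanish from
#' downstream risk, as mercury and lead do in the survey); `zero`,
#' `half_lod`, `full_lod` substitute 0, LOD/2 or LOD.
#'
#' @param mode one of `"exclude"`, `"zero"`, `"half_lod"`, `"full_lod"`.
#' @return The validated mode string, classed `censor_policy`.
#' @export
censor_policy <- function(mode = c("exclude", "zero", "half_lod", "full_lod")) {
  mode <- match.arg(mode)
  structure(mode, class = "censor_policy")
}

#' Apply a censoring policy to concentration records
#'
#' @param records validated concentration records.
#' @param policy a [censor_policy()] (or its mode string).
#' @return Records with a `use_value` column holding the analysable
#'   concentration; under `exclude`, censored rows are removed.
#' @examples
#' rec <- generate_study(default_study_config(seed = 1))
#' nrow(apply_censor_policy(rec, censor_policy("exclude")))
#' @export
apply_censor_policy <- function(records, policy = censor_policy("exclude")) {
  if (!inherits(policy, "censor_policy")) policy <- censor_policy(policy)
  validate_concentrations(records)
  mode <- unclass(policy)
  if (mode == "exclude") {
    out <- records[!records$censored, , drop = FALSE]
    out$use_value <- out$value
    return(out)
  }
  sub <- switch(mode, zero = 0, half_lod = 0.5, full_lod = 1)
  out <- records
  out$use_value <- ifelse(out$censored, sub * out$lod, out$value)
  out
}

#' Mean chronic daily intake per region, cohort and element
#'
#' Dietary exposure uses bread-stage records only (flour and dough feed the
#' apportionment and group statistics, not the diet). The region-level CDI
#' is the CDI of the arithmetic mean of the region's bakery-level bread
#' concentrations; by linearity this equals the mean of the per-bakery CDIs.
#'
#' @param records validated concentration records.
#' @param params list of [exposure_params()] (one per cohort), e.g.
#'   [default_exposure_params()].
#' @param policy a [censor_policy()]; default `exclude`.
#' @return Data frame: `region`, `cohort`, `element`,
#'   `mean_concentration_mg_kg`, `cdi_mg_kg_day`. Regions with no usable
#'   bread record for an element are absent (with a warning when a whole
#'   region yields nothing).
#' @export
mean_cdi_by_element <- function(records, params = default_exposure_params(),
                                policy = censor_policy("exclude")) {
  usable <- apply_censor_policy(records, policy)
  bread <- usable[usable$stage == "bread", , drop = FALSE]
  empty_regions <- setdiff(unique(records$region), unique(bread$region))
  if (length(empty_regions)) {
    warning("no usable bread records for region(s): ",
            paste(empty_regions, collapse = ", "), call. = FALSE)
  }
  if (!nrow(bread)) {
    return(data.frame(region = character(), cohort = character(),
                      element = character(),
                      mean_concentration_mg_kg = numeric(),
                      cdi_mg_kg_day = numeric()))
  }
  means <- aggregate(use_value ~ region + element, data = bread, FUN = mean)
  names(means)[names(means) == "use_value"] <- "mean_concentration_mg_kg"
  out <- do.call(rbind, lapply(params, function(p) {
    data.frame(region = means$region, cohort = p$cohort,
               element = means$element,
               mean_concentration_mg_kg = means$mean_concentration_mg_kg,
               cdi_mg_kg_day = means$mean_concentration_mg_kg * exposure_factor(p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$region, out$cohort, out$element), ]
}
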