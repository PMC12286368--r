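#' Screen mean concentrations against regulatory limits
#'
#' For every (region, element, authority) triple, compares the region's mean
#' concentration at the requested stage with the permissible limit. The
#' boundary convention is strict: a mean exactly equal to its limit does not
#' exceed. Elements with records but no limit entry are reported with
#' `exceeds = NA` so the screening gap is visible; fully censored elements
#' carry no mean and are omitted.
#'
#' @param records validated concentration records.
#' @param limits limit table (`element`, `authority`, `limit_mg_kg`), e.g.
#'   [example_limits()] or [read_limits()].
#' @param stage production stage screened; default `"bread"`.
#' @param policy [censor_policy()] applied before averaging.
#' @return Data frame: `region`, `element`, `authority`,
#'   `mean_mg_kg`, `limit_mg_kg`, `ratio`, `exceeds`.
#' @examples
#' rec <- generate_study(default_study_config(seed = 1))
#' head(exceedance_report(rec, example_limits()))
#' @export
exceedance_report <- function(records, limits, stage = "bread",
                              policy = censor_policy("exclude")) {
  if (!nrow(limits)) stop("limit table is empty", call. = FALSE)
  usable <- apply_censor_policy(records, policy)
  usable <- usable[usable$stage == stage, , drop = FALSE]
  if (!nrow(usable)) stop("no usable records at stage ", stage, call. = FALSE)
  means <- aggregate(use_value ~ region + element, data = usable, FUN = mean)
  names(means)[names(means) == "use_value"] <- "mean_mg_kg"

  out <- do.call(rbind, lapply(seq_len(nrow(means)), function(i) {
    lim <- limits[limits$element == means$element[i], , drop = FALSE]
    if (!nrow(lim)) {
      lim <- data.frame(authority = NA_character_, limit_mg_kg = NA_real_)
    }
    data.frame(region = means$region[i], element = means$element[i],
               authority = lim$authority, mean_mg_kg = means$mean_mg_kg[i],
               limit_mg_kg = lim$limit_mg_kg,
               ratio = means$mean_mg_kg[i] / lim$limit_mg_kg,
               exceeds = means$mean_mg_kg[i] > lim$limit_mg_kg,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$region, out$element, out$authority), ]
}
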