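#' Decompose a bread burden into production-stage contributions
#'
#' Mass-balance reading of the three production stages: the flour level, the
#' dough-stage addition (water, salt, yeast: dough minus flour) and the
#' baking/oven contact (bread minus dough) are expressed as percentage
#' shares of the bread concentration. Negative increments — measurement
#' noise, or an element lost during a stage — are clipped to zero before
#' normalising, so shares are non-negative and sum to 100.
#'
#' @param f,d,b mean concentrations (mg/kg dw) in flour, dough and bread;
#'   `b` must be positive.
#' @return Named vector `c(flour_pct, dough_pct, oven_pct)`.
#' @examples
#' stage_contributions(0.83, 0.975, 1.0)  # 83 / 14.5 / 2.5
#' @export
stage_contributions <- function(f, d, b) {
  stopifnot(length(f) == 1, length(d) == 1, length(b) == 1)
  if (!is.finite(b) || b <= 0) stop("bread mean must be positive", call. = FALSE)
  if (f < 0 || d < 0) stop("stage means must be non-negative", call. = FALSE)
  inc <- pmax(c(f, d - f, b - d), 0)
  shares <- 100 * inc / sum(inc)
  names(shares) <- c("flour_pct", "dough_pct", "oven_pct")
  shares
}

#' Per-element stage apportionment for a survey
#'
#' Region-pooled stage means feed [stage_contributions()] element by
#' element. Elements missing a stage, or censored in every record, are
#' excluded (with a message); a grand-mean row averages the shares over the
#' reported elements.
#'
#' @param records validated concentration records.
#' @param policy [censor_policy()]; default `exclude`.
#' @return Data frame: `element`, `flour_pct`, `dough_pct`, `oven_pct`,
#'   with a final `"(mean)"` row holding the grand means.
#' @export
apportionment_table <- function(records, policy = censor_policy("exclude")) {
  usable <- apply_censor_policy(records, policy)
  elements <- intersect(bread_elements(), unique(records$element))
  rows <- lapply(elements, function(el) {
    d <- usable[usable$element == el, , drop = FALSE]
    m <- tapply(d$use_value, d$stage, mean)
    if (any(!bread_stages() %in% names(m)) || any(is.na(m[bread_stages()]))) {
      message("apportionment: element ", el, " lacks a usable stage; excluded")
      return(NULL)
    }
    if (m[["bread"]] <= 0) {
      warning("apportionment: zero bread mean for ", el, "; row skipped",
              call. = FALSE)
      return(NULL)
    }
    s <- stage_contributions(m[["flour"]], m[["dough"]], m[["bread"]])
    data.frame(element = el, flour_pct = s[[1]], dough_pct = s[[2]],
               oven_pct = s[[3]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no element has all three stages", call. = FALSE)
  grand <- data.frame(element = "(mean)",
                      flour_pct = mean(out$flour_pct),
                      dough_pct = mean(out$dough_pct),
                      oven_pct = mean(out$oven_pct),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  rbind(out, grand)
}
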