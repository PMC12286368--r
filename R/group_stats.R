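#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests a sample against a normal law with sample-estimated mean and
#' standard deviation, as done in the survey's statistical analysis. With
#' estimated parameters the plain KS p-value is conservative (the
#' Lilliefors situation): true rejection rates run below the nominal level.
#' This matches the published procedure and errs toward the parametric
#' branch of [compare_groups()].
#'
#' @param values numeric sample, n >= 5, non-degenerate.
#' @return List with `statistic`, `p.value`, `n`.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("normality test requires n >= 5", call. = FALSE)
  s <- sd(values)
  if (s == 0) stop("degenerate (constant) sample", call. = FALSE)
  kt <- suppressWarnings(ks.test(values, "pnorm", mean(values), s))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       n = length(values))
}

#' Compare element concentrations across groups
#'
#' One-way ANOVA when the data are taken as normal, Kruskal-Wallis
#' otherwise — the survey's decision rule. The method actually used is
#' recorded in the result.
#'
#' @param values numeric vector of concentrations.
#' @param groups group labels, same length as `values`; at least two groups
#'   with two observations each.
#' @param normal logical: route to ANOVA (`TRUE`) or Kruskal-Wallis.
#' @return List with `method`, `statistic`, `p.value`.
#' @export
compare_groups <- function(values, groups, normal) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (isTRUE(normal)) {
    ft <- oneway.test(values ~ groups, var.equal = TRUE)
    list(method = "anova", statistic = unname(ft$statistic),
         p.value = ft$p.value)
  } else {
    kw <- kruskal.test(values, groups)
    list(method = "kruskal-wallis", statistic = unname(kw$statistic),
         p.value = kw$p.value)
  }
}

#' Region- or bread-type-wise comparison for every element
#'
#' Per element: gate on [normality_test()] at `alpha`, then
#' [compare_groups()] across the chosen grouping. Elements censored in
#' every record are skipped; an element with fewer than two groups yields a
#' row with `error` filled instead of a p-value. By default only
#' bread-stage values are tested (config-overridable through `stage`).
#'
#' @param records validated concentration records.
#' @param grouping `"region"` or `"bread_type"`.
#' @param stage production stage tested; default `"bread"`.
#' @param alpha significance level for both the gate and the `significant`
#'   flag; default 0.05.
#' @param adjust p-value adjustment across elements, as in
#'   [stats::p.adjust()] (default `"none"`, matching the survey; `"holm"`
#'   available).
#' @param policy [censor_policy()]; default `exclude`.
#' @return Data frame: `element`, `grouping`, `method`, `statistic`, `p`,
#'   `significant`, `error`.
#' @export
regional_difference_table <- function(records, grouping = c("region", "bread_type"),
                                      stage = "bread", alpha = 0.05,
                                      adjust = "none",
                                      policy = censor_policy("exclude")) {
  grouping <- match.arg(grouping)
  usable <- apply_censor_policy(records, policy)
  usable <- usable[usable$stage == stage, , drop = FALSE]
  elements <- intersect(bread_elements(), unique(usable$element))
  rows <- lapply(elements, function(el) {
    d <- usable[usable$element == el, , drop = FALSE]
    res <- tryCatch({
      normal <- normality_test(d$use_value)$p.value >= alpha
      ct <- compare_groups(d$use_value, d[[grouping]], normal)
      data.frame(element = el, grouping = grouping, method = ct$method,
                 statistic = ct$statistic, p = ct$p.value,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(element = el, grouping = grouping, method = NA_character_,
                 statistic = NA_real_, p = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = adjust)
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}
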