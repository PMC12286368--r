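#' Hazard quotient, hazard index, cancer risk
#'
#' The EPA point-estimate risk metrics. `hazard_quotient()` is `CDI / RfD`
#' (dimensionless); `hazard_index()` is the exact sum of a row's hazard
#' quotients; `cancer_risk()` is `CDI * OSF`; `total_cancer_risk()` the
#' exact sum over carcinogens.
#'
#' @param cdi chronic daily intake, mg/kg/day (non-negative, vectorised).
#' @param rfd oral reference dose, mg/kg/day (positive).
#' @param osf oral slope factor, per mg/kg/day (positive).
#' @param hqs,crs numeric vectors of hazard quotients / cancer risks.
#' @return Dimensionless risk values.
#' @examples
#' hazard_quotient(0.01563, 0.003)
#' hazard_index(c(0.029, 5.21, 0.170))
#' @export
hazard_quotient <- function(cdi, rfd) {
  if (any(!is.finite(rfd)) || any(rfd <= 0)) stop("RfD must be positive", call. = FALSE)
  if (any(!is.finite(cdi)) || any(cdi < 0)) stop("CDI must be non-negative", call. = FALSE)
  cdi / rfd
}

#' @rdname hazard_quotient
#' @export
hazard_index <- function(hqs) {
  if (length(hqs) == 0) stop("hazard index of an empty set is undefined", call. = FALSE)
  if (any(!is.finite(hqs)) || any(hqs < 0)) stop("HQs must be non-negative", call. = FALSE)
  sum(hqs)
}

#' @rdname hazard_quotient
#' @export
cancer_risk <- function(cdi, osf) {
  if (any(!is.finite(osf)) || any(osf <= 0)) stop("OSF must be positive", call. = FALSE)
  if (any(!is.finite(cdi)) || any(cdi < 0)) stop("CDI must be non-negative", call. = FALSE)
  cdi * osf
}

#' @rdname hazard_quotient
#' @export
total_cancer_risk <- function(crs) {
  if (length(crs) == 0) stop("total cancer risk of an empty set is undefined", call. = FALSE)
  if (any(!is.finite(crs)) || any(crs < 0)) stop("CRs must be non-negative", call. = FALSE)
  sum(crs)
}

#' Fit a deterministic risk assessment to a concentration survey
#'
#' The central modelling function. From a long concentration table it
#' derives, per region and cohort: the mean bread concentration and chronic
#' daily intake of every element, the element hazard quotients (for elements
#' with an RfD), the hazard index, the cancer risks of the carcinogens
#' (elements with a slope factor) and the total cancer risk. Elements whose
#' bread records are entirely censored are excluded under the default
#' `exclude` policy (mercury and lead in the survey); elements lacking an
#' RfD are skipped from HI with a warning.
#'
#' @param records validated concentration records (see
#'   [read_concentrations()], [generate_study()]).
#' @param params cohort exposure parameters; default
#'   [default_exposure_params()].
#' @param tox data frame with `element`, `rfd`, `osf`; default
#'   [default_tox_profiles()].
#' @param carcinogens elements entering the total cancer risk; default
#'   arsenic and cadmium.
#' @param policy [censor_policy()] for below-detection cells.
#' @return An object of class `risk_assessment` with components:
#'   \describe{
#'     \item{risk}{long table: region, cohort, element, mean concentration,
#'       CDI, RfD, HQ, OSF, CR.}
#'     \item{index}{one row per (region, cohort): `hi`, `tcr` and element
#'       counts.}
#'     \item{records, params, tox, carcinogens, policy}{the inputs.}
#'   }
#'   Methods: [print()], [summary()], [plot()], [simulate()],
#'   [classify_risk()], [write_risk_report()].
#' @examples
#' fit <- risk_assessment(generate_study(default_study_config(seed = 1)))
#' summary(fit)
#' @export
risk_assessment <- function(records,
                            params = default_exposure_params(),
                            tox = default_tox_profiles(),
                            carcinogens = c("As", "Cd"),
                            policy = censor_policy("exclude")) {
  cdi <- mean_cdi_by_element(records, params = params, policy = policy)
  if (!nrow(cdi)) stop("no usable bread-stage records", call. = FALSE)

  no_rfd <- setdiff(unique(cdi$element), tox$element[!is.na(tox$rfd)])
  if (length(no_rfd)) {
    warning("element(s) without an RfD skipped from hazard index: ",
            paste(no_rfd, collapse = ", "), call. = FALSE)
  }
  risk <- cdi
  risk$rfd <- tox$rfd[match(risk$element, tox$element)]
  risk$hq <- ifelse(is.na(risk$rfd), NA_real_, risk$cdi_mg_kg_day / risk$rfd)
  risk$osf <- tox$osf[match(risk$element, tox$element)]
  risk$osf[!(risk$element %in% carcinogens)] <- NA_real_
  risk$cr <- ifelse(is.na(risk$osf), NA_real_, risk$cdi_mg_kg_day * risk$osf)

  key <- unique(risk[, c("region", "cohort")])
  index <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    rows <- risk[risk$region == key$region[i] & risk$cohort == key$cohort[i], ]
    hq <- rows$hq[!is.na(rows$hq)]
    cr <- rows$cr[!is.na(rows$cr)]
    data.frame(region = key$region[i], cohort = key$cohort[i],
               n_elements = nrow(rows),
               hi = if (length(hq)) hazard_index(hq) else NA_real_,
               tcr = if (length(cr)) total_cancer_risk(cr) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(index) <- NULL

  structure(list(risk = risk, index = index, records = records,
                 params = params, tox = tox, carcinogens = carcinogens,
                 policy = if (inherits(policy, "censor_policy")) policy
                          else censor_policy(policy)),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("Deterministic dietary risk assessment (bread stage)\n")
  cat(sprintf("  regions: %s\n", paste(unique(x$index$region), collapse = ", ")))
  cat(sprintf("  cohorts: %s\n", paste(unique(x$index$cohort), collapse = ", ")))
  cat(sprintf("  elements in HI: %s\n",
              paste(sort(unique(x$risk$element[!is.na(x$risk$hq)])), collapse = ", ")))
  cat(sprintf("  carcinogens in TCR: %s\n",
              paste(intersect(x$carcinogens, unique(x$risk$element)), collapse = ", ")))
  cat("\nHazard index / total cancer risk by region and cohort:\n")
  idx <- x$index
  idx$hi <- signif(idx$hi, 5)
  idx$tcr <- signif(idx$tcr, 3)
  print(idx, row.names = FALSE)
  invisible(x)
}

#' Summarise a risk assessment across regions
#'
#' Arithmetic means, minima and maxima of HI and TCR per cohort across
#' regions, plus per-region child:adult HI ratios when both cohorts are
#' present.
#'
#' @param object a `risk_assessment`.
#' @param ... unused.
#' @return A `risk_summary` list with `by_cohort` (cohort, mean/min/max HI,
#'   mean/min/max TCR) and `hi_ratio` (region, child:adult HI ratio; NULL
#'   when a cohort is missing).
#' @export
summary.risk_assessment <- function(object, ...) {
  idx <- object$index
  by_cohort <- do.call(rbind, lapply(split(idx, idx$cohort), function(d) {
    data.frame(cohort = d$cohort[1],
               mean_hi = mean(d$hi), min_hi = min(d$hi), max_hi = max(d$hi),
               mean_tcr = mean(d$tcr), min_tcr = min(d$tcr), max_tcr = max(d$tcr),
               stringsAsFactors = FALSE)
  }))
  rownames(by_cohort) <- NULL
  hi_ratio <- NULL
  if (all(c("adult", "child") %in% idx$cohort)) {
    ad <- idx[idx$cohort == "adult", ]
    ch <- idx[idx$cohort == "child", ]
    common <- intersect(ad$region, ch$region)
    hi_ratio <- data.frame(
      region = common,
      ratio = ch$hi[match(common, ch$region)] / ad$hi[match(common, ad$region)],
      stringsAsFactors = FALSE)
  }
  structure(list(by_cohort = by_cohort, hi_ratio = hi_ratio),
            class = "risk_summary")
}

#' @export
print.risk_summary <- function(x, ...) {
  cat("Cross-region risk summary\n")
  bc <- x$by_cohort
  bc[-1] <- lapply(bc[-1], signif, digits = 4)
  print(bc, row.names = FALSE)
  if (!is.null(x$hi_ratio)) {
    cat("\nChild:adult hazard-index ratio by region:\n")
    hr <- x$hi_ratio
    hr$ratio <- round(hr$ratio, 3)
    print(hr, row.names = FALSE)
  }
  invisible(x)
}

#' Classify risk values against a threshold policy
#'
#' Adds per-element HQ flags (`hq > hq_limit`), per-row HI flags, and a CR
#' class among `de_minimis`, `acceptable_range`, `unacceptable`. Strictly
#' monotone: raising any HQ never un-flags a row.
#'
#' @param x a `risk_assessment`.
#' @param policy a [threshold_policy()].
#' @return List with `elements` (region, cohort, element, hq, hq_flag, cr,
#'   cr_class) and `index` (region, cohort, hi, hi_flag, tcr, tcr_class).
#' @export
classify_risk <- function(x, policy = default_threshold_policy()) {
  stopifnot(inherits(x, "risk_assessment"), inherits(policy, "threshold_policy"))
  cr_class <- function(cr) {
    ifelse(is.na(cr), NA_character_,
           ifelse(cr > policy$cr_unacceptable, "unacceptable",
                  ifelse(cr < policy$cr_de_minimis, "de_minimis",
                         "acceptable_range")))
  }
  el <- x$risk[, c("region", "cohort", "element", "hq", "cr")]
  el$hq_flag <- !is.na(el$hq) & el$hq > policy$hq_limit
  el$cr_class <- cr_class(el$cr)
  idx <- x$index[, c("region", "cohort", "hi", "tcr")]
  idx$hi_flag <- idx$hi > policy$hq_limit
  idx$tcr_class <- cr_class(idx$tcr)
  list(elements = el, index = idx)
}

#' Barplot of hazard quotients by element
#'
#' @param x a `risk_assessment`.
#' @param cohort cohort to display.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.risk_assessment <- function(x, cohort = "adult", ...) {
  d <- x$risk[x$risk$cohort == cohort & !is.na(x$risk$hq), ]
  if (!nrow(d)) stop("no HQ rows for cohort ", cohort, call. = FALSE)
  m <- tapply(d$hq, list(d$element, d$region), mean)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "Hazard quotient", xlab = "Region",
                    main = paste("Hazard quotients,", cohort), ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Write and re-read the risk report CSVs
#'
#' `write_risk_report()` writes `hq_hi_by_region.csv` (one row per region,
#' cohort and element with HQ, plus the row HI), `cr_tcr_by_region.csv` and
#' `cdi_by_region.csv` into a directory, at full double precision so the
#' round trip through [read_risk_report()] is lossless.
#'
#' @param x a `risk_assessment` with a non-empty risk table.
#' @param dir output directory (created if needed).
#' @return `write_risk_report()` the directory path, invisibly;
#'   `read_risk_report()` a list of the three tables.
#' @export
write_risk_report <- function(x, dir) {
  stopifnot(inherits(x, "risk_assessment"))
  if (!nrow(x$risk)) stop("empty risk table", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(d, file, cols) {
    d[cols] <- lapply(d[cols], num_chr)
    write.csv(d, file.path(dir, file), row.names = FALSE, quote = FALSE, na = "")
  }
  hq <- x$risk[, c("region", "cohort", "element", "hq")]
  hq$hi <- x$index$hi[match(paste(hq$region, hq$cohort),
                            paste(x$index$region, x$index$cohort))]
  wr(hq, "hq_hi_by_region.csv", c("hq", "hi"))
  cr <- x$risk[!is.na(x$risk$cr), c("region", "cohort", "element", "cr")]
  cr$tcr <- x$index$tcr[match(paste(cr$region, cr$cohort),
                              paste(x$index$region, x$index$cohort))]
  wr(cr, "cr_tcr_by_region.csv", c("cr", "tcr"))
  wr(x$risk[, c("region", "cohort", "element", "mean_concentration_mg_kg",
                "cdi_mg_kg_day")],
     "cdi_by_region.csv", c("mean_concentration_mg_kg", "cdi_mg_kg_day"))
  invisible(dir)
}

#' @rdname write_risk_report
#' @export
read_risk_report <- function(dir) {
  rd <- function(file) {
    p <- file.path(dir, file)
    if (!file.exists(p)) stop("missing report file: ", p, call. = FALSE)
    read.csv(p, stringsAsFactors = FALSE)
  }
  list(hq_hi = rd("hq_hi_by_region.csv"),
       cr_tcr = rd("cr_tcr_by_region.csv"),
       cdi = rd("cdi_by_region.csv"))
}
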