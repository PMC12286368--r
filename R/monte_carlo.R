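#' Input distribution specification
#'
#' One stochastic (or degenerate) input to the Monte Carlo risk model.
#' Supported families and parameters:
#' \describe{
#'   \item{point}{`value`}
#'   \item{normal}{`mean`, `sd` (sd >= 0)}
#'   \item{lognormal}{`meanlog`, `sdlog` (sdlog >= 0)}
#'   \item{triangular}{`lower`, `mode`, `upper` (lower <= mode <= upper)}
#'   \item{uniform}{`min`, `max` (min <= max)}
#' }
#'
#' @param variable label: `"C_<element>"` for a concentration, or one of
#'   `IR`, `EF`, `ED`, `BW`, `AT`.
#' @param family distribution family.
#' @param ... family-specific numeric parameters, named as above.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("C_As", "lognormal", meanlog = 0, sdlog = 0.3)
#' @export
dist_spec <- function(variable,
                      family = c("point", "normal", "lognormal",
                                 "triangular", "uniform"),
                      ...) {
  family <- match.arg(family)
  p <- list(...)
  need <- switch(family,
                 point = "value",
                 normal = c("mean", "sd"),
                 lognormal = c("meanlog", "sdlog"),
                 triangular = c("lower", "mode", "upper"),
                 uniform = c("min", "max"))
  missing_p <- setdiff(need, names(p))
  if (length(missing_p)) {
    stop(family, " family requires parameter(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  p <- p[need]
  if (any(!vapply(p, is.finite, logical(1)))) {
    stop("distribution parameters must be finite", call. = FALSE)
  }
  ok <- switch(family,
               point = TRUE,
               normal = p$sd >= 0,
               lognormal = p$sdlog >= 0,
               triangular = p$lower <= p$mode && p$mode <= p$upper,
               uniform = p$min <= p$max)
  if (!ok) stop("invalid parameters for ", family, " family", call. = FALSE)
  structure(list(variable = variable, family = family, parameters = p),
            class = "dist_spec")
}

# one vector of draws from a dist_spec (RNG state managed by caller)
draw_dist <- function(spec, n) {
  p <- spec$parameters
  switch(spec$family,
         point = rep(p$value, n),
         normal = rnorm(n, p$mean, p$sd),
         lognormal = rlnorm(n, p$meanlog, p$sdlog),
         uniform = runif(n, p$min, p$max),
         triangular = {
           # inverse-CDF sampling; no triangular family in base R
           u <- runif(n)
           r <- p$upper - p$lower
           if (r == 0) rep(p$lower, n) else {
             fc <- (p$mode - p$lower) / r
             ifelse(u < fc,
                    p$lower + sqrt(u * r * (p$mode - p$lower)),
                    p$upper - sqrt((1 - u) * r * (p$upper - p$mode)))
           }
         })
}

#' Fit a distribution to concentration samples
#'
#' Maximum-likelihood fit of the requested family (via `fitdistrplus` for
#' the stochastic families; a `point` family collapses to the common value
#' of a constant sample, or errors otherwise). Censored records are
#' resolved through the [censor_policy()] before fitting.
#'
#' @param samples numeric vector (>= 5 usable values), or a concentration
#'   record data frame, in which case `element`/`stage` select the values.
#' @param family distribution family as in [dist_spec()].
#' @param variable label for the resulting spec.
#' @param element,stage used when `samples` is a record table.
#' @param policy [censor_policy()] for record tables.
#' @return A [dist_spec()].
#' @examples
#' set.seed(1)
#' fit_distribution(rlnorm(1000, 0, 1), "lognormal", "C_As")
#' @export
fit_distribution <- function(samples, family, variable = "x",
                             element = NULL, stage = "bread",
                             policy = censor_policy("exclude")) {
  if (is.data.frame(samples)) {
    usable <- apply_censor_policy(samples, policy)
    if (!is.null(element)) usable <- usable[usable$element == element, ]
    usable <- usable[usable$stage == stage, ]
    samples <- usable$use_value
    if (!is.null(element) && variable == "x") variable <- paste0("C_", element)
  }
  samples <- samples[is.finite(samples)]
  if (family == "point") {
    if (length(samples) < 1 || length(unique(samples)) != 1) {
      stop("point family requires a constant sample", call. = FALSE)
    }
    return(dist_spec(variable, "point", value = samples[1]))
  }
  if (length(samples) < 5) stop("need >= 5 usable samples to fit", call. = FALSE)
  if (family == "lognormal" && any(samples <= 0)) {
    stop("lognormal family requires strictly positive samples", call. = FALSE)
  }
  fit <- fitdistrplus::fitdist(samples,
                               switch(family, normal = "norm",
                                      lognormal = "lnorm",
                                      uniform = "unif",
                                      stop("unsupported family: ", family,
                                           call. = FALSE)))
  est <- as.list(fit$estimate)
  switch(family,
         normal = dist_spec(variable, "normal", mean = est$mean, sd = est$sd),
         lognormal = dist_spec(variable, "lognormal",
                               meanlog = est$meanlog, sdlog = est$sdlog),
         uniform = dist_spec(variable, "uniform", min = est$min, max = est$max))
}

#' Monte Carlo risk simulation
#'
#' Draws every input independently per iteration, evaluates the intake and
#' risk equations, and records HI and TCR. Variables without a spec default
#' to point masses at the cohort's exposure parameters; every element
#' entering HI or TCR must have a `C_<element>` spec. Deterministic given
#' `(dists, n, seed)`; the caller's RNG state is untouched.
#'
#' @param dists list of [dist_spec()] objects (names taken from the specs).
#' @param params a single cohort's [exposure_params()].
#' @param tox toxicity table as [default_tox_profiles()].
#' @param n iteration count (default 10000, the survey's setting).
#' @param seed integer seed.
#' @param carcinogens elements entering TCR.
#' @return An object of class `mc_draws`: `n`, `seed`, `cohort`, `inputs`
#'   (n x variables matrix), `hi`, `tcr`.
#' @export
simulate_risk <- function(dists, params, tox = default_tox_profiles(),
                          n = 10000, seed = 1, carcinogens = c("As", "Cd")) {
  stopifnot(inherits(params, "exposure_params"), n >= 1)
  names(dists) <- vapply(dists, function(d) d$variable, character(1))
  exposure_vars <- c("IR", "EF", "ED", "BW", "AT")
  for (v in exposure_vars) {
    if (is.null(dists[[v]])) {
      dists[[v]] <- dist_spec(v, "point", value = params[[v]])
    }
  }
  conc_vars <- grep("^C_", names(dists), value = TRUE)
  if (!length(conc_vars)) {
    stop("no concentration DistSpec (C_<element>) provided", call. = FALSE)
  }
  elements <- sub("^C_", "", conc_vars)
  unknown <- setdiff(elements, bread_elements())
  if (length(unknown)) {
    stop("unknown element(s) in DistSpecs: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  order_vars <- c(exposure_vars, sort(conc_vars))  # fixed draw order for bit-stability
  inputs <- vapply(order_vars, function(v) draw_dist(dists[[v]], n), numeric(n))
  if (n == 1) inputs <- matrix(inputs, nrow = 1, dimnames = list(NULL, order_vars))

  factor <- inputs[, "IR"] * inputs[, "EF"] * inputs[, "ED"] /
    (inputs[, "BW"] * inputs[, "AT"])
  hi <- rep(0, n)
  tcr <- rep(0, n)
  any_hq <- FALSE
  any_cr <- FALSE
  for (el in elements) {
    cdi <- inputs[, paste0("C_", el)] * factor
    rfd <- tox$rfd[match(el, tox$element)]
    if (!is.na(rfd)) {
      hi <- hi + cdi / rfd
      any_hq <- TRUE
    }
    osf <- tox$osf[match(el, tox$element)]
    if (el %in% carcinogens && !is.na(osf)) {
      tcr <- tcr + cdi * osf
      any_cr <- TRUE
    }
  }
  structure(list(n = n, seed = seed, cohort = params$cohort,
                 inputs = inputs,
                 hi = if (any_hq) hi else rep(NA_real_, n),
                 tcr = if (any_cr) tcr else rep(NA_real_, n)),
            class = "mc_draws")
}

#' Monte Carlo simulation method for risk assessments
#'
#' Builds default input distributions from the fitted object — lognormal
#' fits to the pooled bakery-level bread concentrations of every reported
#' element, point masses for the exposure parameters — and runs
#' [simulate_risk()] for each cohort. Any entry of `dists` overrides the
#' default spec of the same variable.
#'
#' @param object a [risk_assessment()].
#' @param nsim iterations per cohort (default 10000).
#' @param seed integer seed; cohort draws use `seed`, `seed + 1`, ... in
#'   the cohort order of `object$params`.
#' @param dists optional list of [dist_spec()] overrides.
#' @param ... unused.
#' @return Named list of `mc_draws`, one per cohort.
#' @examples
#' fit <- risk_assessment(generate_study(default_study_config(seed = 1)))
#' mc <- simulate(fit, nsim = 500, seed = 42)
#' percentile(mc$adult$hi, 0.95)
#' @export
simulate.risk_assessment <- function(object, nsim = 10000, seed = 1,
                                     dists = NULL, ...) {
  usable <- apply_censor_policy(object$records, object$policy)
  bread <- usable[usable$stage == "bread", ]
  elements <- intersect(bread_elements(), unique(bread$element))
  base <- lapply(elements, function(el) {
    fit_distribution(bread$use_value[bread$element == el], "lognormal",
                     variable = paste0("C_", el))
  })
  names(base) <- paste0("C_", elements)
  if (!is.null(dists)) {
    names(dists) <- vapply(dists, function(d) d$variable, character(1))
    base[names(dists)] <- dists
  }
  out <- list()
  for (i in seq_along(object$params)) {
    p <- object$params[[i]]
    out[[p$cohort]] <- simulate_risk(base, p, tox = object$tox,
                                     n = nsim, seed = seed + i - 1,
                                     carcinogens = object$carcinogens)
  }
  out
}

#' @export
print.mc_draws <- function(x, ...) {
  cat(sprintf("Monte Carlo risk draws: cohort %s, n = %d, seed = %d\n",
              x$cohort, x$n, x$seed))
  cat(sprintf("  HI : median %.4g, P95 %.4g\n",
              percentile(x$hi, 0.5), percentile(x$hi, 0.95)))
  if (!all(is.na(x$tcr))) {
    cat(sprintf("  TCR: median %.4g, P95 %.4g\n",
                percentile(x$tcr, 0.5), percentile(x$tcr, 0.95)))
  }
  invisible(x)
}

#' Empirical percentile of Monte Carlo draws
#'
#' Linear-interpolation quantile (R's default type 7, fixed here for
#' bit-stable reruns).
#'
#' @param draws non-empty numeric vector.
#' @param q fraction strictly between 0 and 1.
#' @return The empirical quantile.
#' @export
percentile <- function(draws, q) {
  draws <- draws[!is.na(draws)]
  if (!length(draws)) stop("no draws", call. = FALSE)
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)", call. = FALSE)
  unname(quantile(draws, q, type = 7))
}

#' Empirical cumulative distribution of draws
#'
#' @param draws non-empty numeric vector.
#' @return Data frame `(value, prob)`: the sorted draws with cumulative
#'   probabilities i/n, preceded by a (min, 0) anchor so the curve spans 0
#'   to 1.
#' @export
cumulative_curve <- function(draws) {
  draws <- draws[!is.na(draws)]
  if (!length(draws)) stop("no draws", call. = FALSE)
  v <- sort(draws)
  data.frame(value = c(v[1], v), prob = c(0, seq_along(v) / length(v)))
}

#' @export
plot.mc_draws <- function(x, endpoint = c("hi", "tcr"), ...) {
  endpoint <- match.arg(endpoint)
  cc <- cumulative_curve(x[[endpoint]])
  plot(cc$value, cc$prob, type = "s", xlab = toupper(endpoint),
       ylab = "Cumulative probability",
       main = sprintf("%s, cohort %s (n = %d)", toupper(endpoint),
                      x$cohort, x$n), ...)
  invisible(x)
}
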