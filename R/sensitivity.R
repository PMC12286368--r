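#' Contribution of each input to output variance
#'
#' Crystal-Ball-style sensitivity measure: the squared Spearman rank
#' correlation between each input and the output, normalised across inputs
#' to sum to 100%. Rank-based, so invariant under monotone rescaling of any
#' input; inputs with zero variance contribute exactly 0; negative
#' associations contribute by their square, with the direction reported
#' separately.
#'
#' @param input_draws matrix or data frame, one column per input, n rows.
#' @param output_draws numeric vector of length n.
#' @return Data frame: `variable`, `contribution_pct`, `sign` (-1, 0, 1),
#'   `rho` (the rank correlation), sorted by descending contribution.
#' @examples
#' set.seed(1)
#' x <- cbind(a = rnorm(1000), b = rnorm(1000))
#' contribution_to_variance(x, x[, "a"] + x[, "b"])
#' @export
contribution_to_variance <- function(input_draws, output_draws) {
  input_draws <- as.matrix(input_draws)
  n <- nrow(input_draws)
  if (n < 10) stop("need at least 10 draws", call. = FALSE)
  if (length(output_draws) != n) {
    stop("input and output draws must have equal length", call. = FALSE)
  }
  vars <- colnames(input_draws)
  if (is.null(vars)) vars <- paste0("x", seq_len(ncol(input_draws)))
  sds <- apply(input_draws, 2, sd)
  if (all(sds == 0)) stop("all inputs are constant", call. = FALSE)
  rho <- rep(0, length(vars))
  active <- sds > 0
  rho[active] <- suppressWarnings(
    cor(input_draws[, active, drop = FALSE], output_draws,
        method = "spearman")[, 1])
  rho[is.na(rho)] <- 0
  contrib <- rho^2
  contrib <- 100 * contrib / sum(contrib)
  out <- data.frame(variable = vars, contribution_pct = contrib,
                    sign = sign(rho), rho = rho, stringsAsFactors = FALSE)
  out <- out[order(-out$contribution_pct), ]
  rownames(out) <- NULL
  out
}

#' Ranked sensitivity table for Monte Carlo risk draws
#'
#' Contribution-to-variance of every stored input for the HI and TCR
#' endpoints, per cohort.
#'
#' @param mc an `mc_draws` object, or a named list of them (one per cohort)
#'   as returned by [simulate.risk_assessment()].
#' @return Data frame: `cohort`, `endpoint` (`HI`/`TCR`), `variable`,
#'   `contribution_pct`, `sign`, sorted by descending contribution within
#'   cohort and endpoint.
#' @export
sensitivity_report <- function(mc) {
  if (inherits(mc, "mc_draws")) mc <- setNames(list(mc), mc$cohort)
  rows <- lapply(mc, function(d) {
    if (is.null(d$inputs)) stop("mc_draws lacks stored input draws", call. = FALSE)
    active <- apply(d$inputs, 2, function(v) sd(v) > 0)
    if (!any(active)) stop("all inputs are constant", call. = FALSE)
    per_endpoint <- function(out, label) {
      if (all(is.na(out))) return(NULL)
      cv <- contribution_to_variance(d$inputs, out)
      data.frame(cohort = d$cohort, endpoint = label,
                 variable = cv$variable,
                 contribution_pct = cv$contribution_pct,
                 sign = cv$sign, stringsAsFactors = FALSE)
    }
    rbind(per_endpoint(d$hi, "HI"), per_endpoint(d$tcr, "TCR"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
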