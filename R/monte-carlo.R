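#' Monte Carlo propagation of concentration and exposure uncertainty
#'
#' Draws `n` independent joint samples of the concentration and of every
#' exposure factor given as a [dist_spec()] (point values are held fixed),
#' pushes them through the dose and risk equations, and returns the simulated
#' risk distribution. The draw order is fixed (C, IR_w, EF_r, ED, BW, SA,
#' K_p, ET), so a given seed always yields the identical output.
#'
#' @param conc_dist a [dist_spec()] for the concentration (ug/L).
#' @param profile an [exposure_profile()]; any factor may be a `dist_spec`.
#' @param tox toxicity table, default [default_toxicity()].
#' @param metal metal name.
#' @param route `"ingestion"` or `"dermal"`.
#' @param endpoint `"HQ"` or `"LTCR"`; LTCR with a dermal route is an error.
#' @param n number of iterations (the study convention is 10,000).
#' @param seed integer seed.
#' @return an object of class `risk_distribution`: `draws` (length `n`),
#'   `inputs` (matrix of the drawn stochastic factors, for sensitivity
#'   analysis) and metadata.
#' @export
simulate_risk <- function(conc_dist, profile, tox = default_toxicity(),
                          metal, route = c("ingestion", "dermal"),
                          endpoint = c("HQ", "LTCR"), n = 10000, seed = 1L) {
  route <- match.arg(route)
  endpoint <- match.arg(endpoint)
  stopifnot(is_dist_spec(conc_dist), inherits(profile, "exposure_profile"),
            n >= 1)
  if (endpoint == "LTCR" && route == "dermal")
    stop("LTCR is computed for the ingestion route only", call. = FALSE)
  set.seed(as.integer(seed))
  factors <- c("IR_w", "EF_r", "ED", "BW", "SA", "K_p", "ET")
  draws <- list(C = dist_draw(conc_dist, n))
  for (nm in factors) {
    v <- profile[[nm]]
    draws[[nm]] <- if (is_dist_spec(v)) dist_draw(v, n) else v
  }
  at <- profile$AT_r
  at <- if (is.null(at)) {
    if (endpoint == "LTCR") 70 * 365 else draws$ED * 365
  } else if (is_dist_spec(at)) dist_draw(at, n) else at
  p <- profile
  for (nm in factors) p[[nm]] <- draws[[nm]]
  p$AT_r <- at
  cdi <- if (route == "ingestion") cdi_ingestion(draws$C, p, endpoint)
         else cdi_dermal(draws$C, p, endpoint)
  risk <- if (endpoint == "HQ") hazard_quotient(cdi, metal, tox, route)
          else lifetime_cancer_risk(cdi, metal, tox)
  stochastic <- c("C", names(Filter(function(nm) is_dist_spec(profile[[nm]]),
                                    stats::setNames(factors, factors))))
  inputs <- do.call(cbind, lapply(stochastic, function(nm) draws[[nm]]))
  colnames(inputs) <- stochastic
  structure(list(draws = as.numeric(risk), inputs = inputs,
                 metal = metal, route = route, endpoint = endpoint,
                 population = profile$population, n = n, seed = seed),
            class = "risk_distribution")
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat(sprintf("<risk_distribution %s %s %s (%s): n = %d, mean = %.4g>\n",
              x$metal, x$endpoint, x$route, x$population, x$n, mean(x$draws)))
  invisible(x)
}

.rd_draws <- function(x) {
  if (inherits(x, "risk_distribution")) x$draws else as.numeric(x)
}

#' Percentile summary of a simulated risk distribution
#'
#' Mean, sample SD and empirical percentiles by sorted-sample linear
#' interpolation (the spreadsheet-default "type 7" convention).
#'
#' @param dist a `risk_distribution` or numeric vector of draws.
#' @param levels percentile levels in percent, strictly inside (0, 100).
#' @return a list with `mean`, `sd`, and `percentiles` (named vector).
#' @export
percentile_summary <- function(dist, levels = c(5, 50, 90, 95, 99, 99.9)) {
  v <- .rd_draws(dist)
  if (any(levels <= 0 | levels >= 100))
    stop("percentile levels must lie strictly inside (0, 100)", call. = FALSE)
  q <- stats::quantile(v, probs = levels / 100, type = 7, names = FALSE)
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       percentiles = stats::setNames(q, paste0("p", levels)))
}

#' Fraction of simulated draws above a threshold
#'
#' Strict inequality; under continuous input distributions ties have
#' probability zero.
#'
#' @param dist a `risk_distribution` or numeric vector.
#' @param threshold exceedance threshold (e.g. 1 for HQ, 1e-4 for LTCR).
#' @return percentage in `[0, 100]`.
#' @export
exceedance_fraction <- function(dist, threshold) {
  v <- .rd_draws(dist)
  100 * sum(v > threshold) / length(v)
}

#' Closed-form exceedance probability of a normal distribution
#'
#' `1 - pnorm((threshold - mean) / sd)`; the analytic oracle against which the
#' Monte Carlo exceedance converges at rate 1/sqrt(n).
#'
#' @param mean,sd normal parameters, `sd > 0`.
#' @param threshold exceedance threshold.
#' @return probability in `[0, 1]`.
#' @export
analytic_exceedance_normal <- function(mean, sd, threshold) {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  stats::pnorm((threshold - mean) / sd, lower.tail = FALSE)
}
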