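#' Signed rank-correlation contributions of inputs to a simulated risk
#'
#' For each stochastic input, the Spearman rank correlation with the output is
#' computed; contributions are reported as signed percentages,
#' `100 * sign(rho) * rho^2 / sum(rho^2)` (squared-correlation shares, the
#' default) or `100 * sign(rho) * |rho| / sum(|rho|)` (linear shares). The
#' absolute contributions sum to 100 and the sign carries the direction of
#' influence: body weight, which divides the dose, comes out negative.
#' Spearman correlation makes the shares invariant under monotone
#' transformation of any input.
#'
#' @param inputs matrix or data frame of per-draw input values (one column
#'   per variable), e.g. the `inputs` element of [simulate_risk()].
#' @param output numeric vector of simulated risk values, same length.
#' @param normalization `"squared"` (default) or `"linear"`.
#' @return data frame with `variable`, `rho` and `contribution_pct`,
#'   ordered by decreasing `|contribution_pct|`.
#' @export
contribution_analysis <- function(inputs, output,
                                  normalization = c("squared", "linear")) {
  normalization <- match.arg(normalization)
  inputs <- as.matrix(inputs)
  if (is.null(colnames(inputs)))
    colnames(inputs) <- paste0("V", seq_len(ncol(inputs)))
  if (nrow(inputs) != length(output))
    stop("inputs and output must have the same number of draws", call. = FALSE)
  if (nrow(inputs) < 10)
    stop("at least 10 draws are required", call. = FALSE)
  if (stats::sd(output) == 0)
    stop("output is constant; nothing to attribute", call. = FALSE)
  rho <- vapply(seq_len(ncol(inputs)), function(j) {
    col <- inputs[, j]
    if (stats::sd(col) == 0) {
      warning("input '", colnames(inputs)[j],
              "' is constant; reported as 0 % contribution", call. = FALSE)
      return(0)
    }
    stats::cor(col, output, method = "spearman")
  }, numeric(1))
  w <- if (normalization == "squared") rho^2 else abs(rho)
  total <- sum(w)
  contrib <- if (total == 0) rep(0, length(w)) else 100 * sign(rho) * w / total
  out <- data.frame(variable = colnames(inputs), rho = rho,
                    contribution_pct = contrib)
  out[order(-abs(out$contribution_pct)), , drop = FALSE]
}

#' Contribution analysis of a simulated risk distribution
#'
#' Convenience wrapper applying [contribution_analysis()] to the stored input
#' draws of a [simulate_risk()] result.
#'
#' @param rd a `risk_distribution`.
#' @param ... passed to [contribution_analysis()].
#' @export
sensitivity_report <- function(rd, ...) {
  stopifnot(inherits(rd, "risk_distribution"))
  contribution_analysis(rd$inputs, rd$draws, ...)
}
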