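#' Pearson correlation matrix of a site-by-parameter table
#'
#' @param data numeric matrix or data frame, observations in rows (typically
#'   one row per sampling location, using replicate means), variables in
#'   columns. At least 3 observations; constant columns are an error because
#'   their correlations are undefined.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("data must be a finite numeric table", call. = FALSE)
  if (nrow(m) < 3) stop("at least 3 observations are required", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  r <- stats::cor(m)
  diag(r) <- 1
  r
}

#' Principal-factor extraction from the correlation matrix
#'
#' Eigen-decomposition of the Pearson correlation matrix (principal-component
#' extraction, unrotated). Loadings are eigenvectors scaled by the square
#' root of their eigenvalue, so squared loadings within a factor sum to that
#' factor's eigenvalue and, with all factors retained, `L %*% t(L)`
#' reconstructs the correlation matrix. Scores are the projections of the
#' z-scored data on the eigenvectors. The sign of each factor is fixed so
#' that its largest-magnitude loading is positive, making results
#' reproducible across platforms.
#'
#' @param data observations x variables table (see [correlation_matrix()]).
#' @param n_factors number of factors to retain, or `"kaiser"` (eigenvalue
#'   greater than 1), or a fraction in (0, 1) interpreted as the minimum
#'   cumulative explained variance.
#' @return an object of class `factor_model` with `eigenvalues` (all, in
#'   decreasing order), `loadings` (variables x retained factors), `scores`
#'   (observations x retained factors), `explained_pct`, `cumulative_pct`
#'   and `n_retained`.
#' @export
extract_factors <- function(data, n_factors = "kaiser") {
  m <- as.matrix(data)
  r <- correlation_matrix(m)
  eg <- eigen(r, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  p <- ncol(m)
  explained <- 100 * ev / p
  k <- if (identical(n_factors, "kaiser")) {
    max(1L, sum(ev > 1))
  } else if (is.numeric(n_factors) && length(n_factors) == 1L &&
             n_factors > 0 && n_factors < 1) {
    which(cumsum(explained) >= 100 * n_factors)[1]
  } else if (is.numeric(n_factors) && n_factors >= 1) {
    if (n_factors > p) stop("cannot retain more factors than variables",
                            call. = FALSE)
    as.integer(n_factors)
  } else stop("invalid n_factors", call. = FALSE)
  vec <- eg$vectors
  # deterministic sign convention
  for (j in seq_len(p)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  load_all <- vec %*% diag(sqrt(ev), nrow = p)
  z <- scale(m)
  scores <- z %*% vec[, seq_len(k), drop = FALSE]
  dimnames(load_all) <- list(colnames(m), paste0("PF", seq_len(p)))
  colnames(scores) <- paste0("PF", seq_len(k))
  rownames(scores) <- rownames(m)
  structure(list(
    eigenvalues = ev,
    loadings = load_all[, seq_len(k), drop = FALSE],
    loadings_full = load_all,
    scores = scores,
    explained_pct = explained,
    cumulative_pct = cumsum(explained),
    n_retained = k), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model: %d factor(s) retained of %d, %.1f%% variance>\n",
              x$n_retained, length(x$eigenvalues),
              x$cumulative_pct[x$n_retained]))
  invisible(x)
}

#' Variable contributions to each retained factor
#'
#' `100 * loading^2 / eigenvalue` per factor, so each column sums to 100.
#'
#' @param model a [extract_factors()] result.
#' @return variables x factors matrix of percentages.
#' @export
variable_contributions <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  k <- model$n_retained
  L <- model$loadings
  sweep(100 * L^2, 2, model$eigenvalues[seq_len(k)], "/")
}

#' Observation contributions to each retained factor
#'
#' `100 * score^2 / sum(score^2)` per factor, so each column sums to 100;
#' identifies the sampling locations that drive a factor.
#'
#' @param model a [extract_factors()] result.
#' @return observations x factors matrix of percentages.
#' @export
observation_contributions <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  s2 <- model$scores^2
  sweep(100 * s2, 2, colSums(s2), "/")
}

#' Location-by-parameter matrix for multivariate analysis
#'
#' Builds the observations x variables table the correlation and factor
#' analyses operate on: one row per location (replicate means), one column
#' per parameter measured in the stratum. Parameters with no measured value
#' anywhere in the stratum (fully not-detected or below detection) and
#' constant columns are dropped.
#'
#' @param samples a [water_samples()] table.
#' @param district,source_type stratum selectors (`NULL` pools).
#' @export
location_matrix <- function(samples, district = NULL, source_type = NULL) {
  stopifnot(inherits(samples, "water_samples"))
  params <- unique(samples$parameter)
  cols <- list()
  for (p in params) {
    rows <- .stratum_rows(samples, p, district, source_type)
    if (!any(rows$flag == "measured")) next
    cols[[p]] <- location_values(samples, p, district, source_type)
  }
  if (!length(cols)) stop("no measured parameters in stratum", call. = FALSE)
  locs <- sort(unique(unlist(lapply(cols, names))))
  m <- vapply(cols, function(v) as.numeric(v[locs]), numeric(length(locs)))
  rownames(m) <- locs
  m <- m[, apply(m, 2, function(col) all(is.finite(col)) && stats::sd(col) > 0),
         drop = FALSE]
  m
}

#' Synthetic two-source mixture with planted factor structure
#'
#' Generates an observations x variables table driven by two independent
#' latent factors (e.g. a geogenic and an industrial source): the first
#' variable block loads on factor 1, the second on factor 2, each with
#' loading `sqrt(communality)` plus independent noise. Used to verify that
#' principal-factor extraction recovers planted structure, in the regime
#' where two retained factors dominate the variance.
#'
#' @param n_obs observations (default 18, the per-district location count).
#' @param n_var variables (default 10); the first `ceiling(0.6 * n_var)`
#'   load on factor 1.
#' @param communality fraction of each variable's variance carried by its
#'   latent factor (default 0.85).
#' @param seed integer seed.
#' @return matrix with attribute `"planted_loading"` (the generating
#'   loading vector assignment).
#' @export
two_source_mixture <- function(n_obs = 18, n_var = 10, communality = 0.85,
                               seed = 1L) {
  stopifnot(n_obs >= 3, n_var >= 2, communality > 0, communality < 1)
  set.seed(as.integer(seed))
  n1 <- ceiling(0.6 * n_var)
  f1 <- stats::rnorm(n_obs)
  f2 <- stats::rnorm(n_obs)
  l <- sqrt(communality)
  e <- matrix(stats::rnorm(n_obs * n_var, sd = sqrt(1 - communality)),
              n_obs, n_var)
  x <- sapply(seq_len(n_var), function(j)
    l * (if (j <= n1) f1 else f2) + e[, j])
  colnames(x) <- paste0("V", seq_len(n_var))
  attr(x, "planted_loading") <- rep(c(1L, 2L), c(n1, n_var - n1))
  x
}
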