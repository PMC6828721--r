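#' Parametric distribution specification
#'
#' A `dist_spec` describes one random input of the risk model: a concentration
#' or an exposure factor. Supported families are `point` (degenerate),
#' `normal`, `lognormal`, `uniform` and `triangular`, each with optional
#' truncation bounds. Truncation is applied by restricting the CDF, i.e. the
#' spec describes the conditional distribution on `[lower, upper]`.
#'
#' @param family one of `"point"`, `"normal"`, `"lognormal"`, `"uniform"`,
#'   `"triangular"`.
#' @param ... family parameters: `value` (point); `mean`, `sd` (normal);
#'   `meanlog`, `sdlog` (lognormal); `min`, `max` (uniform); `min`, `mode`,
#'   `max` (triangular).
#' @param lower,upper optional truncation bounds (`lower < upper`; the
#'   truncated region must carry positive probability).
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal", meanlog = 0, sdlog = 1, lower = 0.5, upper = 4)
#' @export
dist_spec <- function(family = c("point", "normal", "lognormal", "uniform", "triangular"),
                      ..., lower = -Inf, upper = Inf) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
    point = "value",
    normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    uniform = c("min", "max"),
    triangular = c("min", "mode", "max"))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("dist_spec('", family, "') requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  params <- params[need]
  for (p in need)
    if (!is.numeric(params[[p]]) || length(params[[p]]) != 1L || !is.finite(params[[p]]))
      stop("parameter '", p, "' must be a single finite number", call. = FALSE)
  if (family == "normal" && params$sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (family == "lognormal" && params$sdlog < 0) stop("sdlog must be >= 0", call. = FALSE)
  if (family == "uniform" && params$min >= params$max)
    stop("uniform requires min < max", call. = FALSE)
  if (family == "triangular" &&
      !(params$min <= params$mode && params$mode <= params$max && params$min < params$max))
    stop("triangular requires min <= mode <= max and min < max", call. = FALSE)
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1L || length(upper) != 1L)
    stop("truncation bounds must be single numbers", call. = FALSE)
  if (lower >= upper) stop("truncation requires lower < upper", call. = FALSE)
  obj <- structure(list(family = family, params = params,
                        lower = lower, upper = upper),
                   class = "dist_spec")
  if (is.finite(lower) || is.finite(upper)) {
    mass <- .spec_mass(obj)
    if (!is.finite(mass) || mass <= 0)
      stop("truncation interval carries no probability mass", call. = FALSE)
  }
  obj
}

## truncation bounds on the standard-normal z scale (normal/lognormal only)
.trunc_z <- function(spec) {
  p <- spec$params
  if (spec$family == "normal") {
    if (p$sd == 0) return(NULL)
    c((spec$lower - p$mean) / p$sd, (spec$upper - p$mean) / p$sd)
  } else if (spec$family == "lognormal") {
    if (p$sdlog == 0) return(NULL)
    lo <- if (spec$lower <= 0) -Inf else (log(spec$lower) - p$meanlog) / p$sdlog
    hi <- if (is.infinite(spec$upper)) Inf else
      (log(spec$upper) - p$meanlog) / p$sdlog
    c(lo, hi)
  } else NULL
}

## probability mass of the truncation interval, stable deep in either tail
.spec_mass <- function(spec) {
  z <- .trunc_z(spec)
  if (!is.null(z)) return(.dphi(z[1], z[2]))
  .spec_cdf(spec, spec$upper) - .spec_cdf(spec, spec$lower)
}

## truncated standard-normal draws; works via survival probabilities when the
## interval lies deep in the right tail, where pnorm() rounds to 1
.rtruncz <- function(n, al, be) {
  if (al > 0) {
    u <- stats::runif(n, stats::pnorm(be, lower.tail = FALSE),
                      stats::pnorm(al, lower.tail = FALSE))
    stats::qnorm(u, lower.tail = FALSE)
  } else {
    u <- stats::runif(n, stats::pnorm(al), stats::pnorm(be))
    stats::qnorm(u)
  }
}

## deterministic quantiles of the truncated standard normal at probs p
.qtruncz <- function(p, al, be) {
  if (al > 0) {
    s_al <- stats::pnorm(al, lower.tail = FALSE)
    s_be <- stats::pnorm(be, lower.tail = FALSE)
    stats::qnorm(s_al - p * (s_al - s_be), lower.tail = FALSE)
  } else {
    f_al <- stats::pnorm(al); f_be <- stats::pnorm(be)
    stats::qnorm(f_al + p * (f_be - f_al))
  }
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- paste(names(x$params), signif(unlist(x$params), 6), sep = " = ", collapse = ", ")
  tr <- if (is.finite(x$lower) || is.finite(x$upper))
    sprintf(" | [%g, %g]", x$lower, x$upper) else ""
  cat(sprintf("<dist_spec %s(%s)%s>\n", x$family, p, tr))
  invisible(x)
}

#' Test whether an object is a distribution specification
#'
#' @param x any object.
#' @export
is_dist_spec <- function(x) inherits(x, "dist_spec")

## triangular CDF / quantile (closed form)
.ptri <- function(q, mn, md, mx) {
  p <- numeric(length(q))
  p[q >= mx] <- 1
  i <- q > mn & q < md
  p[i] <- (q[i] - mn)^2 / ((mx - mn) * (md - mn))
  i <- q >= md & q < mx
  p[i] <- 1 - (mx - q[i])^2 / ((mx - mn) * (mx - md))
  p
}
.qtri <- function(p, mn, md, mx) {
  pm <- (md - mn) / (mx - mn)
  ifelse(p <= pm,
         mn + sqrt(p * (mx - mn) * (md - mn)),
         mx - sqrt((1 - p) * (mx - mn) * (mx - md)))
}

.spec_cdf <- function(spec, q) {
  p <- spec$params
  switch(spec$family,
    point = as.numeric(q >= p$value),
    normal = stats::pnorm(q, p$mean, p$sd),
    lognormal = stats::plnorm(q, p$meanlog, p$sdlog),
    uniform = stats::punif(q, p$min, p$max),
    triangular = .ptri(q, p$min, p$mode, p$max))
}

.spec_quantile_raw <- function(spec, u) {
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, length(u)),
    normal = stats::qnorm(u, p$mean, p$sd),
    lognormal = stats::qlnorm(u, p$meanlog, p$sdlog),
    uniform = stats::qunif(u, p$min, p$max),
    triangular = .qtri(u, p$min, p$mode, p$max))
}

#' Draw random variates from a distribution specification
#'
#' Truncated draws use the inverse-CDF method restricted to
#' `[F(lower), F(upper)]`, so no draw can ever violate the bounds.
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
dist_draw <- function(spec, n) {
  stopifnot(is_dist_spec(spec), is.numeric(n), length(n) == 1L, n >= 0)
  if (n == 0) return(numeric(0))
  if (spec$family == "point") return(rep(spec$params$value, n))
  z <- .trunc_z(spec)
  x <- if (!is.null(z)) {
    zz <- .rtruncz(n, z[1], z[2])
    p <- spec$params
    if (spec$family == "normal") p$mean + p$sd * zz
    else exp(p$meanlog + p$sdlog * zz)
  } else {
    plo <- .spec_cdf(spec, spec$lower)
    phi <- .spec_cdf(spec, spec$upper)
    .spec_quantile_raw(spec, stats::runif(n, plo, phi))
  }
  # guard against floating-point spill at the bounds
  pmin(pmax(x, spec$lower), spec$upper)
}

#' Quantile function of a distribution specification
#'
#' @param spec a [dist_spec()].
#' @param probs probabilities in `[0, 1]` (within the truncated distribution).
#' @export
dist_quantile <- function(spec, probs) {
  stopifnot(is_dist_spec(spec), all(probs >= 0 & probs <= 1))
  if (spec$family == "point") return(rep(spec$params$value, length(probs)))
  z <- .trunc_z(spec)
  x <- if (!is.null(z)) {
    zz <- .qtruncz(probs, z[1], z[2])
    p <- spec$params
    if (spec$family == "normal") p$mean + p$sd * zz
    else exp(p$meanlog + p$sdlog * zz)
  } else {
    plo <- .spec_cdf(spec, spec$lower)
    phi <- .spec_cdf(spec, spec$upper)
    .spec_quantile_raw(spec, plo + probs * (phi - plo))
  }
  pmin(pmax(x, spec$lower), spec$upper)
}

## stable difference of standard-normal CDF values (uses upper tails when both
## arguments are deep in the right tail, where pnorm(x) rounds to 1)
.dphi <- function(lo, hi) {
  if (lo > 0)
    stats::pnorm(lo, lower.tail = FALSE) - stats::pnorm(hi, lower.tail = FALSE)
  else
    stats::pnorm(hi) - stats::pnorm(lo)
}

## k-th raw moment of a lognormal(meanlog, sdlog) truncated to [a, b]
.tlnorm_moment <- function(meanlog, sdlog, a, b, k = 1) {
  if (sdlog == 0) return(exp(k * meanlog))
  al <- if (a <= 0) -Inf else (log(a) - meanlog) / sdlog
  be <- if (is.infinite(b)) Inf else (log(b) - meanlog) / sdlog
  exp(k * meanlog + k^2 * sdlog^2 / 2) *
    .dphi(al - k * sdlog, be - k * sdlog) / .dphi(al, be)
}

#' Analytic mean and standard deviation of a distribution specification
#'
#' Closed forms for all families; truncation is handled analytically for the
#' normal and lognormal families (the ones the generator and the risk engine
#' use). Truncated uniform reduces to a uniform; truncated triangular is not
#' supported.
#'
#' @param spec a [dist_spec()].
#' @return for `dist_mean` / `dist_sd`, a single number.
#' @export
dist_mean <- function(spec) {
  stopifnot(is_dist_spec(spec))
  p <- spec$params
  trunc <- is.finite(spec$lower) || is.finite(spec$upper)
  switch(spec$family,
    point = p$value,
    uniform = {
      lo <- max(p$min, spec$lower); hi <- min(p$max, spec$upper)
      (lo + hi) / 2
    },
    triangular = {
      if (trunc) stop("truncated triangular moments are not supported", call. = FALSE)
      (p$min + p$mode + p$max) / 3
    },
    normal = {
      if (!trunc) return(p$mean)
      if (p$sd == 0) return(p$mean)
      al <- (spec$lower - p$mean) / p$sd
      be <- (spec$upper - p$mean) / p$sd
      z <- .dphi(al, be)
      p$mean + p$sd * (stats::dnorm(al) - stats::dnorm(be)) / z
    },
    lognormal = {
      a <- max(spec$lower, 0); b <- spec$upper
      if (!trunc) exp(p$meanlog + p$sdlog^2 / 2)
      else .tlnorm_moment(p$meanlog, p$sdlog, a, b, 1)
    })
}

#' @rdname dist_mean
#' @export
dist_sd <- function(spec) {
  stopifnot(is_dist_spec(spec))
  p <- spec$params
  trunc <- is.finite(spec$lower) || is.finite(spec$upper)
  switch(spec$family,
    point = 0,
    uniform = {
      lo <- max(p$min, spec$lower); hi <- min(p$max, spec$upper)
      (hi - lo) / sqrt(12)
    },
    triangular = {
      if (trunc) stop("truncated triangular moments are not supported", call. = FALSE)
      sqrt((p$min^2 + p$mode^2 + p$max^2 - p$min * p$mode -
            p$min * p$max - p$mode * p$max) / 18)
    },
    normal = {
      if (!trunc) return(p$sd)
      if (p$sd == 0) return(0)
      al <- (spec$lower - p$mean) / p$sd
      be <- (spec$upper - p$mean) / p$sd
      z <- .dphi(al, be)
      dal <- stats::dnorm(al); dbe <- stats::dnorm(be)
      t1 <- if (is.finite(al)) al * dal else 0
      t2 <- if (is.finite(be)) be * dbe else 0
      v <- 1 + (t1 - t2) / z - ((dal - dbe) / z)^2
      p$sd * sqrt(max(v, 0))
    },
    lognormal = {
      a <- max(spec$lower, 0); b <- spec$upper
      m1 <- if (!trunc) exp(p$meanlog + p$sdlog^2 / 2)
            else .tlnorm_moment(p$meanlog, p$sdlog, a, b, 1)
      m2 <- if (!trunc) exp(2 * p$meanlog + 2 * p$sdlog^2)
            else .tlnorm_moment(p$meanlog, p$sdlog, a, b, 2)
      sqrt(max(m2 - m1^2, 0))
    })
}

#' Fit a lognormal distribution to a mean and standard deviation
#'
#' Moment inversion: `sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`, so the analytic mean and SD of the
#' returned spec equal the inputs exactly. `sd = 0` returns a point mass.
#'
#' @param mean,sd target moments; `mean > 0`, `sd >= 0`.
#' @return a `dist_spec` (`lognormal`, or `point` when `sd = 0`).
#' @export
fit_lognormal_from_summary <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L, length(sd) == 1L)
  if (!is.finite(mean) || mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) return(dist_spec("point", value = mean))
  s2 <- log(1 + (sd / mean)^2)
  dist_spec("lognormal", meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Fit a normal distribution to two symmetric percentiles
#'
#' For symmetric levels `(l, 1 - l)` the mean is the midpoint and the SD is
#' `(p_high - p_low) / (2 * qnorm(1 - l))`.
#'
#' @param p_low,p_high percentile values, `p_low < p_high`.
#' @param levels the two probability levels (default 5th and 95th).
#' @export
fit_normal_from_percentiles <- function(p_low, p_high, levels = c(0.05, 0.95)) {
  stopifnot(length(levels) == 2L, all(levels > 0 & levels < 1))
  if (!is.finite(p_low) || !is.finite(p_high) || p_low >= p_high)
    stop("requires p_low < p_high", call. = FALSE)
  if (abs(levels[1] + levels[2] - 1) > 1e-12)
    stop("levels must be symmetric (l, 1 - l)", call. = FALSE)
  z <- stats::qnorm(levels[2])
  dist_spec("normal", mean = (p_low + p_high) / 2, sd = (p_high - p_low) / (2 * z))
}

#' Fit a lognormal distribution to two symmetric percentiles
#'
#' The normal fit of [fit_normal_from_percentiles()] applied on the log scale;
#' used for right-skewed outputs whose printed 5th/95th percentiles are not
#' symmetric about the printed mean.
#'
#' @inheritParams fit_normal_from_percentiles
#' @export
fit_lognormal_from_percentiles <- function(p_low, p_high, levels = c(0.05, 0.95)) {
  if (!is.finite(p_low) || p_low <= 0) stop("p_low must be > 0", call. = FALSE)
  n <- fit_normal_from_percentiles(log(p_low), log(p_high), levels)
  dist_spec("lognormal", meanlog = n$params$mean, sdlog = n$params$sd)
}

#' Fit a truncated lognormal to a target mean and SD within bounds
#'
#' Finds a lognormal, truncated to `[lower, upper]`, whose truncated mean
#' equals `mean` exactly (1-D root solve in `meanlog` for each candidate
#' `sdlog`) and whose truncated SD is as close as possible to `sd`. When the
#' target mean lies very close to one bound, no member of the family attains
#' the full target SD; the fit is then mean-exact with the best achievable SD.
#'
#' @param mean,sd target stratum moments (`lower < mean < upper`, `sd >= 0`).
#' @param lower,upper truncation bounds, `0 <= lower < upper`.
#' @return a truncated lognormal `dist_spec` with attribute `"achieved_sd"`.
#' @export
fit_truncated_lognormal <- function(mean, sd, lower, upper) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, lower >= 0, lower < upper)
  if (mean <= lower || mean >= upper)
    stop("infeasible stratum: mean must lie strictly inside (lower, upper)",
         call. = FALSE)
  if (sd == 0)
    return(structure(dist_spec("point", value = mean), achieved_sd = 0))
  if (!is.finite(upper) && lower == 0) {
    spec <- fit_lognormal_from_summary(mean, sd)
    attr(spec, "achieved_sd") <- sd
    return(spec)
  }
  la <- if (lower > 0) log(lower) else log(mean) - 50
  lb <- if (is.finite(upper)) log(upper) else log(mean) + 50
  solve_meanlog <- function(sdlog) {
    lo <- la - min(30 * sdlog, 30)
    hi <- lb + min(30 * sdlog, 30)
    f <- function(m) .tlnorm_moment(m, sdlog, lower, upper, 1) - mean
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
  }
  sd_gap <- function(lsd) {
    sdlog <- exp(lsd)
    m <- solve_meanlog(sdlog)
    if (is.na(m)) return(1e300 * (1 + abs(lsd)))
    m2 <- .tlnorm_moment(m, sdlog, lower, upper, 2)
    g <- (sqrt(max(m2 - mean^2, 0)) - sd)^2
    if (!is.finite(g)) 1e300 * (1 + abs(lsd)) else g
  }
  opt <- stats::optimize(sd_gap, c(log(1e-4), log(5)), tol = 1e-10)
  sdlog <- exp(opt$minimum)
  meanlog <- solve_meanlog(sdlog)
  if (is.na(meanlog)) {
    # the golden-section search stalled in the infeasible region; fall back
    # to the best feasible point on a log-spaced grid
    grid <- seq(log(1e-4), log(5), length.out = 80)
    vals <- vapply(grid, sd_gap, numeric(1))
    sdlog <- exp(grid[which.min(vals)])
    meanlog <- solve_meanlog(sdlog)
  }
  if (is.na(meanlog)) stop("truncated lognormal fit failed to converge", call. = FALSE)
  spec <- dist_spec("lognormal", meanlog = meanlog, sdlog = sdlog,
                    lower = lower, upper = upper)
  m2 <- .tlnorm_moment(meanlog, sdlog, lower, upper, 2)
  attr(spec, "achieved_sd") <- sqrt(max(m2 - mean^2, 0))
  spec
}

## serialize a dist_spec (or plain number) to a config token and back;
## numbers are written with 17 significant digits so round-trips are lossless
.spec_serialize <- function(x) {
  fmt <- function(v) format(v, digits = 17, scientific = TRUE, trim = TRUE)
  if (is.numeric(x)) return(fmt(x))
  stopifnot(is_dist_spec(x))
  parts <- paste(names(x$params), vapply(x$params, fmt, ""), sep = "=")
  if (is.finite(x$lower) || is.finite(x$upper))
    parts <- c(parts, paste0("lower=", fmt(x$lower)), paste0("upper=", fmt(x$upper)))
  paste0(x$family, "(", paste(parts, collapse = ", "), ")")
}

.spec_deserialize <- function(token) {
  token <- trimws(token)
  if (grepl("^[-+0-9.eE]+$", token)) return(as.numeric(token))
  m <- regmatches(token, regexec("^([a-z]+)\\((.*)\\)$", token))[[1]]
  if (length(m) != 3L) stop("cannot parse distribution token: ", token, call. = FALSE)
  kv <- strsplit(strsplit(m[3], ",")[[1]], "=")
  vals <- lapply(kv, function(p) as.numeric(trimws(p[2])))
  names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
  lower <- if (!is.null(vals$lower)) vals$lower else -Inf
  upper <- if (!is.null(vals$upper)) vals$upper else Inf
  vals$lower <- NULL; vals$upper <- NULL
  do.call(dist_spec, c(list(family = m[2]), vals, list(lower = lower, upper = upper)))
}
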