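test_that("lognormal moment fit round-trips mean and sd analytically", {
  cases <- list(c(1.108, 0.504), c(13, 5.9), c(3906, 515), c(0.000065, 1.2e-5))
  for (cs in cases) {
    spec <- fit_lognormal_from_summary(cs[1], cs[2])
    expect_equal(dist_mean(spec), cs[1], tolerance = 1e-12)
    expect_equal(dist_sd(spec), cs[2], tolerance = 1e-12)
  }
  expect_identical(fit_lognormal_from_summary(1, 0)$family, "point")
  expect_error(fit_lognormal_from_summary(-1, 1), "mean")
})

test_that("large lognormal samples reproduce the fitted mean within 3 SE", {
  spec <- fit_lognormal_from_summary(1.108, 0.504)
  set.seed(101)
  x <- dist_draw(spec, 1e6)
  se <- dist_sd(spec) / sqrt(1e6)
  expect_lt(abs(mean(x) - 1.108), 3 * se)
})

test_that("normal fit from symmetric percentiles inverts the printed pair", {
  std <- fit_normal_from_percentiles(qnorm(0.05), qnorm(0.95))
  expect_equal(std$params$mean, 0, tolerance = 1e-12)
  expect_equal(std$params$sd, 1, tolerance = 1e-12)

  ni <- fit_normal_from_percentiles(0.000089, 0.000173)
  expect_equal(ni$params$mean, 0.000131, tolerance = 1e-12)
  expect_equal(ni$params$sd, (0.000173 - 0.000089) / (2 * qnorm(0.95)),
               tolerance = 1e-12)
  # the spec's own 5th/95th percentiles reproduce the inputs
  expect_equal(dist_quantile(ni, c(0.05, 0.95)), c(0.000089, 0.000173),
               tolerance = 1e-12)
  expect_error(fit_normal_from_percentiles(2, 1), "p_low < p_high")
})

test_that("lognormal percentile fit matches quantiles and skews right", {
  spec <- fit_lognormal_from_percentiles(0.000047, 0.000088)
  expect_equal(dist_quantile(spec, c(0.05, 0.95)), c(0.000047, 0.000088),
               tolerance = 1e-12)
  # right skew: mean above median
  expect_gt(dist_mean(spec), dist_quantile(spec, 0.5))
})

test_that("truncated lognormal fit is mean-exact for feasible strata", {
  cases <- list(
    c(mean = 13, sd = 5.9, lo = 11.7, hi = 427.2),    # mean near lower bound
    c(mean = 1319, sd = 574, lo = 142, hi = 2221),
    c(mean = 88, sd = 13.4, lo = 47.3, hi = 239.7),
    c(mean = 440.056, sd = 187.55, lo = 163.48, hi = 773.43),
    c(mean = 6.67, sd = 0.577, lo = 5.25, hi = 7.65))
  for (cs in cases) {
    spec <- fit_truncated_lognormal(cs["mean"], cs["sd"], cs["lo"], cs["hi"])
    expect_equal(unname(dist_mean(spec)), unname(cs["mean"]), tolerance = 1e-8)
    expect_equal(unname(attr(spec, "achieved_sd")), dist_sd(spec),
                 tolerance = 1e-8)
  }
  expect_error(fit_truncated_lognormal(5, 1, 10, 20), "infeasible")
})

test_that("no draw ever violates its truncation bounds", {
  set.seed(2024)
  for (i in 1:25) {
    lo <- runif(1, 0.1, 50)
    hi <- lo * runif(1, 1.2, 50)
    m <- runif(1, lo * 1.01, hi * 0.99)
    s <- runif(1, 0.05, 1.5) * m
    spec <- fit_truncated_lognormal(m, s, lo, hi)
    x <- dist_draw(spec, 500)
    expect_true(all(x >= lo & x <= hi))
  }
  # deep right-tail truncation must not produce non-finite draws
  spec <- dist_spec("lognormal", meanlog = -5, sdlog = 0.3,
                    lower = 11.7, upper = 427.2)
  x <- dist_draw(spec, 200)
  expect_true(all(is.finite(x) & x >= 11.7 & x <= 427.2))
})

test_that("draws are deterministic for a fixed seed", {
  spec <- dist_spec("triangular", min = 0, mode = 2, max = 5)
  set.seed(7); a <- dist_draw(spec, 100)
  set.seed(7); b <- dist_draw(spec, 100)
  expect_identical(a, b)
})

test_that("triangular and uniform moments agree with closed forms", {
  tri <- dist_spec("triangular", min = 0, mode = 2, max = 5)
  expect_equal(dist_mean(tri), 7 / 3, tolerance = 1e-12)
  set.seed(5)
  x <- dist_draw(tri, 2e5)
  expect_lt(abs(mean(x) - dist_mean(tri)), 4 * dist_sd(tri) / sqrt(2e5))
  uni <- dist_spec("uniform", min = 180, max = 365)
  expect_equal(dist_mean(uni), 272.5)
  expect_equal(dist_sd(uni), (365 - 180) / sqrt(12))
})

test_that("distribution specs serialize to config tokens and back losslessly", {
  specs <- list(
    dist_spec("lognormal", meanlog = log(2) - 0.01, sdlog = 0.1492,
              lower = 0.4, upper = 6),
    dist_spec("uniform", min = 180, max = 365),
    dist_spec("normal", mean = 70, sd = 8.4, lower = 28, upper = 140),
    dist_spec("point", value = 0.001))
  for (s in specs) {
    rt <- aquarisk:::.spec_deserialize(aquarisk:::.spec_serialize(s))
    expect_identical(rt$family, s$family)
    expect_equal(rt$params, s$params, tolerance = 0)
    expect_identical(c(rt$lower, rt$upper), c(s$lower, s$upper))
  }
})
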