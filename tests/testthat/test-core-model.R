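make_fixture_csv <- function() {
  make_wide_csv(c(
    "location_id,district,source_type,replicate,x,y,pH,Pb[mg/L],Cr[mg/L],Cd[ug/L]",
    "IJB1,Iju,borehole,1,1.0,2.0,6.5,0.0117,<0.00001,ND",
    "IJB1,Iju,borehole,2,1.0,2.0,6.4,0.0130,<0.00001,ND",
    "IJB2,Iju,borehole,1,1.5,2.5,7.0,0.0500,0.0044,ND"))
}

test_that("CSV ingest converts units and records detection flags", {
  s <- read_sample_table(make_fixture_csv())
  expect_s3_class(s, "water_samples")
  pb <- s[s$parameter == "Pb", ]
  # mg/L converted to the canonical ug/L
  expect_equal(sort(pb$value), c(11.7, 13.0, 50.0))
  cr <- s[s$parameter == "Cr" & s$location_id == "IJB1", ]
  expect_true(all(cr$flag == "below_detection"))
  expect_equal(unique(cr$detection_limit), 0.01)  # 0.00001 mg/L -> ug/L
  cd <- s[s$parameter == "Cd", ]
  expect_true(all(cd$flag == "not_detected"))
})

test_that("header-only tables give an empty dataset and bad cells fail loudly", {
  empty <- read_sample_table(make_wide_csv(
    "location_id,district,source_type,replicate,x,y,Pb[ug/L]"))
  expect_equal(nrow(empty), 0)

  bad <- make_wide_csv(c(
    "location_id,district,source_type,replicate,x,y,Pb[ug/L]",
    "A1,Atan,well,1,0,0,oops"))
  expect_error(read_sample_table(bad), "Pb")

  dup <- make_wide_csv(c(
    "location_id,district,source_type,replicate,x,y,Pb[ug/L]",
    "A1,Atan,well,1,0,0,5",
    "A1,Atan,well,1,0,0,6"))
  expect_error(read_sample_table(dup), "duplicate")
})

test_that("write/read round-trip preserves values and flags", {
  s <- read_sample_table(make_fixture_csv())
  path <- tempfile(fileext = ".csv")
  write_sample_table(s, path)
  s2 <- read_sample_table(path)
  key <- function(d) order(d$location_id, d$replicate, d$parameter)
  expect_equal(s$value[key(s)], s2$value[key(s2)], tolerance = 1e-12)
  expect_identical(s$flag[key(s)], s2$flag[key(s2)])
})

test_that("stratum summaries match hand arithmetic and a two-pass oracle", {
  df <- data.frame(location_id = c("A", "B", "C"), district = "Atan",
                   source_type = "well", replicate = 1L, x = 0, y = 0,
                   parameter = "Pb", value = c(1, 2, 3), flag = "measured",
                   detection_limit = NA_real_)
  s <- water_samples(df)
  st <- summarize_stratum(s, "Pb")
  expect_equal(st[c("mean", "sd", "min", "max")],
               list(mean = 2, sd = 1, min = 1, max = 3))

  set.seed(31)
  v <- rlnorm(100, 2, 0.7)
  df2 <- df[rep(1, 100), ]
  df2$location_id <- sprintf("L%03d", 1:100)
  df2$value <- v
  st2 <- summarize_stratum(water_samples(df2), "Pb")
  o <- oracle_mean_sd(v)
  expect_equal(st2$mean, o$mean, tolerance = 1e-12)
  expect_equal(st2$sd, o$sd, tolerance = 1e-12)
  expect_error(summarize_stratum(s, "Pb", district = "Iju"), "stratum")
})

test_that("duplicating a dataset leaves mean, min and max unchanged", {
  set.seed(47)
  df <- data.frame(location_id = sprintf("L%02d", 1:20), district = "Atan",
                   source_type = "well", replicate = 1L, x = 0, y = 0,
                   parameter = "Fe", value = rlnorm(20, 2, 0.5),
                   flag = "measured", detection_limit = NA_real_)
  twice <- df; twice$replicate <- 2L
  a <- summarize_stratum(water_samples(df), "Fe")
  b <- summarize_stratum(water_samples(rbind(df, twice)), "Fe")
  expect_equal(b[c("mean", "min", "max")], a[c("mean", "min", "max")])
  # sample (n-1) convention: the SD shrinks by the known finite-sample factor
  expect_equal(b$sd, a$sd * sqrt((19 / 20) * (40 / 39)), tolerance = 1e-12)
})

test_that("below-detection values enter summaries at half the detection limit", {
  df <- data.frame(location_id = c("A", "B"), district = "Iju",
                   source_type = "borehole", replicate = 1L, x = 0, y = 0,
                   parameter = "Cr", value = c(8, NA),
                   flag = c("measured", "below_detection"),
                   detection_limit = c(NA, 0.01))
  st <- summarize_stratum(water_samples(df), "Cr")
  expect_equal(st$n, 2)
  expect_equal(st$min, 0.005)
  expect_equal(st$mean, (8 + 0.005) / 2)
})

test_that("violation rates are exact location-level ratios", {
  mk <- function(vals) {
    n <- length(vals)
    water_samples(data.frame(
      location_id = rep(sprintf("ATB%d", 1:n), each = 3),
      district = "Atan", source_type = "borehole",
      replicate = rep(1:3, n), x = 0, y = 0, parameter = "Pb",
      value = rep(vals, each = 3), flag = "measured",
      detection_limit = NA_real_))
  }
  nine <- mk(c(20, 30, 15, 12, 5, 8, 2, 9, 1))  # 4 of 9 above 10
  expect_equal(violation_rate(nine, "Pb", 10), 400 / 9)
  expect_equal(violation_rate(mk(rep(1, 9)), "Pb", 10), 0)
  expect_equal(violation_rate(mk(rep(100, 9)), "Pb", 10), 100)
  expect_error(violation_rate(nine, "Zn", 10), "unknown parameter")

  # invariance under reordering and joint rescaling of values and limit
  shuf <- nine[sample(nrow(nine)), ]
  expect_equal(violation_rate(water_samples(shuf), "Pb", 10),
               violation_rate(nine, "Pb", 10))
  scaled <- nine; scaled$value <- scaled$value * 1000
  expect_equal(violation_rate(water_samples(scaled), "Pb", 10 * 1000),
               violation_rate(nine, "Pb", 10))
})

test_that("replicate averaging drives violation accounting", {
  # one location whose replicates straddle the limit but average below it
  s <- water_samples(data.frame(
    location_id = "ATB1", district = "Atan", source_type = "borehole",
    replicate = 1:3, x = 0, y = 0, parameter = "Pb",
    value = c(12, 9, 8), flag = "measured", detection_limit = NA_real_))
  expect_equal(violation_rate(s, "Pb", 10), 0)
})

test_that("correlation strength classes use the quoted boundaries on |r|", {
  expect_identical(classify_correlation(0.9125), "strong")
  expect_identical(classify_correlation(0.6738), "moderate")
  expect_identical(classify_correlation(0.4999), "weak")
  expect_identical(classify_correlation(c(0.5, 0.6999, 0.7)),
                   c("moderate", "moderate", "strong"))
  r <- runif(20, -1, 1)
  expect_identical(classify_correlation(-r), classify_correlation(r))
  expect_error(classify_correlation(1.2), "\\[-1, 1\\]")
})

test_that("guideline lookups error on absent entries instead of returning zero", {
  g <- default_guidelines()
  expect_equal(guideline_limit(g, "Pb", "WHO"), 10)
  expect_error(guideline_limit(g, "TDS", "NSDWQ"), "no NSDWQ")
})
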