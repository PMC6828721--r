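test_that("the default design yields 108 samples from 36 locations", {
  s <- generate_study_dataset(7)
  ids <- unique(s[c("location_id", "replicate")])
  expect_equal(nrow(ids), 108)
  expect_equal(length(unique(s$location_id)), 36)
  expect_setequal(unique(s$district), c("Atan", "Iju"))
  # reading the written fixture reproduces the structure
  path <- tempfile(fileext = ".csv")
  write_sample_table(s, path)
  s2 <- read_sample_table(path)
  expect_equal(nrow(unique(s2[c("location_id", "replicate")])), 108)
})

test_that("generation is deterministic and strata are seed-independent", {
  a <- generate_study_dataset(123)
  b <- generate_study_dataset(123)
  expect_identical(a, b)
  c <- generate_study_dataset(124)
  expect_false(identical(a$value, c$value))
})

test_that("every generated value respects its stratum bounds", {
  s <- generate_study_dataset(99)
  specs <- default_district_specs()
  for (d in names(specs)) {
    prm <- specs[[d]]$params
    for (i in seq_len(nrow(prm))) {
      p <- prm[i, ]
      if (p$status != "measured") next
      srcs <- if (p$source_type == "both") c("borehole", "well") else p$source_type
      for (src in srcs) {
        v <- s$value[s$district == d & s$parameter == p$parameter &
                     s$source_type == src & s$flag == "measured"]
        expect_true(all(v >= p$min & v <= p$max),
                    info = paste(d, src, p$parameter))
      }
    }
  }
})

test_that("detection status is propagated per the study design", {
  s <- generate_study_dataset(5)
  expect_true(all(s$flag[s$parameter %in% c("Cu", "Cd")] == "not_detected"))
  cr_bh <- s[s$parameter == "Cr" & s$district == "Iju" &
             s$source_type == "borehole", ]
  expect_true(all(cr_bh$flag == "below_detection"))
  expect_true(all(cr_bh$detection_limit == 0.01))
  cr_w <- s[s$parameter == "Cr" & s$district == "Iju" &
            s$source_type == "well", ]
  expect_true(all(cr_w$flag == "measured"))
  expect_true(all(s$flag[s$parameter == "Cr" & s$district == "Atan"] ==
                  "not_detected"))
})

test_that("stratum means are recovered at the design size and tightly at scale", {
  specs <- default_district_specs()
  iju <- specs$Iju
  target <- iju$params[iju$params$parameter == "Ni" &
                       iju$params$source_type == "borehole", ]
  # 9 locations: within 25 % of the target mean
  s9 <- generate_district_dataset(iju, seed = 202)
  m9 <- summarize_stratum(s9, "Ni", "Iju", "borehole")$mean
  expect_lt(abs(m9 - target$mean) / target$mean, 0.25)
  # 900 locations: within 3 %
  big <- district_spec("Iju", iju$params, n_locations = 900,
                       n_replicates = 1, bbox = iju$bbox)
  s900 <- generate_district_dataset(big, seed = 202)
  m900 <- summarize_stratum(s900, "Ni", "Iju", "borehole")$mean
  expect_lt(abs(m900 - target$mean) / target$mean, 0.03)
})

test_that("fitting a large generated stratum recovers the generating moments", {
  spec <- fit_truncated_lognormal(88, 13.4, 47.3, 239.7)
  set.seed(314)
  x <- dist_draw(spec, 2e5)
  refit <- fit_truncated_lognormal(mean(x), sd(x), 47.3, 239.7)
  expect_equal(refit$params$meanlog, spec$params$meanlog, tolerance = 0.02)
  expect_equal(refit$params$sdlog, spec$params$sdlog, tolerance = 0.05)
})

test_that("default exposure profiles carry the study conventions", {
  p <- default_exposure_profiles()
  expect_equal(p$adult$IR_w, 2)
  expect_equal(p$adult$BW, 70)
  expect_equal(p$child$IR_w, 1)
  expect_lte(p$child$ED, p$adult$ED)
  st <- default_exposure_profiles(stochastic = TRUE)
  expect_true(is_dist_spec(st$adult$IR_w))
  expect_true(is_dist_spec(st$child$BW))
  # stochastic means stay anchored at the point defaults
  expect_equal(dist_mean(st$adult$EF_r), (180 + 365) / 2)
})

test_that("exposure profiles round-trip through plain-text config losslessly", {
  profs <- default_exposure_profiles(stochastic = TRUE)
  path <- tempfile(fileext = ".cfg")
  write_exposure_config(profs, path)
  back <- read_exposure_config(path)
  expect_setequal(names(back), c("adult", "child"))
  for (pop in names(profs)) {
    for (nm in c("IR_w", "EF_r", "ED", "BW", "SA", "K_p", "ET", "CF")) {
      a <- profs[[pop]][[nm]]; b <- back[[pop]][[nm]]
      if (is_dist_spec(a)) {
        expect_equal(b$params, a$params, tolerance = 0)
        expect_identical(c(b$lower, b$upper), c(a$lower, a$upper))
      } else {
        expect_identical(b, a)
      }
    }
  }
})

test_that("infeasible district specifications are rejected", {
  bad <- data.frame(parameter = "Pb", source_type = "both", min = 10,
                    max = 40, mean = 50, sd = 5, status = "measured",
                    detection_limit = NA)
  expect_error(district_spec("X", bad), "infeasible")
})
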