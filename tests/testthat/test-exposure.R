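resolved_adult <- function(AT = 10950) {
  exposure_profile(IR_w = 2, EF_r = 350, ED = 30, BW = 70, AT_r = AT,
                   SA = 18000, K_p = 0.001, ET = 0.58)
}

test_that("ingestion dose matches the exact rational hand value", {
  # 70 * 2 * 350 * 30 / (70 * 10950) = 1470000 / 766500
  expect_equal(cdi_ingestion(70, resolved_adult()), 1470000 / 766500,
               tolerance = 1e-13)
  expect_equal(cdi_ingestion(0, resolved_adult()), 0)
  # doubling BW exactly halves the dose
  p2 <- resolved_adult(); p2$BW <- 140
  expect_equal(cdi_ingestion(70, p2), cdi_ingestion(70, resolved_adult()) / 2,
               tolerance = 1e-14)
  expect_error(cdi_ingestion(Inf, resolved_adult()), "finite")
})

test_that("dermal dose matches the exact rational hand value", {
  # 1000 * 18000 * 0.001 * 350 * 30 * 0.58 * 0.001 / (70 * 10950)
  expect_equal(cdi_dermal(1000, resolved_adult()), 109620 / 766500,
               tolerance = 1e-13)
  expect_equal(cdi_dermal(0, resolved_adult()), 0)
  p <- resolved_adult(); p$K_p <- NA
  expect_error(cdi_dermal(1000, p), "K_p")
})

test_that("doses are homogeneous of degree 1 in each numerator factor", {
  set.seed(11)
  for (i in 1:10) {
    p <- exposure_profile(IR_w = runif(1, 0.5, 4), EF_r = runif(1, 100, 365),
                          ED = runif(1, 2, 60), BW = runif(1, 10, 120),
                          AT_r = runif(1, 1000, 30000))
    C <- runif(1, 1, 500); k <- runif(1, 0.1, 10)
    expect_equal(cdi_ingestion(k * C, p), k * cdi_ingestion(C, p),
                 tolerance = 1e-12)
    p2 <- p; p2$IR_w <- k * p$IR_w
    expect_equal(cdi_ingestion(C, p2), k * cdi_ingestion(C, p),
                 tolerance = 1e-12)
  }
})

test_that("non-carcinogenic averaging time cancels the exposure duration", {
  p6 <- exposure_profile(IR_w = 2, EF_r = 350, ED = 6, BW = 70)
  p30 <- exposure_profile(IR_w = 2, EF_r = 350, ED = 30, BW = 70)
  expect_equal(cdi_ingestion(50, p6, endpoint = "HQ"),
               cdi_ingestion(50, p30, endpoint = "HQ"), tolerance = 1e-14)
  # carcinogenic convention uses the 70-year lifetime and does depend on ED
  expect_equal(cdi_ingestion(50, p30, endpoint = "LTCR") /
               cdi_ingestion(50, p6, endpoint = "LTCR"), 5, tolerance = 1e-12)
})

test_that("hazard quotients divide by the route-specific reference dose", {
  tox <- default_toxicity()
  expect_equal(hazard_quotient(1.4, "Pb", tox), 1)
  expect_equal(hazard_quotient(0.2, "Ni", tox), 0.01)
  # unit cancellation: same HQ if CDI and RfD are both expressed in mg/kg/day
  tox_mg <- tox; tox_mg$rfd_i <- tox$rfd_i / 1000
  expect_equal(hazard_quotient(0.2 / 1000, "Ni", tox_mg),
               hazard_quotient(0.2, "Ni", tox))
  # recovery: HQ * RfD == CDI to machine precision
  cdi <- 0.37213
  expect_equal(hazard_quotient(cdi, "Mn", tox) * 140, cdi, tolerance = 1e-15)
  expect_error(hazard_quotient(1, "Cd", tox), "toxicity table")
})

test_that("cancer risk converts dose once and respects the route and band", {
  tox <- default_toxicity()
  # 1e-4 mg/kg/day = 0.1 ug/kg/day, SF(Ni) = 1.7
  r <- lifetime_cancer_risk(0.1, "Ni", tox)
  expect_equal(r, 1.7e-4, tolerance = 1e-12)
  expect_identical(classify_ltcr(r), "above_limit")
  # 2e-5 mg/kg/day with SF(Cr) = 0.5 -> 1e-5, inside the acceptable band
  r2 <- lifetime_cancer_risk(0.02, "Cr", tox)
  expect_equal(r2, 1e-5, tolerance = 1e-12)
  expect_identical(classify_ltcr(r2), "acceptable")
  expect_equal(lifetime_cancer_risk(0, "Ni", tox), 0)
  expect_error(lifetime_cancer_risk(0.1, "Ni", tox, route = "dermal"),
               "ingestion route only")
  expect_error(lifetime_cancer_risk(0.1, "Fe", tox), "sf")
})

test_that("the Pb reference-dose convention is selectable", {
  expect_equal(default_toxicity("adjusted")$rfd_i[6], 1.4)
  expect_equal(default_toxicity("printed")$rfd_i[6], 140)
})
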