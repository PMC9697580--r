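test_that("persistence coefficient is T_CV over half-life at full precision", {
  expect_identical(persistence_coefficient(8, 60), 7.5)
  expect_identical(persistence_coefficient(60, 60), 1)
  # extremely persistent compound: C matches the printed value to 2 sig figs
  expect_equal(signif(persistence_coefficient(4.02e6, 60), 2), 1.5e-5)
  expect_equal(persistence_coefficient(4.02e6, 60), 60 / 4.02e6)
  expect_error(persistence_coefficient(0, 60), class = "srftox_invalid-value")
  expect_error(persistence_coefficient(10, -1), class = "srftox_invalid-value")
})

test_that("PNEC applies the acute (1000) and chronic (100) assessment factors", {
  expect_identical(pnec(1e6, "acute_ec50"), 1000)
  expect_identical(pnec(100, "chronic_chv"), 1)
  expect_identical(pnec(9.2e4, "acute_lc50"), 92)  # oracle: 9.2e4 / 1000
  expect_identical(pnec(c(1e6, 100), c("acute_lc50", "chronic_chv")),
                   c(1000, 1))
  expect_error(pnec(-1, "acute_ec50"), class = "srftox_invalid-value")
  expect_error(pnec(1, "lc50"), class = "srftox_invalid-value")
})

test_that("risk quotient is MEC over PNEC", {
  expect_equal(round(risk_quotient(61.01, 92), 2), 0.66)
  expect_identical(risk_quotient(0, 123), 0)
  expect_equal(risk_quotient(2.78, 1.5), 2.78 / 1.5)  # 1.853...
  expect_error(risk_quotient(1, 0), class = "srftox_invalid-value")
  expect_error(risk_quotient(-1, 1), class = "srftox_invalid-value")
})

test_that("synthetic risk factor divides the RQ by the persistence coefficient", {
  expect_equal(round(synthetic_risk_factor(61.01, 92, 0.40), 2), 1.66)
  # C = 1 collapses the SRF to the RQ
  m <- c(0, 0.5, 61.01); p <- c(1, 2, 92)
  expect_identical(synthetic_risk_factor(m, p, 1), risk_quotient(m, p))
  expect_equal(synthetic_risk_factor(6.5, 100, 5.1e-3),
               6.5 / (100 * 5.1e-3))  # 12.74...
  expect_error(synthetic_risk_factor(1, 1, 0), class = "srftox_invalid-value")
})

test_that("classification bands and boundary conventions", {
  expect_equal(as.character(classify_risk(c(0, 0.005, 0.01))),
               rep("negligible", 3))
  expect_equal(as.character(classify_risk(c(0.010001, 0.05))),
               rep("minimal", 2))
  # interior boundaries fall in the higher (protective) band
  expect_equal(as.character(classify_risk(0.1)), "medium")
  expect_equal(as.character(classify_risk(c(0.39, 0.999))),
               rep("medium", 2))
  expect_equal(as.character(classify_risk(c(1, 1.66, 100))), rep("high", 3))
  expect_true(is.ordered(classify_risk(0.5)))
  expect_error(classify_risk(-0.1), class = "srftox_invalid-value")
})

test_that("assess computes the full chain for single compounds", {
  carb <- srf_assess(compound_table(
    list(name = "Carbendazim", half_life = 8, medium = "water",
         mec = 2.78, pnec = 1.5)))
  expect_equal(carb$c, 7.5)
  expect_equal(as.character(carb$rq_class), "high")
  expect_equal(as.character(carb$srf_class), "medium")
  expect_equal(carb$direction, "down")
  expect_true(carb$reclassified)

  # endpoint route: PNEC derived from a chronic value
  chronic <- srf_assess(compound_table(
    list(name = "E", half_life = 60, medium = "water", mec = 5,
         endpoint_kind = "chronic_chv", endpoint_value = 100)))
  expect_equal(chronic$pnec_ng_per_l, 1)
  expect_equal(chronic$rq, 5)
  expect_equal(chronic$srf, chronic$rq)  # T_1/2 = T_CV

  # acute endpoint divides by 1000
  acute <- srf_assess(compound_table(
    list(name = "A", half_life = 30, medium = "water", mec = 10,
         endpoint_kind = "acute_lc50", endpoint_value = 9.2e4)))
  expect_equal(acute$pnec_ng_per_l, 92)
})

test_that("table rounding mode uses the printed C; full precision ignores it", {
  row <- list(name = "Imazalil", half_life = 151, medium = "water",
              mec = 61.01, pnec = 92, c_printed = 0.40)
  full <- srf_assess(compound_table(row))
  tab <- srf_assess(compound_table(row), rounding = "table")
  expect_equal(full$c, 60 / 151)
  expect_equal(tab$c, 0.40)
  expect_equal(sprintf("%.2f", tab$srf), "1.66")
  expect_equal(sprintf("%.2f", full$srf), "1.67")
  # without a printed C, table mode rounds to 2 significant figures
  tab2 <- srf_assess(compound_table(compound_row(half_life = 151)),
                     rounding = "table")
  expect_equal(tab2$c, signif(60 / 151, 2))
})

test_that("assess preserves order, reports invalid rows, errors when all fail", {
  tbl <- compound_table(
    compound_row(name = "B"), compound_row(name = "A"),
    compound_row(name = "broken", half_life = -1))
  res <- srf_assess(tbl)
  expect_equal(res$name, c("B", "A"))
  expect_equal(nrow(attr(res, "problems")), 1)
  expect_error(
    srf_assess(compound_table(compound_row(half_life = 0))),
    class = "srftox_empty-after-validation")
})

test_that("summary counts bands per method and reclassification directions", {
  res <- srf_assess(srf_fixture("ebro_pesticides"), warn_cas = FALSE)
  s <- srf_summary(res)
  expect_equal(s$n_reclassified, 3)
  expect_equal(s$n_up, 1)
  expect_equal(s$n_down, 2)
  expect_setequal(s$reclassified$name, c("Carbendazim", "Hexythiazox", "Imazalil"))
  expect_equal(sum(s$band_counts$n), 2 * nrow(res))

  single <- srf_summary(srf_assess(compound_table(compound_row())))
  expect_equal(sum(single$band_counts$n[single$band_counts$method == "RQ"]), 1)
  expect_equal(sum(single$band_counts$n[single$band_counts$method == "SRF"]), 1)
})

test_that("tidy and glance reshape an assessment", {
  res <- srf_assess(srf_fixture("ebro_pesticides"), warn_cas = FALSE)
  td <- tidy(res)
  expect_equal(nrow(td), 2 * nrow(res))
  expect_setequal(unique(td$method), c("RQ", "SRF"))
  expect_equal(td$value[td$name == "Imazalil" & td$method == "RQ"],
               61.01 / 92)
  gl <- glance(res)
  expect_equal(gl$n_compounds, 8)
  expect_equal(gl$n_reclassified, 3)
  expect_equal(gl$n_rq_high, 3)   # carbendazim, fenitrothion, hexythiazox
  expect_equal(gl$n_srf_high, 2)  # fenitrothion, imazalil
})

test_that("custom boundary values flow through the assessment", {
  cfg <- srf_config(t_cv_days = c(water = 120, soil = 180, sediment = 180))
  res <- srf_assess(compound_table(compound_row(half_life = 120)), config = cfg)
  expect_equal(res$c, 1)
  res_sed <- srf_assess(compound_table(compound_row(half_life = 180,
                                                    medium = "sediment")))
  expect_equal(res_sed$c, 1)
  expect_equal(res_sed$t_cv_days, 180)
})
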