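test_that("enumeration produces product-form weights that sum to one", {
  m <- scc_model(c(A = 0.5, B = 0.5), list(Y = list("A")),
                 roles = list(exposure = "A", outcome = "Y"))
  jd <- enumerate_joint(m)
  expect_equal(nrow(jd$table), 4L)
  expect_equal(jd$weight, rep(0.25, 4))

  # causation weights: P(Z1 & Z2) = 0.06 * 0.10, marginal over the exposure
  cm <- scenario_causation()$model
  jd <- enumerate_joint(cm)
  both <- jd$table$Z1 == 1L & jd$table$Z2 == 1L
  expect_equal(sum(jd$weight[both]), 0.006, tolerance = 1e-15)

  for (s in 1:10) {
    jd <- enumerate_joint(random_scc_model(s, monotone = FALSE))
    expect_equal(sum(jd$weight), 1, tolerance = 1e-12)
    expect_true(all(jd$weight >= 0))
  }

  big <- scc_model(stats::setNames(rep(0.5, 21), paste0("U", 1:21)), list())
  expect_error(enumerate_joint(big), "cap")
})

test_that("closed-form causation effects agree with the enumeration oracle", {
  cf <- closed_form_causation(0.06, 0.10)
  expect_equal(cf$rr, 1.54, tolerance = 1e-12)
  expect_equal(cf$rd, 0.054, tolerance = 1e-12)

  expect_equal(closed_form_causation(0, 0.2)$rr, 1, tolerance = 1e-15)
  expect_equal(closed_form_causation(0, 0.2)$rd, 0, tolerance = 1e-15)

  set.seed(31)
  for (i in 1:100) {
    p1 <- stats::runif(1, 0, 1)
    p2 <- stats::runif(1, 0.01, 0.99)
    cf <- closed_form_causation(p1, p2)
    te <- true_effects(scenario_causation(p_z1 = p1, p_z2 = p2)$model)
    expect_equal(cf$rr, te$rr, tolerance = 1e-12)
    expect_equal(cf$rd, te$rd, tolerance = 1e-12)
  }
})

test_that("back-calculation inverts the closed form", {
  expect_equal(back_calculate_complement(1.54, 0.10), 0.06, tolerance = 1e-12)
  expect_equal(back_calculate_complement(1, 0.3), 0)

  set.seed(32)
  for (i in 1:50) {
    p2 <- stats::runif(1, 0.05, 0.6)
    rr <- stats::runif(1, 1, 1 / p2 * 0.9)
    p1 <- back_calculate_complement(rr, p2)
    expect_equal(closed_form_causation(p1, p2)$rr, rr, tolerance = 1e-10)
  }

  expect_error(back_calculate_complement(50, 0.5), "infeasible")
  expect_error(back_calculate_complement(0.8, 0.5), ">= 1")
  expect_error(back_calculate_complement(1.5, 0), "in \\(0, 1\\)")
})

test_that("true effects: sharp null and degenerate cases", {
  # exposure absent from all outcome causes -> exact null
  null_model <- scc_model(c(E = 0.5, U = 0.3), list(Y = list("U")),
                          roles = list(exposure = "E", outcome = "Y"))
  te <- true_effects(null_model)
  expect_equal(te$rr, 1, tolerance = 1e-15)
  expect_equal(te$rd, 0, tolerance = 1e-15)

  # zero unexposed risk -> RR flagged undefined, RD still reported
  rare <- scc_model(c(E = 0.5, U1 = 0.2), list(Y = list(c("E", "U1"))),
                    roles = list(exposure = "E", outcome = "Y"))
  te <- true_effects(rare)
  expect_false(te$defined)
  expect_true(is.na(te$rr))
  expect_equal(te$rd, 0.2, tolerance = 1e-12)
})

test_that("exact response-type probabilities match the causation closed form", {
  rt <- response_type_probabilities(scenario_causation()$model)
  expect_equal(rt$overall, c(0.10, 0.054, 0, 0.846), tolerance = 1e-12)
  expect_equal(rt$exposed, rt$unexposed, tolerance = 1e-12)  # exchangeability
  expect_equal(sum(rt$overall), 1, tolerance = 1e-12)

  # all prevalences zero -> everyone immune
  m0 <- scenario_causation(p_z1 = 0, p_z2 = 0)$model
  rt0 <- response_type_probabilities(m0)
  expect_equal(rt0$overall, c(0, 0, 0, 1), tolerance = 1e-15)
})

test_that("risk difference equals P(causal) - P(preventive) for any model", {
  for (s in 1:20) {
    m <- random_scc_model(s, monotone = (s %% 2 == 0))
    te <- true_effects(m)
    rt <- response_type_probabilities(m)
    p_causal <- rt$overall[rt$type == "causal"]
    p_prev <- rt$overall[rt$type == "preventive"]
    expect_equal(te$rd, p_causal - p_prev, tolerance = 1e-12)
    if (s %% 2 == 0) expect_equal(p_prev, 0, tolerance = 1e-15)
  }
})

test_that("calibration solves prevalences against exact oracle statistics", {
  # identity when nothing is free
  m <- scenario_causation()$model
  expect_identical(calibrate_prevalences(m, character(0), list()), m)

  # recover Z1 = 0.06 from the target crude risk ratio
  m2 <- scenario_causation(p_z1 = 0.3)$model
  solved <- calibrate_prevalences(
    m2, "Z1", list(list(stat = stat_crude_rr(), value = 1.54)))
  expect_equal(solved$exogenous[["Z1"]], 0.06, tolerance = 1e-5)
  expect_equal(stat_crude_rr()(solved), 1.54, tolerance = 1e-6)

  # infeasible target is a calibration error carrying residual info
  expect_error(
    calibrate_prevalences(m2, "Z1",
                          list(list(stat = stat_crude_rr(), value = 50))),
    "infeasible")
  expect_error(
    calibrate_prevalences(m2, c("Z1", "Z2"),
                          list(list(stat = stat_crude_rr(), value = 1.5),
                               list(stat = stat_crude_rd(), value = 0.05),
                               list(stat = stat_true_rr(), value = 2))),
    "at least as many free parameters")
})
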