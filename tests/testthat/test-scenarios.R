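test_that("causation scenario oracle truth matches its closed form", {
  s <- scenario_causation()
  te <- true_effects(s$model)
  expect_equal(te$rr, 1.54, tolerance = 1e-12)
  expect_equal(te$rd, 0.054, tolerance = 1e-12)
  expect_equal(true_effects(scenario_causation(p_z1 = 0)$model)$rr, 1,
               tolerance = 1e-15)
  rt <- response_type_probabilities(s$model)
  expect_equal(rt$exposed[rt$type == "doomed"], 0.10, tolerance = 1e-12)
  expect_equal(rt$unexposed[rt$type == "doomed"], 0.10, tolerance = 1e-12)
})

test_that("sharp-null confounding calibrates to the target crude association", {
  s <- scenario_confounding()
  te <- true_effects(s$model)
  expect_equal(te$rr, 1, tolerance = 1e-12)
  expect_equal(te$rd, 0, tolerance = 1e-12)

  cr <- sccsim:::oracle_crude(s$model)
  expect_equal(cr$rr, 1.55, tolerance = 1e-6)
  expect_equal(cr$rd, 0.079, tolerance = 1e-6)

  # no causal response types anywhere under the sharp null
  rt <- response_type_probabilities(s$model)
  expect_equal(rt$exposed[rt$type == "causal"], 0, tolerance = 1e-15)
  expect_equal(rt$unexposed[rt$type == "causal"], 0, tolerance = 1e-15)
  # doomed among the exposed is pinned by the crude targets: RD*RR/(RR-1)
  expect_equal(rt$exposed[rt$type == "doomed"], 0.079 * 1.55 / 0.55,
               tolerance = 1e-5)

  # degenerate: no exposure mechanism at all -> calibration cannot proceed
  expect_error(scenario_confounding(p_q1 = 0, p_q2 = 0))
})

test_that("collider scenario: null full population, biased analytic sample", {
  s <- scenario_collider()
  expect_equal(sccsim:::oracle_crude(s$model)$rr, 1, tolerance = 1e-12)
  expect_equal(true_effects(s$model)$rr, 1, tolerance = 1e-12)

  in_analytic <- function(d) d$Participation == 1L
  cr <- sccsim:::oracle_crude(s$model, in_analytic)
  expect_equal(cr$rr, 1.55, tolerance = 1e-6)
  expect_equal(cr$rd, 0.117, tolerance = 1e-6)

  jd <- enumerate_joint(s$model)
  keep <- jd$table$Participation == 1L
  analytic <- jd$table[keep, , drop = FALSE]
  attr(analytic, "roles") <- attr(jd$table, "roles")
  st <- standardized_effect(analytic, weights = jd$weight[keep])
  expect_equal(st$rr, 1, tolerance = 1e-12)
})

test_that("effect-modification strata are back-calculated exactly", {
  s <- scenario_effect_modification()
  carrier <- true_effects(s$model, function(d) d$APOE == 1L)
  expect_equal(carrier$rr, 2.22, tolerance = 1e-12)
  expect_equal(carrier$rd, 0.122, tolerance = 1e-12)
  noncarrier <- true_effects(s$model, function(d) d$APOE == 0L)
  expect_equal(noncarrier$rr, 1.36, tolerance = 1e-12)
  expect_equal(noncarrier$rd, 0.036, tolerance = 1e-12)
  overall <- true_effects(s$model)
  expect_equal(overall$rr, 1.575, tolerance = 1e-12)  # printed as 1.58
  expect_equal(overall$rd, 0.0575, tolerance = 1e-12) # printed as 0.058

  # no modification when both strata share the target: Z1b collapses to 0
  flat <- scenario_effect_modification(rr_carriers = 1.36, rr_noncarriers = 1.36)
  expect_equal(flat$model$exogenous[["Z1b"]], 0, tolerance = 1e-12)
  expect_equal(true_effects(flat$model, function(d) d$APOE == 1L)$rr,
               true_effects(flat$model, function(d) d$APOE == 0L)$rr,
               tolerance = 1e-12)

  expect_error(scenario_effect_modification(rr_carriers = 11),
               "infeasible")
})

test_that("non-sharp-null confounding: crude exceeds adjusted = true effect", {
  s <- scenario_confounding_nonnull()
  te <- true_effects(s$model)
  expect_gt(te$rr, 1)

  jd <- enumerate_joint(s$model)
  cr <- crude_effect(jd$table, weights = jd$weight)
  st <- standardized_effect(jd$table, weights = jd$weight)
  expect_gt(cr$rr, st$rr)                      # confounding inflates the crude
  expect_equal(st$rr, te$rr, tolerance = 1e-12) # standardization recovers truth
  expect_equal(st$rd, te$rd, tolerance = 1e-12)

  # round-trip: choose Z1 via back-calculation for a desired conditional effect
  p_z1 <- back_calculate_complement(1.3, 0.2)
  expect_equal(closed_form_causation(p_z1, 0.2)$rr, 1.3, tolerance = 1e-12)
})

test_that("no canned scenario admits preventive response types", {
  for (name in preset_names) {
    m <- get_scenario(name)$model
    rt <- response_type_probabilities(m)
    expect_equal(rt$overall[rt$type == "preventive"], 0, tolerance = 1e-15)
  }
})

test_that("presets are reachable by name and configs export/reload", {
  expect_error(get_scenario("not-a-scenario"), "unknown scenario")
  sc <- get_scenario("causation", p_z2 = 0.2)
  expect_equal(sc$model$exogenous[["Z2"]], 0.2)

  path <- withr::local_tempfile(fileext = ".scc")
  write_scc_config(get_scenario("effect-modification"), path)
  back <- get_scenario(paste0("config:", path))
  expect_s3_class(back, "scc_scenario")
  expect_equal(true_effects(back$model, function(d) d$APOE == 1L)$rr, 2.22,
               tolerance = 1e-12)
})
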