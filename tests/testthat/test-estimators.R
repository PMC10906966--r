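make_counts_table <- function(cases_e, n_e, cases_u, n_u) {
  d <- data.frame(
    E = c(rep(1L, n_e), rep(0L, n_u)),
    Y = c(rep(1L, cases_e), rep(0L, n_e - cases_e),
          rep(1L, cases_u), rep(0L, n_u - cases_u)))
  attr(d, "roles") <- list(exposure = "E", outcome = "Y")
  d
}

test_that("crude effect is exact arithmetic on the 2x2 table", {
  est <- crude_effect(make_counts_table(154, 1000, 100, 1000))
  expect_equal(est$rr, 1.54, tolerance = 1e-12)
  expect_equal(est$rd, 0.054, tolerance = 1e-12)
  expect_identical(est$n_exposed, 1000)
  expect_identical(est$n_unexposed, 1000)

  same <- crude_effect(make_counts_table(50, 500, 100, 1000))
  expect_equal(same$rr, 1, tolerance = 1e-12)
  expect_equal(same$rd, 0, tolerance = 1e-12)
})

test_that("degenerate 2x2 tables are flagged, not silently estimated", {
  no_unexposed <- make_counts_table(10, 100, 0, 0)
  no_unexposed <- no_unexposed[no_unexposed$E == 1L, ]
  attr(no_unexposed, "roles") <- list(exposure = "E", outcome = "Y")
  est <- crude_effect(no_unexposed)
  expect_false(est$defined)
  expect_match(paste(est$note, collapse = " "), "empty exposure group")

  zero_risk <- crude_effect(make_counts_table(10, 100, 0, 100))
  expect_false(zero_risk$defined)
  expect_true(is.na(zero_risk$rr))
  expect_equal(zero_risk$rd, 0.1, tolerance = 1e-12)  # RD still defined
})

test_that("standardization equals the crude contrast when the adjustment variable is balanced", {
  # exactly balanced by construction: every (E, A) cell same size
  grid <- expand.grid(E = 0:1, A = 0:1, rep = 1:50)
  grid$Y <- as.integer(grid$E == 1 & grid$A == 1 | grid$rep <= 10)
  d <- data.frame(E = as.integer(grid$E), A = as.integer(grid$A), Y = grid$Y)
  attr(d, "roles") <- list(exposure = "E", outcome = "Y", adjustment = "A")
  cr <- crude_effect(d)
  st <- standardized_effect(d)
  expect_equal(st$rr, cr$rr, tolerance = 1e-12)
  expect_equal(st$rd, cr$rd, tolerance = 1e-12)

  # and on the oracle, when the adjustment variable is independent of exposure
  m <- scc_model(c(E = 0.4, A = 0.25, U = 0.2, V = 0.1),
                 list(Y = list(c("E", "U"), "V", c("A", "U"))),
                 roles = list(exposure = "E", outcome = "Y", adjustment = "A"))
  jd <- enumerate_joint(m)
  cr <- crude_effect(jd$table, weights = jd$weight)
  st <- standardized_effect(jd$table, weights = jd$weight)
  expect_equal(st$rr, cr$rr, tolerance = 1e-12)
  expect_equal(st$rd, cr$rd, tolerance = 1e-12)
})

test_that("oracle standardization reproduces the sharp null exactly", {
  conf <- scenario_confounding(iterations = 1)$model
  jd <- enumerate_joint(conf)
  st <- standardized_effect(jd$table, weights = jd$weight)
  expect_equal(st$rr, 1, tolerance = 1e-12)
  expect_equal(st$rd, 0, tolerance = 1e-12)
  # while the crude association is biased upward
  cr <- crude_effect(jd$table, weights = jd$weight)
  expect_equal(cr$rr, 1.55, tolerance = 1e-6)

  coll <- scenario_collider(iterations = 1)$model
  jd <- enumerate_joint(coll)
  full_crude <- crude_effect(jd$table, weights = jd$weight)
  expect_equal(full_crude$rr, 1, tolerance = 1e-12)

  keep <- jd$table$Participation == 1L
  analytic <- jd$table[keep, , drop = FALSE]
  attr(analytic, "roles") <- attr(jd$table, "roles")
  an_crude <- crude_effect(analytic, weights = jd$weight[keep])
  expect_gt(an_crude$rr, 1.5)  # restriction induces the bias
  an_std <- standardized_effect(analytic, weights = jd$weight[keep])
  expect_equal(an_std$rr, 1, tolerance = 1e-12)
  expect_equal(an_std$rd, 0, tolerance = 1e-12)
})

test_that("stratified estimates split by the modifier and flag degenerate strata", {
  s <- scenario_effect_modification()
  d <- simulate_sample(s, n = 20000, seed = 53)
  strat <- stratified_effect(d)
  expect_gt(strat[["1"]]$rr, strat[["0"]]$rr)  # larger effect among carriers

  # stratum with no exposed members is flagged
  d2 <- d[!(d$APOE == 1L & d$LowEdu == 1L), ]
  attr(d2, "roles") <- attr(d, "roles")
  strat2 <- stratified_effect(d2)
  expect_false(strat2[["1"]]$defined)
})

test_that("restriction to the analytic sample keeps metadata and flags emptiness", {
  s <- scenario_collider()
  d <- simulate_sample(s, n = 10000, seed = 59)
  a <- restrict_sample(d)
  expect_true(all(a$Participation == 1L))
  expect_identical(attr(a, "roles"), attr(d, "roles"))
  # analytic fraction close to the oracle participation probability
  jd <- enumerate_joint(s$model)
  p_part <- sum(jd$weight * jd$table$Participation)
  expect_lt(abs(nrow(a) / nrow(d) - p_part), 0.02)

  none <- d[d$Participation == 2L, ]  # empty
  attr(none, "roles") <- attr(d, "roles")
  expect_identical(attr(restrict_sample(none), "flagged"), "empty analytic sample")

  always <- scc_model(c(E = 0.5, S = 1), list(Y = list("E")),
                      roles = list(exposure = "E", outcome = "Y", selection = "S"))
  ds <- simulate_sample(always, n = 100, seed = 3)
  expect_identical(nrow(restrict_sample(ds)), 100L)
})
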