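# The four canned teaching scenarios (plus the non-sharp-null confounding
# variant), all built around the running example of low educational attainment
# and dementia.  Each builder returns an scc_scenario: a calibrated model plus
# default run settings (1,000 samples of 10,000 individuals).
#
# Where a prevalence is pinned down by a published number it is a default
# argument; where it is not, it is fixed by deterministic calibration of the
# exact oracle to the stated crude effects, or set to a documented plausible
# value (see the methods vignette).

#' Bundle a model with simulation settings
#'
#' @param model a valid `scc_model`.
#' @param n sample size per simulated dataset.
#' @param iterations number of simulated datasets.
#' @param seed optional default master seed.
#' @return an object of class `scc_scenario`.
#' @export
scc_scenario <- function(model, n = 10000L, iterations = 1000L, seed = NULL) {
  stopifnot(inherits(model, "scc_model"), n >= 1, iterations >= 1)
  structure(list(model = model, n = as.integer(n),
                 iterations = as.integer(iterations),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "scc_scenario")
}

#' @export
print.scc_scenario <- function(x, ...) {
  cat(sprintf("SCC simulation scenario: %d iterations x n = %d\n",
              x$iterations, x$n))
  print(x$model)
  invisible(x)
}

#' Causation scenario
#'
#' Low education causes dementia through the sufficient cause (LowEdu & Z1);
#' Z2 collects all sufficient causes unrelated to education.  With the default
#' prevalences 0.06 and 0.10 the true risk ratio is 1.54 and the true risk
#' difference 0.054; Z2 = 0.10 anchors dementia risk among the highly educated
#' at a plausible 10%, and Z1 is the value back-calculated from that anchor
#' and a target risk ratio of about 1.55.
#'
#' @param p_z1 prevalence of the exposure's causal complement.
#' @param p_z2 prevalence of the education-independent sufficient cause.
#' @param p_exposure exposure (low education) prevalence.  Has no bearing on
#'   risk ratios, risk differences or within-group response-type proportions.
#' @param n,iterations simulation settings.
#' @return an `scc_scenario`.
#' @examples
#' true_effects(scenario_causation()$model)
#' @export
scenario_causation <- function(p_z1 = 0.06, p_z2 = 0.10, p_exposure = 0.5,
                               n = 10000L, iterations = 1000L) {
  model <- scc_model(
    exogenous = c(LowEdu = p_exposure, Z1 = p_z1, Z2 = p_z2),
    endogenous = list(Dementia = list(c("LowEdu", "Z1"), "Z2")),
    roles = list(exposure = "LowEdu", outcome = "Dementia"))
  scc_scenario(model, n, iterations)
}

#' Confounding scenario
#'
#' Low childhood socioeconomic status causes both low education (via Q1, with
#' Q2 collecting other causes of low education) and dementia (via Z4, with Z3
#' collecting SES- and education-independent causes).  Under the sharp null
#' (`sharp_null = TRUE`, the default) the education-Z1 mechanism is switched
#' off by setting P(Z1) = 0, so the true effect is exactly null, and the
#' prevalences of Z3 and Z4 are calibrated on the exact oracle so the
#' *crude* association equals the target risk ratio and risk difference --
#' confounding alone produces the observed association.
#'
#' @param sharp_null simulate under the sharp null (P(Z1) = 0)?
#' @param crude_rr,crude_rd calibration targets for the exact population crude
#'   association.
#' @param p_z1 complement prevalence used when `sharp_null = FALSE`.
#' @param p_lowses,p_q1,p_q2 prevalences of low childhood SES and of the
#'   components of the sufficient causes for low education (documented
#'   defaults; not pinned down by published values).
#' @param n,iterations simulation settings.
#' @return an `scc_scenario` with `adjustment = "LowSES"`.
#' @export
scenario_confounding <- function(sharp_null = TRUE,
                                 crude_rr = 1.55, crude_rd = 0.079,
                                 p_z1 = 0.06,
                                 p_lowses = 0.4, p_q1 = 0.6, p_q2 = 0.2,
                                 n = 10000L, iterations = 1000L) {
  model <- scc_model(
    exogenous = c(LowSES = p_lowses, Q1 = p_q1, Q2 = p_q2,
                  Z1 = if (sharp_null) 0 else p_z1, Z3 = 0.10, Z4 = 0.15),
    endogenous = list(
      LowEdu = list(c("LowSES", "Q1"), "Q2"),
      Dementia = list(c("LowEdu", "Z1"), "Z3", c("LowSES", "Z4"))),
    roles = list(exposure = "LowEdu", outcome = "Dementia",
                 adjustment = "LowSES"))
  model <- calibrate_prevalences(
    model, free = c("Z3", "Z4"),
    targets = list(list(stat = stat_crude_rr(), value = crude_rr),
                   list(stat = stat_crude_rd(), value = crude_rd)))
  scc_scenario(model, n, iterations)
}

#' Confounding scenario away from the sharp null
#'
#' Same structure as [scenario_confounding()] but with a positive
#' education-Z1 mechanism, so the true effect is non-null while confounding by
#' low childhood SES still inflates the crude association above it.  The
#' non-exposure prevalences default to the sharp-null calibration.
#'
#' @inheritParams scenario_confounding
#' @return an `scc_scenario`.
#' @export
scenario_confounding_nonnull <- function(p_z1 = 0.06, crude_rr = 1.55,
                                         crude_rd = 0.079,
                                         p_lowses = 0.4, p_q1 = 0.6, p_q2 = 0.2,
                                         n = 10000L, iterations = 1000L) {
  stopifnot(p_z1 > 0)
  sc <- scenario_confounding(sharp_null = TRUE, crude_rr = crude_rr,
                             crude_rd = crude_rd, p_lowses = p_lowses,
                             p_q1 = p_q1, p_q2 = p_q2,
                             n = n, iterations = iterations)
  sc$model$exogenous[["Z1"]] <- p_z1
  sc
}

#' Selection (collider) bias scenario
#'
#' Study participation is an endogenous variable caused by *high* education
#' (the absence of low education, with X1), by X2, and by APOE e4 (with X3).
#' Dementia is caused by Z5 and by APOE e4 (with Z6); the education-Z1
#' mechanism is off (P(Z1) = 0), so education and dementia are independent in
#' the full population (true and full-sample crude effects exactly null).
#' Restricting to participants conditions on a collider and induces a
#' positive education-dementia association; Z5 and Z6 are calibrated on the
#' exact oracle so the analytic-sample crude association equals the targets.
#'
#' @param crude_rr,crude_rd calibration targets for the exact analytic-sample
#'   crude association.
#' @param p_exposure low-education prevalence.
#' @param p_apoe APOE e4 carrier prevalence.
#' @param p_x1,p_x2,p_x3 participation-cause prevalences (documented
#'   defaults; chosen so the oracle participation probability is about 1/3).
#' @param n,iterations simulation settings.
#' @return an `scc_scenario` with `selection = "Participation"` and
#'   `adjustment = "APOE"`.
#' @export
scenario_collider <- function(crude_rr = 1.55, crude_rd = 0.117,
                              p_exposure = 0.5, p_apoe = 0.25,
                              p_x1 = 0.28, p_x2 = 0.05, p_x3 = 0.7,
                              n = 10000L, iterations = 1000L) {
  model <- scc_model(
    exogenous = c(LowEdu = p_exposure, APOE = p_apoe, Z1 = 0,
                  Z5 = 0.07, Z6 = 0.34, X1 = p_x1, X2 = p_x2, X3 = p_x3),
    endogenous = list(
      Dementia = list(c("LowEdu", "Z1"), "Z5", c("APOE", "Z6")),
      Participation = list(c("!LowEdu", "X1"), "X2", c("APOE", "X3"))),
    roles = list(exposure = "LowEdu", outcome = "Dementia",
                 selection = "Participation", adjustment = "APOE"))
  in_analytic <- function(d) d$Participation == 1L
  model <- calibrate_prevalences(
    model, free = c("Z5", "Z6"),
    targets = list(list(stat = stat_crude_rr(in_analytic), value = crude_rr),
                   list(stat = stat_crude_rd(in_analytic), value = crude_rd)))
  scc_scenario(model, n, iterations)
}

#' Effect-modification scenario
#'
#' The education sufficient cause is split into two mechanisms: one in which
#' low education with Z1a suffices, and one in which low education must work
#' with APOE e4 and Z1b.  The stratum-specific true effects are then
#' back-calculated in closed form: among non-carriers only the Z1a mechanism
#' operates, so `P(Z1a) = p_z2 (rr_nc - 1) / (1 - p_z2)`; among carriers both
#' operate, giving `P(Z1b) = 1 - (1 - p_z2 rr_c) / ((1 - P(Z1a))(1 - p_z2))`.
#' The defaults reproduce true stratum effects RR 2.22 / RD 0.122 (carriers)
#' and RR 1.36 / RD 0.036 (non-carriers), hence overall RR 1.58 / RD 0.058 at
#' a carrier prevalence of 0.25.
#'
#' @param p_z2 prevalence of the education-independent cause (anchors the
#'   unexposed risk in both strata at `p_z2`).
#' @param rr_carriers,rr_noncarriers target true risk ratios within APOE e4
#'   strata.
#' @param p_modifier APOE e4 carrier prevalence.
#' @param p_exposure low-education prevalence.
#' @param n,iterations simulation settings.
#' @return an `scc_scenario` with `modifier = "APOE"`.
#' @export
scenario_effect_modification <- function(p_z2 = 0.10, rr_carriers = 2.22,
                                         rr_noncarriers = 1.36,
                                         p_modifier = 0.25, p_exposure = 0.5,
                                         n = 10000L, iterations = 1000L) {
  stopifnot(rr_carriers >= rr_noncarriers, rr_noncarriers >= 1)
  p_z1a <- back_calculate_complement(rr_noncarriers, p_z2)
  risk1_c <- p_z2 * rr_carriers
  if (risk1_c > 1)
    stop("infeasible carrier-stratum target: exposed risk would exceed 1")
  p_z1b <- 1 - (1 - risk1_c) / ((1 - p_z1a) * (1 - p_z2))
  if (p_z1b < 0 || p_z1b > 1)
    stop("infeasible targets: required P(Z1b) outside [0, 1]")
  model <- scc_model(
    exogenous = c(LowEdu = p_exposure, APOE = p_modifier,
                  Z1a = p_z1a, Z2 = p_z2, Z1b = p_z1b),
    endogenous = list(
      Dementia = list(c("LowEdu", "Z1a"), "Z2", c("LowEdu", "APOE", "Z1b"))),
    roles = list(exposure = "LowEdu", outcome = "Dementia",
                 modifier = "APOE"))
  scc_scenario(model, n, iterations)
}

# Registry used by the command-line interface and the acceptance script.
scenario_presets <- function() {
  list(
    "causation" = scenario_causation,
    "confounding" = scenario_confounding,
    "confounding-nonnull" = scenario_confounding_nonnull,
    "collider" = scenario_collider,
    "effect-modification" = scenario_effect_modification)
}

#' Build a preset scenario by name
#'
#' @param name one of `"causation"`, `"confounding"`, `"confounding-nonnull"`,
#'   `"collider"`, `"effect-modification"`, or `"config:<path>"` to read a
#'   config file.
#' @param ... passed to the scenario builder.
#' @return an `scc_scenario`.
#' @export
get_scenario <- function(name, ...) {
  if (startsWith(name, "config:")) {
    sc <- read_scc_config(sub("^config:", "", name))
    if (!inherits(sc, "scc_scenario")) sc <- scc_scenario(sc)
    return(sc)
  }
  presets <- scenario_presets()
  if (!name %in% names(presets))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]](...)
}
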