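# Exact truth oracle: enumeration of the joint distribution of exogenous
# components.  Because components are mutually independent Bernoulli draws,
# the joint is product-form over the 2^k patterns; every population quantity
# (true and crude risks, response-type probabilities) is a weighted sum over
# patterns and therefore exact.

#' Enumerate the exact joint distribution of an SCC model
#'
#' Lists all `2^k` patterns of the `k` exogenous components with product-form
#' probability weights, and realizes every endogenous variable per pattern.
#'
#' @param model a valid `scc_model`.
#' @param cap refuse models with more than `cap` exogenous components
#'   (default 20, i.e. at most `2^20` patterns).
#' @return object of class `scc_joint`: list with `table` (data frame of all
#'   factual variable values, one row per pattern) and `weight` (numeric,
#'   sums to 1).
#' @export
enumerate_joint <- function(model, cap = 20L) {
  k <- length(model$exogenous)
  if (k > cap)
    stop(sprintf("model has %d exogenous components; enumeration cap is %d", k, cap))
  grid <- do.call(expand.grid, c(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
  names(grid) <- names(model$exogenous)
  w <- rep(1, nrow(grid))
  for (v in names(model$exogenous)) {
    p <- model$exogenous[[v]]
    w <- w * ifelse(grid[[v]] == 1L, p, 1 - p)
  }
  tab <- realize_endogenous_impl(model, grid)
  attr(tab, "roles") <- model$roles
  structure(list(table = tab, weight = w, model = model), class = "scc_joint")
}

#' @export
print.scc_joint <- function(x, ...) {
  cat(sprintf("Exact joint distribution: %d patterns over %d exogenous components\n",
              nrow(x$table), length(x$model$exogenous)))
  invisible(x)
}

#' @export
as.data.frame.scc_joint <- function(x, ...) {
  out <- x$table
  out$.weight <- x$weight
  out
}

# Potential outcome of `var` (default: the outcome role) for every enumeration
# pattern, with the exposure clamped to `e`.
oracle_potential <- function(model, jd, e, var = model$roles$outcome) {
  exposure <- model$roles$exposure
  if (is.null(exposure) || is.null(var))
    stop("exposure and outcome roles must be set")
  exo <- jd$table[names(model$exogenous)]
  realize_endogenous_impl(model, exo, clamp = stats::setNames(e, exposure))[[var]]
}

#' Exact causal effects by enumeration
#'
#' Computes `P(Y = 1 | do(E = 1))` and `P(Y = 1 | do(E = 0))` exactly by
#' clamping the exposure and re-evaluating all endogenous variables over the
#' enumerated joint distribution, optionally restricted to a sub-population.
#' The restriction uses *factual* (non-intervened) variable values, so e.g.
#' conditioning on realized study participation gives the analytic-sample
#' truth, and conditioning on a modifier gives the stratum-specific truth.
#'
#' @param model a valid `scc_model` with exposure and outcome roles.
#' @param condition optional predicate: a function taking the factual
#'   enumeration table (data frame) and returning a logical vector.
#' @param label optional label describing the sub-population.
#' @return an `scc_effect` with exact `rr`, `rd`, `risk_exposed`,
#'   `risk_unexposed`.
#' @examples
#' m <- scc_model(c(LowEdu = 0.5, Z1 = 0.06, Z2 = 0.10),
#'                list(Dementia = list(c("LowEdu", "Z1"), "Z2")),
#'                roles = list(exposure = "LowEdu", outcome = "Dementia"))
#' true_effects(m)  # RR 1.54, RD 0.054
#' @export
true_effects <- function(model, condition = NULL, label = "true") {
  jd <- enumerate_joint(model)
  y1 <- oracle_potential(model, jd, 1L)
  y0 <- oracle_potential(model, jd, 0L)
  keep <- if (is.null(condition)) rep(TRUE, nrow(jd$table)) else condition(jd$table)
  w <- jd$weight * keep
  W <- sum(w)
  if (W <= 0) stop("conditioning predicate selects a zero-probability sub-population")
  risk1 <- sum(w * y1) / W
  risk0 <- sum(w * y0) / W
  new_scc_effect(risk1, risk0, n_exposed = W, n_unexposed = W, label = label)
}

#' Closed-form true effects for the two-cause causation model
#'
#' For the model `Y <- (E & Z1) | Z2` with independent components, the risk
#' under exposure is `P(Z1) + P(Z2) - P(Z1)P(Z2)` and the risk without
#' exposure is `P(Z2)`, giving the printed closed forms for the true risk
#' ratio and risk difference.
#'
#' @param p_complement prevalence of the exposure's causal complement (Z1).
#' @param p_other prevalence of the exposure-independent sufficient cause (Z2).
#' @return an `scc_effect`.
#' @examples
#' closed_form_causation(0.06, 0.10)  # RR 1.54, RD 0.054
#' @export
closed_form_causation <- function(p_complement, p_other) {
  stopifnot(p_complement >= 0, p_complement <= 1, p_other >= 0, p_other <= 1)
  risk1 <- p_complement + p_other - p_complement * p_other
  risk0 <- p_other
  new_scc_effect(risk1, risk0, label = "closed form")
}

#' Back-calculate a complement prevalence from a target risk ratio
#'
#' Inverts [closed_form_causation()]: given the prevalence of the
#' exposure-independent cause (which fixes the risk in the unexposed) and a
#' desired true risk ratio, returns the complement prevalence
#' `p_other * (rr - 1) / (1 - p_other)`.
#'
#' @param target_rr desired true risk ratio (`>= 1`).
#' @param p_other prevalence of the other sufficient cause, in `(0, 1)`.
#' @return the complement prevalence.
#' @examples
#' back_calculate_complement(1.54, 0.10)  # 0.06
#' @export
back_calculate_complement <- function(target_rr, p_other) {
  if (target_rr < 1) stop("target_rr must be >= 1 under monotonicity")
  if (p_other <= 0 || p_other >= 1) stop("p_other must be in (0, 1)")
  p1 <- p_other * (target_rr - 1) / (1 - p_other)
  if (p1 > 1 + 1e-12)
    stop(sprintf("infeasible calibration: required complement prevalence %.4f > 1", p1))
  min(p1, 1)
}

#' Exact response-type probabilities
#'
#' Classifies every enumeration pattern by its pair of potential outcomes
#' (exposure clamped to 1 and to 0) and aggregates pattern weights, overall
#' and within groups defined by the *factual* exposure value.
#'
#' @inheritParams true_effects
#' @return data frame with columns `type`, `overall`, `exposed`, `unexposed`;
#'   each probability column sums to 1.
#' @export
response_type_probabilities <- function(model, condition = NULL) {
  jd <- enumerate_joint(model)
  y1 <- oracle_potential(model, jd, 1L)
  y0 <- oracle_potential(model, jd, 0L)
  type <- classify_response_types(y1, y0)
  e <- jd$table[[model$roles$exposure]]
  keep <- if (is.null(condition)) rep(TRUE, nrow(jd$table)) else condition(jd$table)
  w <- jd$weight * keep
  agg <- function(mask) {
    ww <- w * mask
    s <- sum(ww)
    if (s <= 0) return(rep(NA_real_, nlevels(type)))
    vapply(levels(type), function(l) sum(ww[type == l]), 0) / s
  }
  data.frame(type = levels(type),
             overall = agg(rep(TRUE, length(w))),
             exposed = agg(e == 1L),
             unexposed = agg(e == 0L))
}

# ---- calibration ----------------------------------------------------------

#' Statistic specifications for calibration
#'
#' Closures mapping a model to an exact population statistic computed on the
#' enumeration oracle: the crude (factual-association) or true (do-operator)
#' risk ratio / risk difference, optionally within a sub-population such as
#' the analytic sample.
#'
#' @param condition optional predicate over the factual enumeration table.
#' @return a function `model -> numeric`.
#' @rdname calibration-stats
#' @export
stat_crude_rr <- function(condition = NULL) {
  function(model) oracle_crude(model, condition)$rr
}

#' @rdname calibration-stats
#' @export
stat_crude_rd <- function(condition = NULL) {
  function(model) oracle_crude(model, condition)$rd
}

#' @rdname calibration-stats
#' @export
stat_true_rr <- function(condition = NULL) {
  function(model) true_effects(model, condition)$rr
}

#' @rdname calibration-stats
#' @export
stat_true_rd <- function(condition = NULL) {
  function(model) true_effects(model, condition)$rd
}

# Exact crude (observational) contrast on the oracle: risks among the
# factually exposed vs unexposed, optionally within `condition`.
oracle_crude <- function(model, condition = NULL) {
  jd <- enumerate_joint(model)
  keep <- if (is.null(condition)) rep(TRUE, nrow(jd$table)) else condition(jd$table)
  crude_effect(jd$table[keep, , drop = FALSE],
               exposure = model$roles$exposure,
               outcome = model$roles$outcome,
               weights = jd$weight[keep])
}

#' Calibrate component prevalences to exact population targets
#'
#' Solves for the prevalences of selected exogenous components so that exact
#' oracle statistics hit desired values, mirroring the practice of setting
#' causal-component prevalences to produce an a-priori effect size.  The
#' solver is deterministic: the i-th free parameter is paired with the i-th
#' target and bisected on `[0, 1]` while the others are held fixed, with an
#' outer fixed-point sweep until every residual is below `tol`.
#'
#' @param model a valid `scc_model`.
#' @param free character vector of exogenous component names to solve for.
#' @param targets list of `list(stat = <function model -> numeric>, value =
#'   <target>)`; see [stat_crude_rr()] and friends.  Must not be longer than
#'   `free`; extra free parameters are left untouched.
#' @param tol absolute tolerance on each statistic (default `1e-6`).
#' @param max_iter maximum outer sweeps (default 200).
#' @return the model with solved prevalences.
#' @export
calibrate_prevalences <- function(model, free, targets, tol = 1e-6,
                                  max_iter = 200L) {
  if (length(targets) == 0 || length(free) == 0) return(model)
  if (length(targets) > length(free))
    stop("need at least as many free parameters as targets")
  stopifnot(all(free %in% names(model$exogenous)))

  stat_at <- function(model, i, p) {
    model$exogenous[[free[i]]] <- p
    targets[[i]]$stat(model)
  }
  residuals <- function(model) vapply(seq_along(targets), function(i)
    targets[[i]]$stat(model) - targets[[i]]$value, 0)

  for (iter in seq_len(max_iter)) {
    for (i in seq_along(targets)) {
      f <- function(p) stat_at(model, i, p) - targets[[i]]$value
      lo <- 0; hi <- 1
      flo <- f(lo); fhi <- f(hi)
      if (is.na(flo)) { lo <- 1e-9; flo <- f(lo) }
      if (is.na(fhi)) { hi <- 1 - 1e-9; fhi <- f(hi) }
      if (abs(flo) < tol) { model$exogenous[[free[i]]] <- lo; next }
      if (abs(fhi) < tol) { model$exogenous[[free[i]]] <- hi; next }
      if (sign(flo) == sign(fhi)) {
        res <- residuals(model)
        stop(sprintf(
          "calibration infeasible for '%s' (target %g); best residuals: %s",
          free[i], targets[[i]]$value, paste(signif(res, 4), collapse = ", ")))
      }
      for (b in 1:80) {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (is.na(fm)) break
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
        if ((hi - lo) < 1e-13) break
      }
      model$exogenous[[free[i]]] <- mid
    }
    if (max(abs(residuals(model))) < tol) return(model)
  }
  stop(sprintf("calibration did not converge within %d sweeps; residuals: %s",
               max_iter, paste(signif(residuals(model), 4), collapse = ", ")))
}
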