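# Repeated-sampling experiments: simulate many datasets, analyze each as one
# would real data, and summarize across iterations with means and empirical
# 2.5/97.5 percentiles.

# Named vector of per-iteration statistics for one simulated dataset.
# Undefined estimates yield NA and are excluded (and counted) in the summary.
iteration_stats <- function(scenario, data) {
  model <- scenario$model
  roles <- model$roles
  out <- c()
  grab <- function(est, prefix) {
    stats::setNames(c(est$rr, est$rd), paste0(prefix, c("_rr", "_rd")))
  }

  out <- c(out, grab(crude_effect(data), "crude"))

  po <- potential_outcomes(model, data)
  types <- classify_response_types(po)
  out <- c(out, ate = mean(po$y1 - po$y0))

  rt_props <- function(mask, prefix) {
    m <- sum(mask)
    p <- if (m > 0) as.integer(table(types[mask])) / m else rep(NA_real_, 4)
    stats::setNames(p, paste0(prefix, "_", RESPONSE_TYPES))
  }
  e <- data[[roles$exposure]]
  out <- c(out, rt_props(e == 1L, "rt_exposed"), rt_props(e == 0L, "rt_unexposed"))

  if (!is.null(roles$adjustment) && is.null(roles$selection))
    out <- c(out, grab(standardized_effect(data), "adj"))

  if (!is.null(roles$selection)) {
    analytic <- restrict_sample(data)
    out <- c(out, analytic_n = nrow(analytic))
    out <- c(out, grab(crude_effect(analytic), "analytic_crude"))
    if (!is.null(roles$adjustment))
      out <- c(out, grab(standardized_effect(analytic), "analytic_adj"))
    ea <- analytic[[roles$exposure]]
    ta <- types[data[[roles$selection]] == 1L]
    pa <- function(mask, prefix) {
      m <- sum(mask)
      p <- if (m > 0) as.integer(table(ta[mask])) / m else rep(NA_real_, 4)
      stats::setNames(p, paste0(prefix, "_", RESPONSE_TYPES))
    }
    out <- c(out, pa(ea == 1L, "analytic_rt_exposed"),
             pa(ea == 0L, "analytic_rt_unexposed"))
  }

  if (!is.null(roles$modifier)) {
    strat <- stratified_effect(data)
    out <- c(out, grab(strat[["1"]], "mod1"), grab(strat[["0"]], "mod0"))
    s <- data[[roles$modifier]]
    out <- c(out,
             rt_props(e == 1L & s == 1L, "rt_exposed_mod1"),
             rt_props(e == 0L & s == 1L, "rt_unexposed_mod1"),
             rt_props(e == 1L & s == 0L, "rt_exposed_mod0"),
             rt_props(e == 0L & s == 0L, "rt_unexposed_mod0"))
  }
  out
}

#' Run a repeated-sampling experiment
#'
#' For each iteration: simulate a sample, estimate crude (and, as the
#' scenario's roles dictate, stratified, restricted and standardized) risk
#' ratios and risk differences, and tabulate response-type proportions by
#' exposure group.  One master seed drives the experiment; each iteration
#' uses an independent seed spawned from it, so identical calls are
#' bit-reproducible.
#'
#' @param scenario an `scc_scenario`.
#' @param n,iterations overrides of the scenario settings.
#' @param seed master seed (defaults to the scenario's seed, else 1).
#' @return an object of class `scc_experiment`: list with `records` (matrix,
#'   iterations x statistics), `summary` (data frame), `scenario`, `seed`.
#' @examples
#' ex <- run_experiment(scenario_causation(), n = 2000, iterations = 50, seed = 1)
#' ex$summary[ex$summary$statistic == "crude_rr", ]
#' @export
run_experiment <- function(scenario, n = NULL, iterations = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "scc_scenario"))
  n <- if (is.null(n)) scenario$n else as.integer(n)
  iterations <- if (is.null(iterations)) scenario$iterations else as.integer(iterations)
  seed <- if (!is.null(seed)) as.integer(seed)
          else if (!is.null(scenario$seed)) scenario$seed else 1L

  set.seed(seed)
  it_seeds <- sample.int(.Machine$integer.max, iterations)
  records <- NULL
  for (i in seq_len(iterations)) {
    d <- simulate_sample(scenario, n = n, seed = it_seeds[i])
    st <- iteration_stats(scenario, d)
    if (is.null(records))
      records <- matrix(NA_real_, iterations, length(st),
                        dimnames = list(NULL, names(st)))
    records[i, names(st)] <- st
  }
  structure(list(records = records,
                 summary = summarize_experiment(records),
                 scenario = scenario, n = n, iterations = iterations,
                 seed = seed, iteration_seeds = it_seeds),
            class = "scc_experiment")
}

#' Summarize per-iteration records
#'
#' Arithmetic mean and empirical 2.5th/97.5th percentiles per statistic,
#' computed over the iterations where the statistic was defined; undefined
#' (flagged) iterations are excluded and counted.
#'
#' @param records numeric matrix, one row per iteration, named columns.
#' @return data frame with columns `statistic`, `mean`, `lower`, `upper`,
#'   `n_used`, `n_excluded`.
#' @export
summarize_experiment <- function(records) {
  if (is.null(dim(records))) records <- matrix(records, ncol = 1,
                                               dimnames = list(NULL, "statistic"))
  if (nrow(records) == 0 || all(is.na(records)))
    stop("no valid iterations to summarize")
  rows <- lapply(colnames(records), function(s) {
    x <- records[, s]
    ok <- !is.na(x)
    if (!any(ok))
      return(data.frame(statistic = s, mean = NA_real_, lower = NA_real_,
                        upper = NA_real_, n_used = 0L, n_excluded = sum(!ok)))
    q <- stats::quantile(x[ok], c(0.025, 0.975), names = FALSE)
    data.frame(statistic = s, mean = mean(x[ok]), lower = q[1], upper = q[2],
               n_used = sum(ok), n_excluded = sum(!ok))
  })
  do.call(rbind, rows)
}

#' @export
print.scc_experiment <- function(x, digits = 3, ...) {
  cat(sprintf("SCC experiment: %d iterations x n = %d (master seed %d)\n",
              x$iterations, x$n, x$seed))
  s <- x$summary
  est <- s[grepl("_(rr|rd)$", s$statistic) | s$statistic %in% c("ate", "analytic_n"), ]
  cat("\nEstimates (mean and 2.5-97.5 percentile interval):\n")
  for (i in seq_len(nrow(est)))
    cat(sprintf("  %-18s %8s  (%s, %s)\n", est$statistic[i],
                format(est$mean[i], digits = digits),
                format(est$lower[i], digits = digits),
                format(est$upper[i], digits = digits)))
  rt <- s[grepl("^rt_", s$statistic) & !grepl("_mod", s$statistic), ]
  if (nrow(rt)) {
    cat("\nResponse-type proportions (mean %):\n")
    for (i in seq_len(nrow(rt)))
      cat(sprintf("  %-24s %6.1f%%\n", rt$statistic[i], 100 * rt$mean[i]))
  }
  if (any(s$n_excluded > 0))
    cat(sprintf("\n%d statistic(s) had excluded (undefined) iterations\n",
                sum(s$n_excluded > 0)))
  invisible(x)
}

#' @export
plot.scc_experiment <- function(x, statistic = "crude_rr", truth = NULL, ...) {
  vals <- x$records[, statistic]
  graphics::hist(vals, breaks = 40, col = "grey80", border = "white",
                 main = sprintf("%s across %d simulations", statistic, x$iterations),
                 xlab = statistic, ...)
  graphics::abline(v = mean(vals, na.rm = TRUE), lwd = 2)
  if (!is.null(truth)) graphics::abline(v = truth, lwd = 2, lty = 2, col = "red3")
  invisible(x)
}

#' Exact oracle truth report for a scenario
#'
#' One row per population statistic computed on the enumeration oracle: true
#' and crude risk ratio and risk difference, plus analytic-sample and
#' stratum-specific versions where the scenario defines selection or a
#' modifier.
#'
#' @param scenario an `scc_scenario` (or `scc_model`).
#' @return data frame with columns `statistic`, `condition`, `value`.
#' @export
truth_report <- function(scenario) {
  model <- if (inherits(scenario, "scc_scenario")) scenario$model else scenario
  roles <- model$roles
  rows <- list()
  add <- function(eff, condition) {
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = c("true_rr", "true_rd"), condition = condition,
      value = c(eff$rr, eff$rd))
  }
  addc <- function(eff, condition) {
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = c("crude_rr", "crude_rd"), condition = condition,
      value = c(eff$rr, eff$rd))
  }
  add(true_effects(model), "full population")
  addc(oracle_crude(model), "full population")
  if (!is.null(roles$selection)) {
    sel <- roles$selection
    cond <- function(d) d[[sel]] == 1L
    add(true_effects(model, cond), "analytic sample")
    addc(oracle_crude(model, cond), "analytic sample")
    jd <- enumerate_joint(model)
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = "participation_probability", condition = "full population",
      value = sum(jd$weight * jd$table[[sel]]))
  }
  if (!is.null(roles$modifier)) {
    modv <- roles$modifier
    add(true_effects(model, function(d) d[[modv]] == 1L),
        sprintf("%s = 1", modv))
    add(true_effects(model, function(d) d[[modv]] == 0L),
        sprintf("%s = 0", modv))
  }
  do.call(rbind, rows)
}
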