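# Individual-level data generation: independent binomial draws for the
# exogenous components, then hierarchical evaluation of endogenous variables
# from the components that cause them.

#' Draw exogenous component values
#'
#' Each component column holds `n` independent Bernoulli draws at the
#' component's prevalence; components are mutually independent by
#' construction.
#'
#' @param model a valid `scc_model`.
#' @param n sample size (`>= 1`).
#' @param seed optional integer seed for reproducibility.
#' @return data frame with one 0/1 integer column per exogenous component.
#' @export
draw_exogenous <- function(model, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cols <- lapply(model$exogenous, function(p) stats::rbinom(n, 1L, p))
  as.data.frame(cols)
}

#' Realize endogenous variables from component values
#'
#' Fills in every endogenous column in hierarchical (topological) order,
#' starting from the exogenous components and working toward the outcome.
#' Deterministic given the component values.
#'
#' @param model a valid `scc_model`.
#' @param components data frame covering all exogenous columns.
#' @return the completed individual-level table, with role tags and the model
#'   attached as attributes.
#' @export
realize_endogenous <- function(model, components) {
  miss <- setdiff(names(model$exogenous), names(components))
  if (length(miss))
    stop("components are missing exogenous column(s): ", paste(miss, collapse = ", "))
  out <- realize_endogenous_impl(model, components[names(model$exogenous)])
  attr(out, "roles") <- model$roles
  attr(out, "model") <- model
  out
}

#' Simulate one individual-level sample
#'
#' Composition of [draw_exogenous()] and [realize_endogenous()]: one simulated
#' dataset in which the values of all causal components for each individual
#' are known.  Identical seed implies an identical table.
#'
#' @param x an `scc_scenario` or `scc_model`.
#' @param n sample size; defaults to the scenario's `n`.
#' @param seed optional integer seed.
#' @return individual-level data frame (0/1 columns, roles attached).
#' @examples
#' sc <- scenario_causation()
#' d <- simulate_sample(sc, n = 1000, seed = 1)
#' crude_effect(d)
#' @export
simulate_sample <- function(x, n = NULL, seed = NULL) {
  model <- if (inherits(x, "scc_scenario")) x$model else x
  stopifnot(inherits(model, "scc_model"))
  if (is.null(n)) {
    if (inherits(x, "scc_scenario")) n <- x$n
    else stop("'n' must be given when simulating from a bare model")
  }
  realize_endogenous(model, draw_exogenous(model, n, seed))
}

#' Simulate method for SCC models
#'
#' @param object an `scc_model`.
#' @param nsim number of samples.
#' @param seed optional master seed; per-sample seeds are spawned from it.
#' @param n sample size per dataset.
#' @param ... unused.
#' @return a list of `nsim` individual-level tables (a single table when
#'   `nsim = 1`).
#' @export
simulate.scc_model <- function(object, nsim = 1, seed = NULL, n = 10000L, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  out <- lapply(seeds, function(s) simulate_sample(object, n = n, seed = s))
  if (nsim == 1) out[[1]] else out
}
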