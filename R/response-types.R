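# "Under the hood" of the simulation: each individual's pair of potential
# outcomes under do(exposure = 1) and do(exposure = 0), and the induced
# response type.  Clamping overrides only the exposure value -- no exogenous
# component is resampled, because an individual's response type is determined
# by their components other than the exposure (their risk-set type).  When the
# exposure is itself endogenous (e.g. under confounding), clamping severs its
# causes, as with any do() intervention.

#' Potential outcomes under both exposure values
#'
#' Re-evaluates the outcome cascade twice per individual with the exposure
#' clamped to 1 and to 0, holding every other exogenous component fixed.
#'
#' @param model a valid `scc_model` with exposure and outcome roles.
#' @param data individual-level table containing all exogenous columns.
#' @return data frame with integer columns `y1` and `y0`.
#' @export
potential_outcomes <- function(model, data) {
  exposure <- model$roles$exposure
  outcome <- model$roles$outcome
  if (is.null(exposure) || is.null(outcome))
    stop("exposure and outcome roles must be set")
  exo <- data[names(model$exogenous)]
  y1 <- realize_endogenous_impl(model, exo, clamp = stats::setNames(1L, exposure))[[outcome]]
  y0 <- realize_endogenous_impl(model, exo, clamp = stats::setNames(0L, exposure))[[outcome]]
  data.frame(y1 = y1, y0 = y0)
}

RESPONSE_TYPES <- c("doomed", "causal", "preventive", "immune")

#' Classify response types from potential-outcome pairs
#'
#' The four-way classification for a dichotomous exposure: doomed `(1,1)`
#' experiences the outcome regardless of exposure; causal `(1,0)` only if
#' exposed; preventive `(0,1)` only if unexposed; immune `(0,0)` never.
#'
#' @param y1 potential outcomes under exposure = 1, or a data frame with
#'   columns `y1`/`y0` as returned by [potential_outcomes()].
#' @param y0 potential outcomes under exposure = 0.
#' @return factor with levels `doomed`, `causal`, `preventive`, `immune`.
#' @export
classify_response_types <- function(y1, y0 = NULL) {
  if (is.data.frame(y1)) { y0 <- y1$y0; y1 <- y1$y1 }
  lab <- ifelse(y1 == 1L & y0 == 1L, "doomed",
         ifelse(y1 == 1L & y0 == 0L, "causal",
         ifelse(y1 == 0L & y0 == 1L, "preventive", "immune")))
  factor(lab, levels = RESPONSE_TYPES)
}

#' Tabulate response types by exposure group
#'
#' Proportions of each response type within exposure groups, optionally inside
#' a sub-population (e.g. the factually selected analytic sample) and/or
#' within levels of a stratification variable.  Each non-empty cell's
#' proportions sum to 1; empty cells are flagged with `NA` proportions, never
#' silently zeroed.
#'
#' @param data individual-level table.
#' @param model the generating `scc_model`; defaults to the model attached to
#'   `data`.
#' @param types optional precomputed response-type factor (recomputed from the
#'   model otherwise).
#' @param by_exposure also break down by factual exposure group (default).
#' @param condition optional predicate (function of `data` returning a logical
#'   vector) restricting the tabulation.
#' @param stratum optional name of a binary column to stratify on.
#' @return data frame with columns (`stratum`,) `group`, `type`, `n`, `prop`.
#' @export
tabulate_response_types <- function(data, model = attr(data, "model"),
                                    types = NULL, by_exposure = TRUE,
                                    condition = NULL, stratum = NULL) {
  if (is.null(types)) {
    if (is.null(model)) stop("either 'types' or 'model' is required")
    types <- classify_response_types(potential_outcomes(model, data))
  }
  keep <- if (is.null(condition)) rep(TRUE, nrow(data)) else condition(data)
  groups <- list(all = keep)
  if (by_exposure) {
    exposure <- resolve_role(data, "exposure", model$roles$exposure)
    e <- data[[exposure]]
    groups <- c(groups, list(exposed = keep & e == 1L, unexposed = keep & e == 0L))
  }
  strata <- if (is.null(stratum)) list(`NA` = rep(TRUE, nrow(data)))
            else list(`0` = data[[stratum]] == 0L, `1` = data[[stratum]] == 1L)

  rows <- list()
  for (sv in names(strata)) for (g in names(groups)) {
    mask <- groups[[g]] & strata[[sv]]
    cnt <- as.integer(table(types[mask]))
    m <- sum(cnt)
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = if (is.null(stratum)) NA_character_ else sv,
      group = g, type = RESPONSE_TYPES, n = cnt,
      prop = if (m > 0) cnt / m else rep(NA_real_, 4))
  }
  out <- do.call(rbind, rows)
  if (is.null(stratum)) out$stratum <- NULL
  if (anyNA(out$prop)) attr(out, "empty_cells") <- TRUE
  out
}
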