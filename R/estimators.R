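# Effect estimators applied to an individual-level table "as one would analyze
# any real-world dataset": crude, stratified, restricted and
# direct-standardized risk ratios and risk differences.  Every function also
# accepts probability weights, so the same code computes exact population
# quantities on the enumeration oracle.

new_scc_effect <- function(risk_exposed, risk_unexposed,
                           n_exposed = NA_real_, n_unexposed = NA_real_,
                           label = "crude", defined = TRUE, note = NULL) {
  rd <- risk_exposed - risk_unexposed
  rr <- if (isTRUE(defined) && !is.na(risk_unexposed) && risk_unexposed > 0)
    risk_exposed / risk_unexposed else NA_real_
  if (isTRUE(defined) && is.na(rr)) {
    defined <- FALSE
    note <- c(note, "risk ratio undefined: zero risk among the unexposed")
  }
  structure(list(rr = rr, rd = rd,
                 risk_exposed = risk_exposed, risk_unexposed = risk_unexposed,
                 n_exposed = n_exposed, n_unexposed = n_unexposed,
                 label = label, defined = defined, note = note),
            class = "scc_effect")
}

#' @export
print.scc_effect <- function(x, digits = 4, ...) {
  cat(sprintf("Effect estimate [%s]\n", x$label))
  if (!x$defined && is.na(x$rd)) {
    cat("  undefined:", paste(x$note, collapse = "; "), "\n")
    return(invisible(x))
  }
  cat(sprintf("  RR = %s, RD = %s\n",
              format(x$rr, digits = digits), format(x$rd, digits = digits)))
  cat(sprintf("  risk(exposed) = %s (n = %s), risk(unexposed) = %s (n = %s)\n",
              format(x$risk_exposed, digits = digits), format(x$n_exposed, digits = 7),
              format(x$risk_unexposed, digits = digits), format(x$n_unexposed, digits = 7)))
  if (!is.null(x$note)) cat("  note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

resolve_role <- function(data, role, value) {
  if (!is.null(value)) return(value)
  roles <- attr(data, "roles")
  if (!is.null(roles[[role]])) return(roles[[role]])
  stop(sprintf("no '%s' given and the table carries no '%s' role", role, role))
}

#' Crude risk ratio and risk difference from a 2x2 table
#'
#' @param data individual-level table (data frame of 0/1 columns), e.g. from
#'   [simulate_sample()]; role tags attached to the table supply default
#'   column names.
#' @param exposure,outcome column names; default from the table's roles.
#' @param weights optional non-negative weights (defaults to 1 per row);
#'   probability weights turn this into the exact crude contrast on an
#'   enumeration table.
#' @param label label stored on the estimate.
#' @return an `scc_effect`.  If an exposure group is empty, or the unexposed
#'   risk is zero (risk ratio only), the estimate is flagged `defined = FALSE`
#'   rather than silently returned.
#' @export
crude_effect <- function(data, exposure = NULL, outcome = NULL, weights = NULL,
                         label = "crude") {
  exposure <- resolve_role(data, "exposure", exposure)
  outcome <- resolve_role(data, "outcome", outcome)
  e <- data[[exposure]]
  y <- data[[outcome]]
  w <- if (is.null(weights)) rep(1, length(e)) else weights
  n1 <- sum(w[e == 1L]); n0 <- sum(w[e == 0L])
  if (n1 <= 0 || n0 <= 0)
    return(new_scc_effect(NA_real_, NA_real_, n1, n0, label = label,
                          defined = FALSE, note = "empty exposure group"))
  risk1 <- sum(w[e == 1L] * y[e == 1L]) / n1
  risk0 <- sum(w[e == 0L] * y[e == 0L]) / n0
  new_scc_effect(risk1, risk0, n1, n0, label = label)
}

#' Stratum-specific crude effects
#'
#' Applies [crude_effect()] within each level of a binary stratification
#' variable (e.g. an effect modifier).
#'
#' @inheritParams crude_effect
#' @param stratum name of a binary column to stratify on; default from the
#'   table's `modifier` role.
#' @return named list of `scc_effect`s, one per stratum level (`"0"`, `"1"`).
#' @export
stratified_effect <- function(data, stratum = NULL, exposure = NULL,
                              outcome = NULL, weights = NULL) {
  stratum <- resolve_role(data, "modifier", stratum)
  out <- list()
  for (s in c(0L, 1L)) {
    keep <- data[[stratum]] == s
    out[[as.character(s)]] <- crude_effect(
      data[keep, , drop = FALSE], exposure, outcome,
      weights = if (is.null(weights)) NULL else weights[keep],
      label = sprintf("stratum:%s=%d", stratum, s))
  }
  out
}

#' Direct-standardized risk ratio and risk difference
#'
#' Adjusts for a binary variable by weighting the stratum-specific risks in
#' each exposure arm by a standard distribution of that variable -- by default
#' the marginal distribution in the analyzed sample itself (the full sample
#' when adjusting for a confounder; the analytic sample when correcting
#' collider bias after restriction).
#'
#' @inheritParams crude_effect
#' @param adjustment name of the binary adjustment column; default from the
#'   table's `adjustment` role.
#' @param standard either `NULL` (use the analyzed sample's marginal
#'   distribution), a named numeric vector `c("0" = w0, "1" = w1)`, or a data
#'   frame whose marginal distribution of `adjustment` is used.
#' @return an `scc_effect` labelled `"adjusted"`; flagged undefined if any
#'   exposure-by-adjustment cell is empty.
#' @export
standardized_effect <- function(data, adjustment = NULL, standard = NULL,
                                exposure = NULL, outcome = NULL,
                                weights = NULL, label = "adjusted") {
  adjustment <- resolve_role(data, "adjustment", adjustment)
  exposure <- resolve_role(data, "exposure", exposure)
  outcome <- resolve_role(data, "outcome", outcome)
  e <- data[[exposure]]; y <- data[[outcome]]; a <- data[[adjustment]]
  w <- if (is.null(weights)) rep(1, length(e)) else weights

  if (is.null(standard)) {
    wt <- c(`0` = sum(w[a == 0L]), `1` = sum(w[a == 1L])) / sum(w)
  } else if (is.data.frame(standard)) {
    as_ <- standard[[adjustment]]
    wt <- c(`0` = mean(as_ == 0L), `1` = mean(as_ == 1L))
  } else {
    wt <- standard[c("0", "1")] / sum(standard[c("0", "1")])
  }

  risks <- matrix(NA_real_, 2, 2, dimnames = list(arm = c("0", "1"),
                                                  stratum = c("0", "1")))
  for (ev in c(0L, 1L)) for (av in c(0L, 1L)) {
    keep <- e == ev & a == av
    denom <- sum(w[keep])
    if (denom <= 0)
      return(new_scc_effect(NA_real_, NA_real_, label = label, defined = FALSE,
                            note = sprintf("empty cell: %s=%d, %s=%d",
                                           exposure, ev, adjustment, av)))
    risks[as.character(ev), as.character(av)] <- sum(w[keep] * y[keep]) / denom
  }
  risk1 <- sum(wt * risks["1", ])
  risk0 <- sum(wt * risks["0", ])
  new_scc_effect(risk1, risk0, sum(w[e == 1L]), sum(w[e == 0L]), label = label)
}

#' Restrict a table to the selected (analytic) sample
#'
#' Keeps the rows with selection indicator 1, i.e. conditions on study
#' participation -- the operation that induces collider bias when the
#' selection variable is a common effect of exposure and another outcome
#' cause.
#'
#' @inheritParams crude_effect
#' @param selection name of the binary selection column; default from the
#'   table's `selection` role.
#' @return the restricted table (roles and model attributes preserved); an
#'   empty result carries attribute `flagged = "empty analytic sample"`.
#' @export
restrict_sample <- function(data, selection = NULL) {
  selection <- resolve_role(data, "selection", selection)
  out <- data[data[[selection]] == 1L, , drop = FALSE]
  attr(out, "roles") <- attr(data, "roles")
  attr(out, "model") <- attr(data, "model")
  if (nrow(out) == 0) attr(out, "flagged") <- "empty analytic sample"
  out
}
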