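#' Declare a sufficient-component-cause model
#'
#' An SCC model describes a system of binary variables.  Exogenous components
#' are drawn independently from Bernoulli distributions with the stated
#' prevalences; each endogenous variable takes the value 1 exactly when at
#' least one of its *sufficient causes* -- a conjunction of components that are
#' jointly sufficient for the outcome -- is completed.  A literal inside a
#' cause may require a variable to be present (`"Z1"`) or absent (`"!LowEdu"`),
#' the latter encoding mechanisms triggered by the absence of a factor (e.g.
#' high education causing study participation).
#'
#' Roles tag which variables play the part of exposure, outcome, selection
#' (study participation), effect modifier and adjustment variable.  They are
#' annotations, not types: one evaluation engine serves every causal structure.
#'
#' @param exogenous named numeric vector of component prevalences in `[0, 1]`.
#' @param endogenous named list; each element is a list of sufficient causes
#'   for that variable, each cause a character vector of literals (prefix `!`
#'   for required absence) or a named 0/1 vector.
#' @param roles named list with any of `exposure`, `outcome`, `selection`,
#'   `modifier`, `adjustment`, each a declared variable name.
#' @param validate if `TRUE` (default), stop on an invalid model; otherwise
#'   the (possibly broken) model is returned and can be inspected with
#'   [validate_model()].
#' @return an object of class `scc_model`.
#' @examples
#' m <- scc_model(
#'   exogenous  = c(LowEdu = 0.5, Z1 = 0.06, Z2 = 0.10),
#'   endogenous = list(Dementia = list(c("LowEdu", "Z1"), "Z2")),
#'   roles      = list(exposure = "LowEdu", outcome = "Dementia")
#' )
#' print(m)
#' @seealso [validate_model()], [enumerate_joint()], [simulate_sample()]
#' @export
scc_model <- function(exogenous, endogenous = list(), roles = list(),
                      validate = TRUE) {
  if (is.null(names(exogenous)) || any(!nzchar(names(exogenous))))
    stop("'exogenous' must be a fully named numeric vector")
  endogenous <- lapply(endogenous, function(causes) lapply(causes, parse_cause))
  model <- structure(
    list(exogenous = exogenous, endogenous = endogenous,
         roles = normalize_roles(roles)),
    class = "scc_model")
  if (validate) {
    rep <- validate_model(model)
    if (!rep$ok)
      stop("invalid SCC model:\n  - ", paste(rep$issues, collapse = "\n  - "))
  }
  model
}

# A cause is stored as a named integer vector: names are variables, values the
# required state (1 = present, 0 = absent).
parse_cause <- function(x) {
  if (is.character(x)) {
    state <- ifelse(startsWith(x, "!"), 0L, 1L)
    vars <- sub("^!", "", x)
    return(stats::setNames(state, vars))
  }
  if (is.numeric(x) && !is.null(names(x)))
    return(stats::setNames(as.integer(x), names(x)))
  stop("a sufficient cause must be a character vector of literals or a named 0/1 vector")
}

normalize_roles <- function(roles) {
  known <- c("exposure", "outcome", "selection", "modifier", "adjustment")
  bad <- setdiff(names(roles), known)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  roles[known[known %in% names(roles)]]
}

format_cause <- function(cause) {
  lit <- ifelse(cause == 1L, names(cause), paste0("!", names(cause)))
  if (length(lit) > 1) paste0("(", paste(lit, collapse = " & "), ")") else lit
}

#' Validate an SCC model
#'
#' Checks the structural invariants a model must satisfy before it can be
#' evaluated: declared variables only, prevalences in range, non-empty and
#' non-contradictory sufficient causes, no self-reference and an acyclic
#' dependency graph.  Violations are itemized in the returned report rather
#' than raised as errors.
#'
#' @param model an `scc_model` (typically built with `validate = FALSE`).
#' @return an object of class `scc_validation`: list with elements `ok`
#'   (logical) and `issues` (character vector, empty when `ok`).
#' @export
validate_model <- function(model) {
  issues <- character(0)
  exo <- model$exogenous
  endo <- model$endogenous
  all_vars <- c(names(exo), names(endo))

  if (anyDuplicated(all_vars))
    issues <- c(issues, paste0("duplicated variable name(s): ",
                               paste(unique(all_vars[duplicated(all_vars)]), collapse = ", ")))
  if (!is.numeric(exo) || anyNA(exo) || any(exo < 0 | exo > 1))
    issues <- c(issues, "exogenous prevalences must be in [0, 1]")

  for (v in names(endo)) {
    causes <- endo[[v]]
    if (length(causes) == 0) {
      issues <- c(issues, sprintf("endogenous variable '%s' has no sufficient cause", v))
      next
    }
    for (i in seq_along(causes)) {
      cause <- causes[[i]]
      tag <- sprintf("cause %d of '%s'", i, v)
      if (length(cause) == 0) {
        issues <- c(issues, paste0(tag, " is empty"))
        next
      }
      if (anyDuplicated(names(cause))) {
        dup <- unique(names(cause)[duplicated(names(cause))])
        con <- vapply(dup, function(u) length(unique(cause[names(cause) == u])) > 1, TRUE)
        issues <- c(issues, paste0(
          tag, if (any(con)) " has contradictory literals for: " else " repeats literal(s): ",
          paste(dup, collapse = ", ")))
      }
      if (v %in% names(cause))
        issues <- c(issues, paste0(tag, " references its own target"))
      undecl <- setdiff(names(cause), all_vars)
      if (length(undecl))
        issues <- c(issues, paste0(tag, " references undeclared variable(s): ",
                                   paste(undecl, collapse = ", ")))
    }
  }

  ord <- tryCatch(evaluation_order(model), error = function(e) conditionMessage(e))
  if (is.character(ord) && length(ord) == 1 && grepl("cycle", ord))
    issues <- c(issues, ord)

  for (r in names(model$roles)) {
    v <- model$roles[[r]]
    if (!is.null(v) && !(v %in% all_vars))
      issues <- c(issues, sprintf("role '%s' refers to undeclared variable '%s'", r, v))
  }

  structure(list(ok = length(issues) == 0, issues = issues),
            class = "scc_validation")
}

#' @export
print.scc_validation <- function(x, ...) {
  if (x$ok) cat("SCC model: valid\n")
  else cat("SCC model: INVALID\n  - ", paste(x$issues, collapse = "\n  - "), "\n", sep = "")
  invisible(x)
}

#' Hierarchical evaluation order of the endogenous variables
#'
#' Returns a topological order in which every endogenous variable appears
#' after all variables referenced by its sufficient causes, i.e. the order in
#' which values are assigned when generating data "starting with exogenous
#' variables and working toward the outcome".
#'
#' @param model a valid `scc_model`.
#' @return character vector of endogenous variable names.
#' @export
evaluation_order <- function(model) {
  endo <- names(model$endogenous)
  deps <- lapply(model$endogenous,
                 function(cl) intersect(unique(unlist(lapply(cl, names))), endo))
  ordered <- character(0)
  remaining <- endo
  while (length(remaining)) {
    ready <- remaining[vapply(remaining,
                              function(v) all(deps[[v]] %in% ordered), TRUE)]
    if (!length(ready))
      stop("cycle detected among endogenous variables: ",
           paste(remaining, collapse = ", "))
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

#' Evaluate one endogenous variable for a single assignment
#'
#' Disjunction-of-conjunctions semantics of the SCC "causal pies": the result
#' is 1 iff at least one sufficient cause has every literal satisfied.
#'
#' @param cause_list list of sufficient causes (as stored in
#'   `model$endogenous[[v]]`, or character vectors of literals).
#' @param assignment named 0/1 vector covering every variable the causes
#'   reference.
#' @return integer 0 or 1.
#' @examples
#' causes <- list(c("LowEdu", "Z1"), "Z2")
#' evaluate_variable(causes, c(LowEdu = 1, Z1 = 1, Z2 = 0))  # 1
#' evaluate_variable(causes, c(LowEdu = 0, Z1 = 1, Z2 = 0))  # 0
#' @export
evaluate_variable <- function(cause_list, assignment) {
  cause_list <- lapply(cause_list, parse_cause)
  miss <- setdiff(unique(unlist(lapply(cause_list, names))), names(assignment))
  if (length(miss))
    stop("assignment is missing variable(s): ", paste(miss, collapse = ", "))
  for (cause in cause_list) {
    if (all(assignment[names(cause)] == cause)) return(1L)
  }
  0L
}

# Vectorized engine: `data` holds one column per variable already available;
# endogenous columns are filled in topological order.  `clamp` is a named 0/1
# vector of do()-interventions: a clamped variable keeps the clamped value and
# its own causes are severed (never evaluated), while downstream variables are
# re-evaluated -- standard do-operator semantics on a boolean structural model.
realize_endogenous_impl <- function(model, data, clamp = NULL) {
  n <- nrow(data)
  for (v in names(clamp)) {
    data[[v]] <- rep(as.integer(clamp[[v]]), n)
  }
  for (v in evaluation_order(model)) {
    if (v %in% names(clamp)) next
    hit <- rep(FALSE, n)
    for (cause in model$endogenous[[v]]) {
      ok <- rep(TRUE, n)
      vars <- names(cause)
      for (j in seq_along(cause)) ok <- ok & (data[[vars[j]]] == cause[[j]])
      hit <- hit | ok
    }
    data[[v]] <- as.integer(hit)
  }
  data
}

#' @export
print.scc_model <- function(x, ...) {
  cat("Sufficient-component-cause model\n")
  cat("  Exogenous components:\n")
  for (v in names(x$exogenous))
    cat(sprintf("    %-12s P = %s\n", v, format(x$exogenous[[v]])))
  if (length(x$endogenous)) {
    cat("  Endogenous variables:\n")
    for (v in names(x$endogenous)) {
      rhs <- paste(vapply(x$endogenous[[v]], format_cause, ""), collapse = " | ")
      cat(sprintf("    %s <- %s\n", v, rhs))
    }
  }
  if (length(x$roles)) {
    tags <- vapply(x$roles, identity, "")
    cat("  Roles: ", paste(names(tags), tags, sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.scc_model <- function(object, ...) {
  out <- list(model = object)
  if (!is.null(object$roles$exposure) && !is.null(object$roles$outcome)) {
    out$true <- true_effects(object)
    out$response_types <- response_type_probabilities(object)
  }
  structure(out, class = "summary.scc_model")
}

#' @export
print.summary.scc_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$true)) {
    cat("\nOracle truth (exact enumeration):\n")
    print(x$true)
    cat("\nResponse-type probabilities:\n")
    print(x$response_types, digits = 4)
  }
  invisible(x)
}
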