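# Plain-text serialization of models and scenarios.
#
# Format: INI-like sections.  Prevalences are written with "%.17g" so a
# write/read round trip is bit-exact.
#
#   [exogenous]
#   Z1: 0.059999999999999998
#   [endogenous]
#   Dementia: LowEdu Z1 | Z2
#   [roles]
#   exposure: LowEdu
#   [settings]          # present only for scenarios
#   n: 10000
#   iterations: 1000

#' Write a model or scenario to a plain-text config file
#'
#' @param x an `scc_model` or `scc_scenario`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @seealso [read_scc_config()]
#' @export
write_scc_config <- function(x, path) {
  scenario <- inherits(x, "scc_scenario")
  model <- if (scenario) x$model else x
  stopifnot(inherits(model, "scc_model"))
  lines <- c("# sccsim model configuration", "[exogenous]")
  for (v in names(model$exogenous))
    lines <- c(lines, sprintf("%s: %.17g", v, model$exogenous[[v]]))
  lines <- c(lines, "[endogenous]")
  for (v in names(model$endogenous)) {
    rhs <- paste(vapply(model$endogenous[[v]], function(cause) {
      paste(ifelse(cause == 1L, names(cause), paste0("!", names(cause))),
            collapse = " ")
    }, ""), collapse = " | ")
    lines <- c(lines, sprintf("%s: %s", v, rhs))
  }
  if (length(model$roles)) {
    lines <- c(lines, "[roles]")
    for (r in names(model$roles))
      if (!is.null(model$roles[[r]]))
        lines <- c(lines, sprintf("%s: %s", r, model$roles[[r]]))
  }
  if (scenario) {
    lines <- c(lines, "[settings]",
               sprintf("n: %d", x$n),
               sprintf("iterations: %d", x$iterations))
    if (!is.null(x$seed)) lines <- c(lines, sprintf("seed: %d", x$seed))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a model or scenario from a plain-text config file
#'
#' @param path file written by [write_scc_config()] (or by hand, same format).
#' @return an `scc_scenario` if the file has a `[settings]` section, otherwise
#'   an `scc_model`.
#' @export
read_scc_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  exo <- numeric(0)
  endo <- list()
  roles <- list()
  settings <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    kv <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1]]
    if (length(kv) != 3)
      stop("cannot parse config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    switch(section,
      exogenous = { exo[key] <- as.numeric(val) },
      endogenous = {
        causes <- strsplit(val, "|", fixed = TRUE)[[1]]
        endo[[key]] <- lapply(causes, function(s) strsplit(trimws(s), "\\s+")[[1]])
      },
      roles = { roles[[key]] <- val },
      settings = { settings[[key]] <- as.integer(val) },
      stop("config line outside a recognized section: ", ln)
    )
  }
  model <- scc_model(exo, endo, roles)
  if (length(settings) == 0) return(model)
  scc_scenario(model,
               n = if (!is.null(settings$n)) settings$n else 10000L,
               iterations = if (!is.null(settings$iterations)) settings$iterations else 1000L,
               seed = settings$seed)
}
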