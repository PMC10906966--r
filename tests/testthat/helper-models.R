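# Shared fixtures: hand-written reference models and a random-model generator
# for property-style tests.

# Fig-1-style single-exposure model: Y <- (E & U1) | U2, optionally with the
# preventive mechanism (!E & U3).
example_model <- function(p_e = 0.5, p_u1 = 0.06, p_u2 = 0.10,
                          p_u3 = NULL) {
  exo <- c(E = p_e, U1 = p_u1, U2 = p_u2)
  causes <- list(c("E", "U1"), "U2")
  if (!is.null(p_u3)) {
    exo <- c(exo, U3 = p_u3)
    causes <- c(causes, list(c("!E", "U3")))
  }
  scc_model(exo, list(Y = causes), roles = list(exposure = "E", outcome = "Y"))
}

# Random layered SCC model with exposure E and outcome Y.  monotone = TRUE
# keeps every exposure literal positive, so preventive response types are
# structurally impossible.
random_scc_model <- function(seed, monotone = TRUE) {
  set.seed(seed)
  k <- sample(2:4, 1)
  comps <- paste0("U", seq_len(k))
  exo <- c(stats::setNames(stats::runif(1, 0.2, 0.8), "E"),
           stats::setNames(stats::runif(k, 0.05, 0.6), comps))
  n_causes <- sample(1:3, 1)
  causes <- lapply(seq_len(n_causes), function(i) {
    lits <- sample(comps, sample(seq_len(min(2, k)), 1))
    if (stats::runif(1) < 0.7) {
      e_lit <- if (!monotone && stats::runif(1) < 0.4) "!E" else "E"
      lits <- c(e_lit, lits)
    }
    lits
  })
  scc_model(exo, list(Y = causes), roles = list(exposure = "E", outcome = "Y"))
}

# All five preset scenario names shipped by the package.
preset_names <- c("causation", "confounding", "confounding-nonnull",
                  "collider", "effect-modification")
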