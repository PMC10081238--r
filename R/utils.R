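# Internal helpers shared across the package.

# Classed error constructor: every package error carries
# c("robustewas_<class>", "robustewas_error") so callers can branch on kind.
.stop <- function(class, msg) {
  stop(errorCondition(msg, class = c(paste0("robustewas_", class),
                                     "robustewas_error", "error", "condition")))
}

# Evaluate `expr` under set.seed(seed), then restore the caller's RNG state.
# This gives seeded operations (fold assignment, splits, fixtures) their own
# substream: drawing folds never perturbs the surrounding stream.
.with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

# Draw a seed for a named substream from the current stream.
.draw_seed <- function() sample.int(.Machine$integer.max, 1L)

# TRUE if the outcome is binary (exactly two distinct values).
.is_binary <- function(y) length(unique(y)) == 2L
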