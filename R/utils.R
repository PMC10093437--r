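# Internal helpers: condition classes and seed derivation.

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ecvalid_invalid_input", "error", "condition")))
}

stop_contract <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ecvalid_contract_error", "error", "condition")))
}

#' Derive a reproducible sequence of seeds from one master seed
#'
#' Repetitions, down-sampling draws and bootstrap loops each consume their own
#' seed so that any single step can be re-run in isolation. The derivation is
#' counter-based (position `i` of the returned vector always maps to the same
#' seed for a given `master_seed`) and leaves the caller's RNG state untouched.
#'
#' @param master_seed single integer seed.
#' @param n number of seeds to derive.
#' @return integer vector of length `n`, each usable with [set.seed()].
#' @export
derive_seeds <- function(master_seed, n) {
  if (!is.numeric(master_seed) || length(master_seed) != 1 || is.na(master_seed))
    stop_invalid("master_seed must be a single integer")
  if (n < 0) stop_invalid("n must be non-negative")
  if (n == 0) return(integer(0))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(abs(master_seed) %% (.Machine$integer.max - 1L)))
  sample.int(.Machine$integer.max - 1L, n)
}

# Cyclic "wrong label" used by the mock classifiers: maps each factor level to
# the next one, guaranteeing the prediction differs from the truth.
next_level <- function(labels, levels) {
  idx <- match(as.character(labels), levels)
  factor(levels[(idx %% length(levels)) + 1L], levels = levels)
}
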