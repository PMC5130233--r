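# Internal helpers shared across modules.

# Derive a reproducible sub-seed for one named operation from the top-level
# seed. Each operation draws from its own stream, so adding a new operation
# to the generator never perturbs the draws of existing ones.
op_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(op)
  h <- sum(chars * seq_along(chars)) %% 99991L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2017L + h)
}

with_op_seed <- function(seed, op, code) {
  withr::with_seed(op_seed(seed, op), code)
}

# Symbol alphabet for the five correlation levels, strongest positive first.
symbol_alphabet <- function() c("A", "B", "C", "D", "E")

# Human labels for the five levels, in alphabet order.
symbol_labels <- function() {
  c(
    A = "strong positive",
    B = "weak positive",
    C = "no",
    D = "weak negative",
    E = "strong negative"
  )
}

check_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single integer.", name))
  }
  if (!is.null(min) && x < min) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, min, x))
  }
  invisible(as.integer(x))
}
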