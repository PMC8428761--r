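# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded package functions never perturb a user's stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_wristrf <- function(fmt, ..., class = "wristrf_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_wristrf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) {
    stop_wristrf("`%s` must be > 0 (got %g)", name, x)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
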