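# internal validation helpers; all user-facing errors go through stop_kaicdyn()
# so they carry a class that tests and the CLI can dispatch on

stop_kaicdyn <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "kaicdyn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_that <- function(ok, msg, class = "kaicdyn_validation_error") {
  if (!isTRUE(ok)) stop_kaicdyn(msg, class)
  invisible(TRUE)
}

assert_numeric <- function(x, name, finite = TRUE, min = NULL) {
  assert_that(is.numeric(x) && length(x) > 0,
              sprintf("`%s` must be a non-empty numeric vector", name))
  if (finite) assert_that(all(is.finite(x)), sprintf("`%s` contains non-finite values", name))
  if (!is.null(min)) assert_that(all(x >= min),
                                 sprintf("`%s` must be >= %g", name, min))
  invisible(x)
}

assert_increasing <- function(x, name) {
  assert_that(all(diff(x) > 0), sprintf("`%s` must be strictly increasing", name))
  invisible(x)
}

# derive a child RNG seed deterministically from a master seed; kept well
# below .Machine$integer.max so seeds survive as R integers
derive_seed <- function(master, index) {
  (as.integer(master) * 7919L + as.integer(index) * 104729L) %% 2147483647L
}
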