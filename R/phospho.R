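#' Canonical KaiC phosphoform states
#'
#' The four phosphorylation states of a KaiC protomer at S431/T432, in the
#' fixed cycle order S/pT -> pS/pT -> pS/T -> S/T (-> S/pT). "S" denotes
#' unmodified S431, "pS" phosphorylated S431, and likewise "T"/"pT" for
#' T432. All abundance matrices, intensity vectors and file columns in the
#' package use this order.
#'
#' @return Character vector of the four state labels in canonical order.
#' @export
#' @examples
#' phospho_states()
phospho_states <- function() c("S/pT", "pS/pT", "pS/T", "S/T")

# column-safe versions used in file headers
phospho_state_cols <- function() c("S_pT", "pS_pT", "pS_T", "S_T")

#' First-order rate constants of the phosphoform cycle
#'
#' @param k1 Rate S/pT -> pS/pT, in h^-1.
#' @param k2 Rate pS/pT -> pS/T, in h^-1.
#' @param k3 Rate pS/T -> S/T, in h^-1.
#' @param k4 Rate S/T -> S/pT, in h^-1. Defaults to 0: closing the cycle
#'   requires KaiA-stimulated phosphorylation, absent in the
#'   auto-dephosphorylation assay.
#'
#' @return An object of class `phospho_rates`.
#' @export
#' @examples
#' phospho_rates(0.5, 0.4, 0.3)
phospho_rates <- function(k1, k2, k3, k4 = 0) {
  k <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  assert_numeric(k, "rates", min = 0)
  assert_that(length(k) == 4L, "exactly four rates are required")
  structure(as.list(k), class = "phospho_rates")
}

#' @export
print.phospho_rates <- function(x, ...) {
  st <- phospho_states()
  steps <- paste0(st, " -> ", st[c(2:4, 1)])
  cat("Phosphoform cycle rates (h^-1):\n")
  for (i in 1:4) cat(sprintf("  %-14s %g\n", steps[i], x[[i]]))
  invisible(x)
}

# 4x4 generator matrix M with dA/dt = M %*% A for the cycle 1->2->3->4->1
phospho_rate_matrix <- function(rates) {
  k <- unlist(rates)
  M <- diag(-k)
  for (i in 1:4) M[if (i == 4) 1 else i + 1, i] <- k[i]
  dimnames(M) <- list(phospho_state_cols(), phospho_state_cols())
  M
}

#' Phosphoform abundance trajectories
#'
#' Container for fractional abundances of the four phosphoforms on a shared
#' time grid. Rows of `A` must sum to 1 within `tol` (1e-9 for simulated
#' trajectories; measured or noisy abundances may state a looser tolerance).
#'
#' @param times Time grid in hours, strictly increasing.
#' @param A Numeric matrix, one row per time point, four columns in
#'   canonical state order (see [phospho_states()]).
#' @param tol Row-sum tolerance.
#'
#' @return An object of class `phospho_abundances` with elements `times`
#'   and `A`.
#' @export
phospho_abundances <- function(times, A, tol = 1e-9) {
  assert_numeric(times, "times")
  assert_increasing(times, "times")
  A <- as.matrix(A)
  assert_that(ncol(A) == 4L && nrow(A) == length(times),
              "`A` must have 4 columns and one row per time point")
  assert_numeric(c(A), "A")
  assert_that(all(A >= -tol & A <= 1 + tol),
              "abundances must lie in [0, 1]")
  assert_that(max(abs(rowSums(A) - 1)) <= tol,
              sprintf("abundance rows must sum to 1 within %g", tol))
  colnames(A) <- phospho_state_cols()
  structure(list(times = as.numeric(times), A = A), class = "phospho_abundances")
}

#' @export
print.phospho_abundances <- function(x, ...) {
  cat(sprintf("Phosphoform abundances: %d time points, %.3g-%.3g h\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Simulate the four-state phosphoform cycle
#'
#' Solves the linear first-order system `dA/dt = M A` of the cycle
#' S/pT -> pS/pT -> pS/T -> S/T (-> S/pT) exactly, via the matrix
#' exponential `A(t) = expm(t M) A(0)`. Total abundance is conserved
#' (columns of `M` sum to zero), so every returned row sums to 1.
#'
#' @param rates A [phospho_rates()] object.
#' @param initial Length-4 vector of initial fractions in canonical state
#'   order, summing to 1 within 1e-9.
#' @param times Time grid in hours, strictly increasing (may start at 0).
#'
#' @return A [phospho_abundances()] object.
#' @export
#' @examples
#' r <- phospho_rates(1, 0, 0)
#' ab <- simulate_abundances(r, c(1, 0, 0, 0), c(0, log(2), 10))
#' ab$A[2, ]  # (0.5, 0.5, 0, 0) at t = ln 2
simulate_abundances <- function(rates, initial, times) {
  assert_that(inherits(rates, "phospho_rates"),
              "`rates` must be a phospho_rates object")
  assert_numeric(initial, "initial", min = 0)
  assert_that(length(initial) == 4L, "`initial` must have length 4")
  assert_that(abs(sum(initial) - 1) <= 1e-9, "`initial` must sum to 1 within 1e-9")
  assert_numeric(times, "times")
  assert_increasing(times, "times")

  M <- phospho_rate_matrix(rates)
  A <- t(vapply(times, function(t) {
    as.numeric(Matrix::expm(M * t) %*% initial)
  }, numeric(4)))
  # clip quadrature-level negatives from the exponential before validation
  A[A < 0 & A > -1e-12] <- 0
  phospho_abundances(times, A)
}

#' Default auto-dephosphorylation scenario
#'
#' Documented default rate constants and initial phosphoform composition
#' for simulating a KaiC auto-dephosphorylation experiment at 30 degC
#' (temperature-jump from ice, no KaiA). The defaults are package
#' constants chosen so that relaxation toward the fully dephosphorylated
#' S/T state is substantially complete within ~20 h, the time scale seen
#' in such assays; they are not fitted to any measured gel densitometry.
#' `k4 = 0` because the return step S/T -> S/pT requires KaiA.
#'
#' @param seed Integer seed, recorded in the result for provenance. The
#'   scenario itself is deterministic and identical for every seed.
#'
#' @return A list with elements `rates` ([phospho_rates()]), `initial`
#'   (length-4 fractions, canonical order) and `seed`.
#' @export
#' @examples
#' sc <- default_dephospho_scenario()
#' sc$rates
default_dephospho_scenario <- function(seed = 0L) {
  list(
    rates   = phospho_rates(k1 = 0.55, k2 = 0.45, k3 = 0.30, k4 = 0),
    initial = c(0.35, 0.45, 0.15, 0.05),
    seed    = as.integer(seed)
  )
}
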