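#' Apparent fluorescence time course
#'
#' Band-integrated (320--370 nm), NATA- and concentration-normalised
#' tryptophan fluorescence of a KaiC construct sampled over time.
#'
#' @param times Time grid in hours, strictly increasing.
#' @param fi_app Apparent fluorescence intensity FI_app (a.u.), finite and
#'   non-negative, one value per time point.
#' @param variant KaiC construct label (e.g. `"WT"`, `"S157W"`, `"W92F"`).
#' @param condition Free-text experimental condition.
#'
#' @return An object of class `fluor_timecourse`.
#' @export
fluor_timecourse <- function(times, fi_app, variant = "WT",
                             condition = "auto-dephosphorylation, 30 degC") {
  assert_numeric(times, "times")
  assert_increasing(times, "times")
  assert_numeric(fi_app, "fi_app", min = 0)
  assert_that(length(fi_app) == length(times),
              "`fi_app` and `times` must have equal length")
  structure(list(times = as.numeric(times), fi_app = as.numeric(fi_app),
                 variant = variant, condition = condition),
            class = "fluor_timecourse")
}

#' @export
print.fluor_timecourse <- function(x, ...) {
  cat(sprintf("FI_app time course [%s]: %d points, %.3g-%.3g h (%s)\n",
              x$variant, length(x$times), min(x$times), max(x$times),
              x$condition))
  invisible(x)
}

state_intensities <- function(fi, se, rss, n_replicates = 1L, variant = "WT") {
  names(fi) <- names(se) <- phospho_state_cols()
  structure(list(fi = fi, se = se, rss = rss,
                 n_replicates = as.integer(n_replicates), variant = variant),
            class = "state_intensities")
}

#' @export
print.state_intensities <- function(x, ...) {
  cat(sprintf("Per-phosphoform intensities [%s] (n = %d, RSS = %.4g):\n",
              x$variant, x$n_replicates, x$rss))
  m <- rbind(FI = x$fi, SE = x$se)
  colnames(m) <- phospho_states()
  print(round(m, 4))
  invisible(x)
}

# shared grid check + design matrix with identifiability screening;
# check_rank = FALSE for pure evaluation (no coefficients estimated)
unmixing_design <- function(tc, ab, pop_threshold = 0.01, check_rank = TRUE) {
  assert_that(inherits(tc, "fluor_timecourse"), "`tc` must be a fluor_timecourse")
  assert_that(inherits(ab, "phospho_abundances"), "`ab` must be phospho_abundances")
  if (length(tc$times) != length(ab$times) || any(tc$times != ab$times)) {
    stop_kaicdyn(
      "time grids of the fluorescence course and the abundances differ; resample explicitly before fitting",
      "kaicdyn_alignment_error")
  }
  assert_that(length(tc$times) >= 4L, "at least 4 time points are required")
  X <- ab$A
  never <- apply(X, 2, max) < pop_threshold
  if (any(never)) {
    stop_kaicdyn(
      sprintf("state(s) never populated (column max < %g): %s; intensities unidentifiable",
              pop_threshold, paste(phospho_states()[never], collapse = ", ")),
      "kaicdyn_identifiability_error")
  }
  if (check_rank && qr(X)$rank < 4L) {
    stop_kaicdyn("abundance design matrix is rank-deficient; intensities unidentifiable",
                 "kaicdyn_identifiability_error")
  }
  X
}

#' Unmix a fluorescence time course into per-phosphoform intensities
#'
#' Fits the linear mixture model
#' \deqn{FI_{app}(t) = \sum_i FI_i A_i(t), \quad i \in \{S/pT, pS/pT, pS/T, S/T\}}
#' by least squares, treating the measured phosphoform abundances
#' \eqn{A_i(t)} as the (fixed) design matrix. Because the abundances are
#' data rather than a smooth model, the reconstructed fit is typically
#' slightly jagged. Time grids must match exactly; interpolation is an
#' explicit pre-processing step, never performed here.
#'
#' @param tc A [fluor_timecourse()].
#' @param ab A [phospho_abundances()] on the identical time grid.
#' @param nonnegative Constrain intensities to be >= 0 (default `TRUE`;
#'   fluorescence intensities are physical). The unconstrained fit is
#'   retained for diagnostics. The unconstrained residual sum of squares
#'   is never larger than the constrained one.
#' @param pop_threshold A state whose abundance never exceeds this value
#'   is flagged unidentifiable (default 0.01, the practical resolution of
#'   gel densitometry).
#'
#' @return A `state_intensities` object: `fi` (4 intensities, canonical
#'   order), `se` (asymptotic standard errors from the residual variance;
#'   replicate-based errors come from [fit_replicates()]), `rss`, and
#'   `n_replicates = 1`.
#' @seealso [compute_rss()], [probe_contribution()], [fit_replicates()]
#' @export
#' @examples
#' ab <- phospho_abundances(1:4, diag(4))
#' tc <- fluor_timecourse(1:4, c(2, 4, 1, 3))
#' fit_state_intensities(tc, ab)$fi  # recovers (2, 4, 1, 3) exactly
fit_state_intensities <- function(tc, ab, nonnegative = TRUE,
                                  pop_threshold = 0.01) {
  X <- unmixing_design(tc, ab, pop_threshold)
  y <- tc$fi_app
  if (nonnegative) {
    fit <- pracma::lsqnonneg(X, y)
    fi <- fit$x
  } else {
    fi <- qr.solve(X, y)
  }
  resid <- y - as.numeric(X %*% fi)
  rss <- sum(resid^2)
  # asymptotic SE from the unconstrained information matrix; at interior
  # solutions (all fi > 0) this is the usual linear-model SE
  dof <- max(length(y) - 4L, 1L)
  sigma2 <- rss / dof
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(sigma2 * diag(XtX_inv), 0))
  state_intensities(as.numeric(fi), se, rss, 1L, tc$variant)
}

#' Residual sum of squares of a fluorescence mixture model
#'
#' \eqn{RSS = \sum_t (FI_{app}(t) - \sum_i FI_i A_i(t))^2}, the fit-quality
#' statistic for the linear unmixing.
#'
#' @inheritParams fit_state_intensities
#' @param fi Length-4 intensity vector in canonical state order.
#' @return RSS in a.u. squared.
#' @export
compute_rss <- function(tc, ab, fi) {
  assert_numeric(fi, "fi")
  assert_that(length(fi) == 4L, "`fi` must have length 4")
  X <- unmixing_design(tc, ab, pop_threshold = 0, check_rank = FALSE)
  sum((tc$fi_app - as.numeric(X %*% fi))^2)
}

#' Fit replicate experiments and aggregate
#'
#' Fits each replicate separately with [fit_state_intensities()] and
#' reports the mean intensity per state with the standard error of the
#' mean, SE = SD/sqrt(n), across replicates — the convention used when
#' reporting n = 3 independent experiments. A pooled global fit (all
#' replicates stacked into one design) is available via `pooled = TRUE`
#' but is not the default.
#'
#' @param tcs List of [fluor_timecourse()] replicates.
#' @param abs List of matching [phospho_abundances()] (same length).
#' @inheritParams fit_state_intensities
#' @param pooled Stack replicates into a single least-squares problem
#'   instead of averaging per-replicate fits.
#'
#' @return A `state_intensities` object; `rss` is the sum of per-replicate
#'   RSS values (or the pooled RSS when `pooled = TRUE`).
#' @export
fit_replicates <- function(tcs, abs, nonnegative = TRUE, pooled = FALSE,
                           pop_threshold = 0.01) {
  assert_that(is.list(tcs) && is.list(abs) && length(tcs) == length(abs),
              "`tcs` and `abs` must be lists of equal length")
  n <- length(tcs)
  assert_that(n >= 1L, "at least one replicate is required")
  fits <- mapply(fit_state_intensities, tcs, abs,
                 MoreArgs = list(nonnegative = nonnegative,
                                 pop_threshold = pop_threshold),
                 SIMPLIFY = FALSE)
  if (pooled) {
    X <- do.call(rbind, lapply(abs, function(a) a$A))
    y <- unlist(lapply(tcs, function(t) t$fi_app))
    fi <- if (nonnegative) pracma::lsqnonneg(X, y)$x else qr.solve(X, y)
    rss <- sum((y - as.numeric(X %*% fi))^2)
    sigma2 <- rss / max(length(y) - 4L, 1L)
    se <- sqrt(pmax(sigma2 * diag(chol2inv(chol(crossprod(X)))), 0))
    return(state_intensities(as.numeric(fi), se, rss, n, tcs[[1]]$variant))
  }
  FI <- t(vapply(fits, function(f) f$fi, numeric(4)))
  fi_mean <- colMeans(FI)
  se <- if (n > 1) apply(FI, 2, sd) / sqrt(n) else fits[[1]]$se
  rss <- sum(vapply(fits, function(f) f$rss, numeric(1)))
  state_intensities(fi_mean, se, rss, n, tcs[[1]]$variant)
}

#' Per-phosphoform contribution of a single tryptophan probe
#'
#' Isolates the fluorescence contribution \eqn{\Delta FI_i} of one Trp
#' residue by differencing the per-phosphoform intensities of the
#' wild-type protein and a Trp-masked or Trp-inserted mutant:
#' * `mode = "masked"` (the probe Trp was removed in the mutant, e.g.
#'   W92F): \eqn{\Delta FI_i = FI_i(\mathrm{ref}) - FI_i(\mathrm{mut})};
#' * `mode = "inserted"` (the probe Trp was added in the mutant, e.g.
#'   S157W): \eqn{\Delta FI_i = FI_i(\mathrm{mut}) - FI_i(\mathrm{ref})}.
#'
#' Standard errors propagate in quadrature,
#' \eqn{SE_i = \sqrt{SE_{ref,i}^2 + SE_{mut,i}^2}}.
#'
#' @param reference `state_intensities` of the reference construct
#'   (typically wild type).
#' @param mutant `state_intensities` of the Trp-masked/-inserted mutant.
#' @param mode `"masked"` or `"inserted"`.
#' @param probe Residue label of the probe (e.g. `"W157"`).
#'
#' @return An object of class `probe_contribution` with `delta_fi`, `se`,
#'   `probe` and `mode`.
#' @export
probe_contribution <- function(reference, mutant,
                               mode = c("masked", "inserted"),
                               probe = mutant$variant) {
  mode <- match.arg(mode)
  assert_that(inherits(reference, "state_intensities") &&
                inherits(mutant, "state_intensities"),
              "`reference` and `mutant` must be state_intensities objects")
  delta <- switch(mode,
                  masked   = reference$fi - mutant$fi,
                  inserted = mutant$fi - reference$fi)
  se <- sqrt(reference$se^2 + mutant$se^2)
  structure(list(delta_fi = delta, se = se, probe = probe, mode = mode),
            class = "probe_contribution")
}

#' @export
print.probe_contribution <- function(x, ...) {
  cat(sprintf("Probe contribution of %s (%s mode):\n", x$probe, x$mode))
  m <- rbind(dFI = x$delta_fi, SE = x$se)
  colnames(m) <- phospho_states()
  print(round(m, 4))
  invisible(x)
}
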