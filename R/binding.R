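#' Kinetic parameters of KaiB--KaiC assembly
#'
#' Parameter set for the two-step relaxation schemes used to model slow
#' KaiB--KaiC complex formation monitored by W157 fluorescence quenching:
#'
#' * `mode = "CS"` (conformational selection): the C1 ring converts from a
#'   pre- to a post-hydrolysis conformation before binding,
#'   `C_pre <=> C_post` (`k_cf`/`k_cr`), then
#'   `C_post + B <=> C_post.B` (`k_on`/`k_off`).
#' * `mode = "IF"` (induced fit): binding precedes the conformational
#'   change, `C + B <=> C.B_enc` (`k_on`/`k_off`) then
#'   `C.B_enc <=> C.B*` (`k_cf`/`k_cr`).
#' * `mode = "CS_dual"`: as CS, with KaiB additionally fold-switching
#'   between a ground state and the binding-competent fold,
#'   `B_gs <=> B_fs` (`k_bf`/`k_br`); only `B_fs` binds.
#'
#' @param mode `"CS"`, `"IF"` or `"CS_dual"`.
#' @param k_cf Forward conformational rate of KaiC (h^-1). Under the
#'   hydrolysis-coupling interpretation this is the C1 ATPase turnover;
#'   activities quoted per day convert via [atpase_to_rate()]. `k_cf = 0`
#'   models the AMP-PNP condition (hydrolysis-driven transition disabled).
#' @param k_cr Reverse conformational rate (h^-1).
#' @param k_on Association rate constant (uM^-1 h^-1, monomer basis).
#' @param k_off Dissociation rate constant (h^-1). The default is small:
#'   assembled complexes survive gel filtration, so dissociation is slow.
#' @param k_bf,k_br KaiB fold-switch rates (h^-1), used only by
#'   `"CS_dual"`.
#' @param fi_free,fi_bound Observable FI_app levels (a.u.) of fully free
#'   and fully bound KaiC; binding quenches W157, so
#'   `fi_bound <= fi_free`.
#'
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(mode = c("CS", "IF", "CS_dual"),
                           k_cf = 0.5, k_cr = 0.05,
                           k_on = 100, k_off = 0.5,
                           k_bf = 2, k_br = 2,
                           fi_free = 1, fi_bound = 0.2) {
  mode <- match.arg(mode)
  rates <- c(k_cf = k_cf, k_cr = k_cr, k_on = k_on, k_off = k_off,
             k_bf = k_bf, k_br = k_br)
  assert_numeric(rates, "rates", min = 0)
  assert_numeric(c(fi_free, fi_bound), "fi levels")
  assert_that(fi_bound <= fi_free,
              "`fi_bound` must not exceed `fi_free` (binding quenches)")
  structure(c(list(mode = mode), as.list(rates),
              list(fi_free = fi_free, fi_bound = fi_bound)),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("KaiB-KaiC binding parameters [%s]:\n", x$mode))
  cat(sprintf("  k_cf = %g, k_cr = %g h^-1; k_on = %g uM^-1 h^-1, k_off = %g h^-1 (Kd = %g uM)\n",
              x$k_cf, x$k_cr, x$k_on, x$k_off, x$k_off / x$k_on))
  if (x$mode == "CS_dual")
    cat(sprintf("  KaiB fold switch: k_bf = %g, k_br = %g h^-1\n", x$k_bf, x$k_br))
  cat(sprintf("  FI levels: free %g, bound %g a.u.\n", x$fi_free, x$fi_bound))
  invisible(x)
}

#' Mixing experiment layout
#'
#' @param c_total Total KaiC concentration (uM, monomer basis), > 0.
#' @param b_total Total KaiB concentration (uM, monomer basis), >= 0
#'   (0 models the no-KaiB control).
#' @param times Observation grid in hours starting at mixing (t = 0).
#'   Default 0--18 h at 5-min spacing, the standard incubation window.
#'
#' @return An object of class `mix_experiment`.
#' @export
mix_experiment <- function(c_total = 3.5, b_total = 3.5,
                           times = seq(0, 18, by = 5 / 60)) {
  assert_numeric(c_total, "c_total")
  assert_that(c_total > 0, "`c_total` must be > 0")
  assert_numeric(b_total, "b_total", min = 0)
  assert_numeric(times, "times")
  assert_increasing(times, "times")
  assert_that(times[1] >= 0, "times must start at or after mixing (t >= 0)")
  structure(list(c_total = c_total, b_total = b_total,
                 times = as.numeric(times)),
            class = "mix_experiment")
}

relaxation_curve <- function(times, fi_app, species, params, experiment) {
  structure(list(times = times, fi_app = fi_app, species = species,
                 params = params, experiment = experiment),
            class = "relaxation_curve")
}

#' @export
print.relaxation_curve <- function(x, ...) {
  cat(sprintf("Relaxation curve [%s]: [KaiC] = %g uM, [KaiB] = %g uM, %d points over %.3g-%.3g h\n",
              x$params$mode, x$experiment$c_total, x$experiment$b_total,
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  FI_app: %.4g -> %.4g a.u.\n",
              x$fi_app[1], x$fi_app[length(x$fi_app)]))
  invisible(x)
}

# right-hand sides of the three schemes; concentrations in uM, time in h
binding_rhs <- function(mode) {
  switch(mode,
    CS = function(t, y, p) {
      B <- p$b_total - y[3]
      v_conf <- p$k_cf * y[1] - p$k_cr * y[2]
      v_bind <- p$k_on * y[2] * B - p$k_off * y[3]
      list(c(-v_conf, v_conf - v_bind, v_bind))
    },
    IF = function(t, y, p) {
      B <- p$b_total - y[2] - y[3]
      v_bind <- p$k_on * y[1] * B - p$k_off * y[2]
      v_conf <- p$k_cf * y[2] - p$k_cr * y[3]
      list(c(-v_bind, v_bind - v_conf, v_conf))
    },
    CS_dual = function(t, y, p) {
      B_gs <- p$b_total - y[3] - y[4]
      v_conf <- p$k_cf * y[1] - p$k_cr * y[2]
      v_fold <- p$k_bf * B_gs - p$k_br * y[3]
      v_bind <- p$k_on * y[2] * y[3] - p$k_off * y[4]
      list(c(-v_conf, v_conf - v_bind, v_fold - v_bind, v_bind))
    })
}

binding_initial_state <- function(p, e) {
  switch(p$mode,
    CS = c(C_pre = e$c_total, C_post = 0, complex = 0),
    IF = c(C_free = e$c_total, C_B_enc = 0, complex = 0),
    # KaiB is pre-incubated separately, so its fold-switch equilibrium is
    # already established at mixing; KaiC starts in the unbound pre state
    CS_dual = c(C_pre = e$c_total, C_post = 0,
                B_fs = e$b_total * p$k_bf / max(p$k_bf + p$k_br, .Machine$double.eps),
                complex = 0))
}

# column index of the bound, quenched species in each scheme's state vector
binding_complex_index <- function(mode) switch(mode, CS = 3L, IF = 3L, CS_dual = 4L)

#' Simulate a KaiB--KaiC relaxation after mixing
#'
#' Integrates the mass-action ODEs of the selected scheme (see
#' [binding_params()]) from the mixing initial condition — all KaiC
#' unbound in its ground (pre-hydrolysis) state, no complex — and maps the
#' bound fraction onto the fluorescence observable
#' \deqn{FI_{app}(t) = FI_{free} + (FI_{bound} - FI_{free}) \cdot
#'   \mathrm{complex}(t) / C_{total}.}
#' For the induced-fit scheme the quenched species is the
#' conformationally converted complex `C.B*` (the observable reports the
#' C1-ring rearrangement, not the encounter complex).
#'
#' Integration uses `deSolve::lsoda` with relative tolerance 1e-8 and
#' absolute tolerance 1e-10 uM; mass conservation of KaiC and KaiB is
#' verified to 1e-6 uM at every time point.
#'
#' @param p A [binding_params()] object.
#' @param e A [mix_experiment()] object.
#'
#' @return A `relaxation_curve`: `times` (h), `fi_app` (a.u.), `species`
#'   (uM trajectories of the scheme's states), plus the parameters and
#'   experiment used.
#' @export
#' @examples
#' p <- binding_params("CS", k_cf = 0.5, k_cr = 0.05, k_on = 100, k_off = 50)
#' cv <- simulate_relaxation(p, mix_experiment(3.5, 10.5))
#' extract_half_life(cv)
simulate_relaxation <- function(p, e) {
  assert_that(inherits(p, "binding_params"), "`p` must be a binding_params object")
  assert_that(inherits(e, "mix_experiment"), "`e` must be a mix_experiment object")
  y0 <- binding_initial_state(p, e)
  pars <- c(unclass(p)[c("k_cf", "k_cr", "k_on", "k_off", "k_bf", "k_br")],
            b_total = e$b_total)
  times <- e$times
  # lsoda needs the initial time on the grid; prepend t = 0 if absent
  prepend <- times[1] > 0
  tgrid <- if (prepend) c(0, times) else times
  out <- tryCatch(
    deSolve::lsoda(y0, tgrid, binding_rhs(p$mode), pars,
                   rtol = 1e-8, atol = 1e-10),
    error = function(err) stop_kaicdyn(
      sprintf("ODE integration failed (%s) for mode=%s, k_cf=%g, k_cr=%g, k_on=%g, k_off=%g, [KaiC]=%g, [KaiB]=%g",
              conditionMessage(err), p$mode, p$k_cf, p$k_cr, p$k_on, p$k_off,
              e$c_total, e$b_total),
      "kaicdyn_integration_error"))
  sp <- out[, -1, drop = FALSE]
  if (prepend) sp <- sp[-1, , drop = FALSE]
  if (any(!is.finite(sp)))
    stop_kaicdyn("non-finite species trajectory; check parameters",
                 "kaicdyn_integration_error")
  cx <- sp[, binding_complex_index(p$mode)]
  c_tot <- switch(p$mode,
                  CS = rowSums(sp),
                  IF = rowSums(sp),
                  CS_dual = sp[, 1] + sp[, 2] + sp[, 4])
  b_tot <- switch(p$mode,
                  CS = cx + (e$b_total - cx),     # free B by closure
                  IF = e$b_total,                 # closed over in rhs
                  CS_dual = sp[, 3] + sp[, 4] +
                    (e$b_total - sp[, 3] - sp[, 4]))
  if (max(abs(c_tot - e$c_total)) > 1e-6)
    stop_kaicdyn("KaiC mass conservation violated beyond 1e-6 uM",
                 "kaicdyn_integration_error")
  fi <- p$fi_free + (p$fi_bound - p$fi_free) * cx / e$c_total
  relaxation_curve(times, fi, sp, p, e)
}

#' Midpoint-crossing half-life of a relaxation curve
#'
#' The half-life is the first time at which `fi_app` crosses the midpoint
#' between its initial and final values, located by linear interpolation
#' between the bracketing grid points. If the total change is below
#' `min_amplitude` the relaxation is classified as absent ("no
#' transition") — the behaviour observed when ATP is exchanged for
#' AMP-PNP — and a `kaicdyn_no_transition_error` is raised.
#'
#' @param curve A `relaxation_curve` (or any list with `times` and
#'   `fi_app`).
#' @param min_amplitude Minimum |first - last| change (a.u.) for a
#'   transition to be considered present. Default 1e-3 a.u. on the
#'   NATA-normalised scale.
#'
#' @return Half-life t1/2 in hours.
#' @export
extract_half_life <- function(curve, min_amplitude = 1e-3) {
  t <- curve$times
  y <- curve$fi_app
  assert_that(length(t) >= 2L, "curve needs at least 2 points")
  amp <- y[1] - y[length(y)]
  if (abs(amp) < min_amplitude)
    stop_kaicdyn(sprintf("no transition: total FI_app change %.3g a.u. below threshold %.3g",
                         abs(amp), min_amplitude),
                 "kaicdyn_no_transition_error")
  mid <- (y[1] + y[length(y)]) / 2
  crossed <- if (amp > 0) y <= mid else y >= mid
  i <- which(crossed)[1]
  if (is.na(i))
    stop_kaicdyn("curve never reaches its midpoint", "kaicdyn_no_transition_error")
  if (i == 1L) return(t[1])
  # linear interpolation between the bracketing points
  t[i - 1] + (mid - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' Total relaxation amplitude
#'
#' The difference in FI_app between the first and the last time point,
#' positive for quenching. This first-minus-last convention is the one
#' used when reporting titration amplitudes.
#'
#' @inheritParams extract_half_life
#' @return Amplitude in a.u.
#' @export
total_amplitude <- function(curve) {
  y <- curve$fi_app
  assert_that(length(y) >= 2L, "curve needs at least 2 points")
  y[1] - y[length(y)]
}

#' Analytic relaxation rate: conformational selection
#'
#' Observed relaxation rate of the two-step conformational-selection
#' scheme in the rapid-equilibrium, excess-ligand limit:
#' \deqn{k_{obs} = k_{cf} + \frac{k_{cr}}{1 + L/K_d}}
#' — decreasing hyperbolically in ligand concentration \eqn{L}, the CS
#' signature. At saturation (\eqn{L \to \infty}) the rate approaches
#' `k_cf`, the conformational (hydrolysis) rate itself.
#'
#' @param k_cf,k_cr Forward/reverse conformational rates (h^-1).
#' @param Kd Dissociation constant of the binding step (uM), > 0.
#' @param L Free ligand (KaiB) concentration (uM), >= 0. Vectorised.
#' @return k_obs in h^-1.
#' @export
analytic_kobs_cs <- function(k_cf, k_cr, Kd, L) {
  assert_numeric(c(k_cf, k_cr), "rates", min = 0)
  assert_that(Kd > 0, "`Kd` must be > 0")
  assert_numeric(L, "L", min = 0)
  k_cf + k_cr / (1 + L / Kd)
}

#' Analytic relaxation rate: induced fit
#'
#' Observed relaxation rate of the two-step induced-fit scheme in the
#' rapid-equilibrium limit:
#' \deqn{k_{obs} = k_{cr} + k_{cf} \frac{L}{K_{d} + L}}
#' — increasing in ligand concentration, the IF signature (the contrast
#' class to [analytic_kobs_cs()]).
#'
#' @inheritParams analytic_kobs_cs
#' @param Kd_enc Dissociation constant of the encounter complex (uM).
#' @return k_obs in h^-1.
#' @export
analytic_kobs_if <- function(k_cf, k_cr, Kd_enc, L) {
  assert_numeric(c(k_cf, k_cr), "rates", min = 0)
  assert_that(Kd_enc > 0, "`Kd_enc` must be > 0")
  assert_numeric(L, "L", min = 0)
  k_cr + k_cf * L / (Kd_enc + L)
}

#' Convert an ATPase activity per day to an hourly rate constant
#'
#' ATP turnover activities are conventionally quoted per day (e.g.
#' 12 d^-1); kinetic modelling uses h^-1. Used when identifying the
#' forward conformational rate `k_cf` with the measured C1 ATPase
#' turnover.
#'
#' @param per_day Activity in d^-1.
#' @return Rate in h^-1.
#' @export
#' @examples
#' atpase_to_rate(12)  # 0.5 h^-1
atpase_to_rate <- function(per_day) {
  assert_numeric(per_day, "per_day", min = 0)
  per_day / 24
}

#' KaiB titration profile of rate and amplitude
#'
#' Runs [simulate_relaxation()] at each KaiB concentration of a titration
#' and collects the inverse midpoint half-life and the total
#' (first-minus-last) amplitude. Concentrations whose relaxation shows no
#' transition (e.g. `k_cf = 0`, the AMP-PNP limit) are kept in the table
#' with `NA` rate and `ok = FALSE` rather than dropped.
#'
#' @param p A [binding_params()] object.
#' @param c_total Fixed KaiC concentration (uM).
#' @param b_grid KaiB concentrations to titrate (uM), non-empty.
#' @param times Observation grid (h); default as in [mix_experiment()].
#' @param min_amplitude Passed to [extract_half_life()].
#'
#' @return An object of class `kobs_profile`: a data frame with columns
#'   `b_um`, `inv_t_half` (h^-1), `amplitude` (a.u.) and `ok`.
#' @export
kobs_profile <- function(p, c_total = 3.5, b_grid = seq(0.9, 10.5, length.out = 5),
                         times = seq(0, 18, by = 5 / 60), min_amplitude = 1e-3) {
  assert_numeric(b_grid, "b_grid", min = 0)
  rows <- lapply(b_grid, function(b) {
    cv <- simulate_relaxation(p, mix_experiment(c_total, b, times))
    th <- tryCatch(extract_half_life(cv, min_amplitude),
                   kaicdyn_no_transition_error = function(e) NA_real_)
    data.frame(b_um = b, inv_t_half = 1 / th,
               amplitude = total_amplitude(cv), ok = !is.na(th))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("kobs_profile", "data.frame")
  out
}

#' Build a titration profile from observed values
#'
#' Assembles a `kobs_profile` from externally measured (or synthetic,
#' noisy) inverse half-lives and amplitudes, for use with
#' [classify_mechanism()] and [fit_cs_profile()].
#'
#' @param b_um KaiB concentrations (uM).
#' @param inv_t_half Inverse half-lives (h^-1); `NA` marks failed points.
#' @param amplitude Total amplitudes (a.u.); defaults to `NA`.
#' @return A `kobs_profile` data frame.
#' @export
as_kobs_profile <- function(b_um, inv_t_half, amplitude = NA_real_) {
  assert_numeric(b_um, "b_um", min = 0)
  assert_that(length(b_um) == length(inv_t_half),
              "`b_um` and `inv_t_half` must have equal length")
  out <- data.frame(b_um = b_um, inv_t_half = inv_t_half,
                    amplitude = amplitude, ok = is.finite(inv_t_half))
  class(out) <- c("kobs_profile", "data.frame")
  out
}

# fit one hyperbolic form to a profile; returns list(fit, rss, span) or NULL
fit_hyperbolic <- function(L, y, form = c("cs", "if")) {
  form <- match.arg(form)
  start <- list(kcf = max(min(y), 1e-6), kcr = max(max(y) - min(y), 1e-6),
                kd = max(median(L), 1e-3))
  if (form == "if")
    start <- list(kcf = max(max(y) - min(y), 1e-6), kcr = max(min(y), 1e-6),
                  kd = max(median(L), 1e-3))
  fml <- if (form == "cs") y ~ kcf + kcr / (1 + L / kd)
         else y ~ kcr + kcf * L / (kd + L)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(L = L, y = y), start = start,
                      lower = c(0, 0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  pred <- function(l) if (form == "cs") cf["kcf"] + cf["kcr"] / (1 + l / cf["kd"])
                      else cf["kcr"] + cf["kcf"] * l / (cf["kd"] + l)
  list(fit = fit, coef = cf, rss = sum(residuals(fit)^2),
       span = abs(pred(min(L)) - pred(max(L))))
}

#' Classify the binding mechanism from a titration profile
#'
#' Fits both hyperbolic forms — the decreasing conformational-selection
#' form \eqn{k_{obs} = k_{cf} + k_{cr}/(1 + L/K_d)} and the increasing
#' induced-fit form \eqn{k_{obs} = k_{cr} + k_{cf} L/(K_d + L)} — to the
#' inverse half-lives and returns the mechanism whose form fits better
#' (lower RSS) *and* whose fitted change across the observed concentration
#' range is significant: the fitted span must exceed `rel_threshold`
#' times the mean observed rate. Profiles failing both requirements
#' (e.g. flat profiles, where both forms degenerate to a constant) are
#' `"ambiguous"`.
#'
#' @param profile A `kobs_profile` with at least 3 valid points.
#' @param rel_threshold Minimum fitted relative span for a significant
#'   trend (default 0.05).
#'
#' @return `"CS"`, `"IF"` or `"ambiguous"`.
#' @export
classify_mechanism <- function(profile, rel_threshold = 0.05) {
  ok <- profile$ok & is.finite(profile$inv_t_half)
  assert_that(sum(ok) >= 3L, "at least 3 valid concentrations are required")
  L <- profile$b_um[ok]
  y <- profile$inv_t_half[ok]
  scale <- mean(y)
  # observed span screen: a flat profile is ambiguous regardless of fits
  if (diff(range(y)) < rel_threshold * scale) return("ambiguous")
  cs <- fit_hyperbolic(L, y, "cs")
  ifit <- fit_hyperbolic(L, y, "if")
  rss_cs <- if (is.null(cs)) Inf else cs$rss
  rss_if <- if (is.null(ifit)) Inf else ifit$rss
  sig_cs <- !is.null(cs) && cs$span > rel_threshold * scale &&
    cs$coef["kcf"] + cs$coef["kcr"] / (1 + min(L) / cs$coef["kd"]) >
      cs$coef["kcf"] + cs$coef["kcr"] / (1 + max(L) / cs$coef["kd"])
  sig_if <- !is.null(ifit) && ifit$span > rel_threshold * scale
  if (sig_cs && (rss_cs < rss_if || !sig_if)) return("CS")
  if (sig_if && (rss_if < rss_cs || !sig_cs)) return("IF")
  "ambiguous"
}

#' Fit the conformational-selection form to a titration profile
#'
#' Nonlinear least-squares fit of
#' \eqn{k_{obs}(L) = k_{cf} + k_{cr}/(1 + L/K_d)} to the inverse
#' half-lives of a titration, with standard errors from the fit
#' covariance. A flat profile leaves \eqn{K_d} (and the
#' \eqn{k_{cf}}/\eqn{k_{cr}} split) unidentifiable; the result then
#' carries `kd_identifiable = FALSE` with `k_cr = 0`, `kd = NA`.
#'
#' @param profile A `kobs_profile` with >= 4 valid concentrations
#'   spanning the region around \eqn{K_d}.
#' @param flat_threshold Relative observed span below which the profile
#'   is treated as flat (default 1e-3).
#'
#' @return A list with `k_cf`, `k_cr`, `kd`, their standard errors
#'   (`se`, named), and `kd_identifiable`.
#' @export
fit_cs_profile <- function(profile, flat_threshold = 1e-3) {
  ok <- profile$ok & is.finite(profile$inv_t_half)
  assert_that(sum(ok) >= 4L, "at least 4 valid concentrations are required")
  L <- profile$b_um[ok]
  y <- profile$inv_t_half[ok]
  if (diff(range(y)) < flat_threshold * mean(y)) {
    return(list(k_cf = mean(y), k_cr = 0, kd = NA_real_,
                se = c(k_cf = sd(y) / sqrt(length(y)), k_cr = NA, kd = NA),
                kd_identifiable = FALSE))
  }
  res <- fit_hyperbolic(L, y, "cs")
  if (is.null(res))
    stop_kaicdyn(sprintf(
      "CS profile fit did not converge (starts: kcf=%.3g, kcr=%.3g, kd=%.3g)",
      min(y), max(y) - min(y), median(L)),
      "kaicdyn_fit_error")
  cf <- res$coef
  se <- tryCatch(sqrt(diag(vcov(res$fit))), error = function(e) rep(NA_real_, 3))
  list(k_cf = unname(cf["kcf"]), k_cr = unname(cf["kcr"]), kd = unname(cf["kd"]),
       se = setNames(se, c("k_cf", "k_cr", "kd")), kd_identifiable = TRUE)
}

#' Single-exponential fit of a relaxation curve
#'
#' Least-squares fit of \eqn{a e^{-k t} + c} to `fi_app(t)`. This is the
#' fitted-rate counterpart of [extract_half_life()]: for a true
#' exponential the two agree via \eqn{t_{1/2} = \ln 2 / k}. The
#' exponential-fit half-life is reported separately and never silently
#' substituted for the midpoint-crossing one. Multi-exponential curves
#' receive the best single-exponential approximation in the
#' least-squares sense.
#'
#' @param curve A `relaxation_curve` (or list with `times`, `fi_app`)
#'   with >= 5 points.
#' @return A list with `rate` (h^-1), `amplitude` (a.u.), `baseline`
#'   (a.u.) and `t_half` (= ln 2 / rate, h).
#' @export
fit_exponential_relaxation <- function(curve) {
  t <- curve$times
  y <- curve$fi_app
  assert_that(length(t) >= 5L, "at least 5 points are required")
  c0 <- y[length(y)]
  a0 <- y[1] - c0
  # crude rate start from the log-linear early decay; fall back to 1/range
  k0 <- {
    d <- (y - c0) / ifelse(a0 == 0, 1, a0)
    sel <- d > 1e-3
    if (sum(sel) >= 3) max(-unname(coef(lm(log(d[sel]) ~ t[sel]))[2]), 1e-6)
    else 1 / max(diff(range(t)), 1e-6)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-k * t) + c,
                      data = data.frame(t = t, y = y),
                      start = list(a = ifelse(a0 == 0, 1e-6, a0), k = k0, c = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_kaicdyn(
      sprintf("exponential fit did not converge (starts: a=%.3g, k=%.3g, c=%.3g)",
              a0, k0, c0),
      "kaicdyn_fit_error"))
  cf <- coef(fit)
  list(rate = unname(cf["k"]), amplitude = unname(cf["a"]),
       baseline = unname(cf["c"]), t_half = log(2) / unname(cf["k"]))
}
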