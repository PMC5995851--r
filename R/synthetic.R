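#' Observation noise model for synthetic experiments
#'
#' @param fi_sigma Additive Gaussian noise on FI_app (a.u.). Default
#'   0.01, i.e. ~1 percent of the NATA-normalised signal — stated as an
#'   assumption; the magnitude of instrument noise is not quantified in
#'   the source experiments.
#' @param densitometry_sigma Fractional (multiplicative) Gaussian noise
#'   on phosphoform abundances before renormalisation, emulating
#'   per-band gel densitometry error. Default 0.01.
#' @param seed Master seed; replicate seeds derive deterministically
#'   from it.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(fi_sigma = 0.01, densitometry_sigma = 0.01, seed = 1L) {
  assert_numeric(c(fi_sigma, densitometry_sigma), "sigmas", min = 0)
  structure(list(fi_sigma = fi_sigma, densitometry_sigma = densitometry_sigma,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# multiplicative noise + clip at 0 + renormalise rows to sum 1 (mimics gel
# band quantification; additive noise would allow negative abundances)
perturb_abundances <- function(A, sigma) {
  if (sigma == 0) return(A)
  noisy <- A * (1 + matrix(rnorm(length(A), 0, sigma), nrow(A)))
  noisy[noisy < 0] <- 0
  sweep(noisy, 1, rowSums(noisy), "/")
}

#' Generate a synthetic auto-dephosphorylation dataset
#'
#' Emulates the dephosphorylation experiment for one KaiC construct:
#' the phosphoform cycle is simulated exactly, per-replicate abundances
#' are perturbed with densitometry noise and renormalised to sum 1, and
#' FI_app is built from the linear mixture of the *clean* abundances
#' (the underlying truth shared by gel and fluorimeter) with the given
#' per-state intensities, plus additive observation noise. Replicates
#' get seeds derived deterministically from the master seed, so a fixed
#' master seed reproduces the dataset bitwise.
#'
#' @param truth_fi Length-4 vector of true per-state intensities (a.u.,
#'   canonical order), >= 0.
#' @param rates A [phospho_rates()] object; default from
#'   [default_dephospho_scenario()].
#' @param initial Initial phosphoform fractions; default from the same
#'   scenario.
#' @param noise A [noise_model()].
#' @param n_replicates Number of independent replicates (default 3, the
#'   usual experimental n).
#' @param times Sampling grid in hours (default 0--20 h hourly).
#' @param variant Construct label carried into the time courses.
#'
#' @return A list of `n_replicates` elements, each with `abundances`
#'   (noisy, renormalised [phospho_abundances()]), `timecourse`
#'   ([fluor_timecourse()]), and `seed`. The attribute `"truth"` records
#'   the generating parameters.
#' @export
generate_dephospho_dataset <- function(truth_fi,
                                       rates = default_dephospho_scenario()$rates,
                                       initial = default_dephospho_scenario()$initial,
                                       noise = noise_model(),
                                       n_replicates = 3L,
                                       times = seq(0, 20, by = 1),
                                       variant = "WT") {
  assert_numeric(truth_fi, "truth_fi", min = 0)
  assert_that(length(truth_fi) == 4L, "`truth_fi` must have length 4")
  clean <- simulate_abundances(rates, initial, times)
  fi_clean <- as.numeric(clean$A %*% truth_fi)
  reps <- lapply(seq_len(n_replicates), function(r) {
    seed_r <- derive_seed(noise$seed, r)
    set.seed(seed_r)
    A_noisy <- perturb_abundances(clean$A, noise$densitometry_sigma)
    fi <- pmax(fi_clean + rnorm(length(fi_clean), 0, noise$fi_sigma), 0)
    list(abundances = phospho_abundances(times, A_noisy, tol = 1e-6),
         timecourse = fluor_timecourse(times, fi, variant = variant),
         seed = seed_r)
  })
  attr(reps, "truth") <- list(truth_fi = truth_fi, rates = rates,
                              initial = initial, noise = noise,
                              variant = variant)
  reps
}

#' Generate a synthetic KaiB titration dataset
#'
#' Simulates one relaxation curve per KaiB concentration with
#' [simulate_relaxation()] and adds additive Gaussian observation noise
#' to FI_app. With `noise$fi_sigma = 0` the curves reproduce the
#' simulator output exactly.
#'
#' @param p A [binding_params()] object.
#' @param c_total Fixed KaiC concentration (uM); default 3.5.
#' @param b_grid KaiB concentrations (uM); default five points spanning
#'   0.9--10.5, the experimental titration range.
#' @param noise A [noise_model()] (only `fi_sigma` and `seed` are used).
#' @param times Observation grid (h).
#'
#' @return A list of `relaxation_curve` objects (one per concentration)
#'   with noisy `fi_app`; each carries attribute `"seed"`, and the list
#'   carries `"truth"` with the generating parameters.
#' @export
generate_binding_dataset <- function(p, c_total = 3.5,
                                     b_grid = seq(0.9, 10.5, length.out = 5),
                                     noise = noise_model(),
                                     times = seq(0, 18, by = 5 / 60)) {
  assert_numeric(b_grid, "b_grid", min = 0)
  curves <- lapply(seq_along(b_grid), function(i) {
    cv <- simulate_relaxation(p, mix_experiment(c_total, b_grid[i], times))
    seed_i <- derive_seed(noise$seed, i)
    set.seed(seed_i)
    cv$fi_app <- cv$fi_app + rnorm(length(cv$fi_app), 0, noise$fi_sigma)
    attr(cv, "seed") <- seed_i
    cv
  })
  attr(curves, "truth") <- list(params = p, c_total = c_total,
                                b_grid = b_grid, noise = noise)
  curves
}

#' Generate a smooth tryptophan emission band
#'
#' A unimodal log-normal band on a 300--400 nm grid at 1-nm steps
#' (excitation fixed at 295 nm), sufficient to exercise band
#' integration and normalisation; spectral realism is out of scope.
#'
#' @param center Peak wavelength (nm).
#' @param width Band width parameter (nm), > 0.
#' @param scale Peak intensity scale (a.u.), >= 0.
#' @param wavelengths Wavelength grid (nm), default `300:400`.
#'
#' @return An object of class `emission_spectrum` with `wavelengths`,
#'   `intensity`, `excitation`.
#' @export
generate_spectrum <- function(center = 340, width = 25, scale = 1,
                              wavelengths = 300:400) {
  assert_that(width > 0, "`width` must be > 0")
  assert_that(scale >= 0, "`scale` must be >= 0")
  # log-normal in wavelength, parameterised so the mode sits at `center`
  lo <- min(wavelengths) - 10
  s <- width / center
  mu <- log(center - lo) + s^2
  x <- wavelengths - lo
  intensity <- scale * exp(-(log(x) - mu)^2 / (2 * s^2)) * (center - lo) / x
  intensity <- intensity / max(intensity) * scale
  if (scale == 0) intensity <- rep(0, length(x))
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensity = intensity, excitation = 295),
            class = "emission_spectrum")
}

#' Band-integrated fluorescence intensity
#'
#' Trapezoidal integral of an emission spectrum over a closed band,
#' by default 320--370 nm — the band used to define FI.
#'
#' @param sp An `emission_spectrum` (or list with `wavelengths`,
#'   `intensity`).
#' @param lo,hi Band limits (nm); must lie within the spectral grid.
#' @return Integrated intensity (nm times a.u.).
#' @export
integrate_band <- function(sp, lo = 320, hi = 370) {
  w <- sp$wavelengths
  assert_that(lo < hi, "`lo` must be < `hi`")
  if (lo < min(w) || hi > max(w))
    stop_kaicdyn(sprintf("band [%g, %g] nm outside spectral grid [%g, %g] nm",
                         lo, hi, min(w), max(w)),
                 "kaicdyn_band_error")
  keep <- w >= lo & w <= hi
  pracma::trapz(w[keep], sp$intensity[keep])
}

#' Normalise a fluorescence intensity to concentration and NATA standard
#'
#' Raw band-integrated intensities are normalised against both the KaiC
#' concentration and the signal of an N-acetyl-L-tryptophanamide (NATA)
#' standard: `raw / (kaic_conc * nata_signal)`.
#'
#' @param raw Raw intensity (a.u.).
#' @param kaic_conc KaiC concentration (uM), > 0.
#' @param nata_signal NATA standard signal (a.u.), > 0.
#' @return Normalised intensity (a.u.).
#' @export
normalize_fi <- function(raw, kaic_conc, nata_signal) {
  assert_numeric(raw, "raw")
  assert_that(all(kaic_conc > 0), "`kaic_conc` must be > 0")
  assert_that(all(nata_signal > 0), "`nata_signal` must be > 0")
  raw / (kaic_conc * nata_signal)
}

#' Write a self-describing synthetic fixture directory
#'
#' Emits TSV tables for a dephosphorylation dataset (abundances and
#' FI_app time course per replicate) plus a JSON manifest recording the
#' seed, generating parameters and package version, so any fixture can
#' be regenerated or audited.
#'
#' @param dir Output directory (created if needed).
#' @param truth_fi,rates,initial,noise,n_replicates,times,variant Passed
#'   to [generate_dephospho_dataset()].
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(dir, truth_fi = c(1.0, 2.5, 1.8, 0.7),
                              rates = default_dephospho_scenario()$rates,
                              initial = default_dephospho_scenario()$initial,
                              noise = noise_model(),
                              n_replicates = 3L,
                              times = seq(0, 20, by = 1),
                              variant = "WT") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reps <- generate_dephospho_dataset(truth_fi, rates, initial, noise,
                                     n_replicates, times, variant)
  for (r in seq_along(reps)) {
    write_abundances(reps[[r]]$abundances,
                     file.path(dir, sprintf("abundances_rep%d.tsv", r)))
    write_timecourse(reps[[r]]$timecourse,
                     file.path(dir, sprintf("timecourse_rep%d.tsv", r)))
  }
  manifest <- list(
    seed = noise$seed,
    variant = variant,
    truth_fi = as.numeric(truth_fi),
    rates = unlist(unclass(rates)),
    initial = as.numeric(initial),
    fi_sigma = noise$fi_sigma,
    densitometry_sigma = noise$densitometry_sigma,
    n_replicates = n_replicates,
    package_version = as.character(utils::packageVersion("kaicdyn")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
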