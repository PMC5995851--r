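cs_default <- function(...) binding_params("CS", k_cf = 0.5, k_cr = 0.05,
                                           k_on = 100, k_off = 50, ...)

test_that("disabling hydrolysis (AMP-PNP) or omitting KaiB freezes the signal", {
  pnp <- binding_params("CS", k_cf = 0, k_cr = 0.05, k_on = 100, k_off = 50)
  cv <- simulate_relaxation(pnp, mix_experiment(3.5, 10.5))
  expect_lt(max(abs(cv$fi_app - cv$params$fi_free)), 1e-9)
  expect_lt(max(cv$species[, "complex"]), 1e-9)
  expect_error(extract_half_life(cv), class = "kaicdyn_no_transition_error")
  expect_equal(total_amplitude(cv), 0, tolerance = 1e-9)

  nob <- simulate_relaxation(cs_default(), mix_experiment(3.5, 0))
  expect_lt(max(abs(nob$fi_app - nob$params$fi_free)), 1e-9)
})

test_that("rapid-equilibrium CS relaxation matches the closed-form rate", {
  # excess ligand, binding much faster than conversion
  p <- binding_params("CS", k_cf = 0.5, k_cr = 0.3, k_on = 100, k_off = 100)
  cv <- simulate_relaxation(p, mix_experiment(0.2, 10))
  k_fit <- fit_exponential_relaxation(cv)$rate
  k_true <- analytic_kobs_cs(0.5, 0.3, 1.0, 10)
  expect_lt(abs(k_fit - k_true) / k_true, 0.05)
})

test_that("half-life extraction matches closed forms", {
  tt <- seq(0, 30, by = 0.01)
  expon <- fake_curve(tt, exp(-log(2) * tt))
  expect_equal(extract_half_life(expon), 1.0, tolerance = 1e-3)
  lin <- fake_curve(c(0, 2), c(1, 0))
  expect_equal(extract_half_life(lin), 1.0, tolerance = 1e-12)
})

test_that("coarse-grid half-life agrees with a 1000x finer resimulation", {
  p <- cs_default()
  coarse_times <- seq(0, 18, by = 0.25)
  fine_times <- seq(0, 18, by = 0.25 / 1000)
  cv_coarse <- simulate_relaxation(p, mix_experiment(3.5, 5, coarse_times))
  cv_fine <- simulate_relaxation(p, mix_experiment(3.5, 5, fine_times))
  # brute-force midpoint search on the fine grid
  y <- cv_fine$fi_app
  mid <- (y[1] + y[length(y)]) / 2
  t_fine <- fine_times[which(y <= mid)[1]]
  expect_lt(abs(extract_half_life(cv_coarse) - t_fine), 0.25)
})

test_that("total amplitude follows the first-minus-last convention", {
  expect_equal(total_amplitude(fake_curve(0:5, rep(2, 6))), 0)
  tt <- seq(0, 20, by = 0.1)
  expect_equal(total_amplitude(fake_curve(tt, 0.2 + 0.8 * exp(-2 * tt))), 0.8,
               tolerance = 1e-10)
  # longer observation can only grow the amplitude of a monotone relaxation
  p <- cs_default()
  short <- simulate_relaxation(p, mix_experiment(3.5, 3.5, seq(0, 2, by = 0.05)))
  long <- simulate_relaxation(p, mix_experiment(3.5, 3.5, seq(0, 30, by = 0.05)))
  expect_gte(total_amplitude(long), total_amplitude(short))
})

test_that("analytic k_obs limits behave as hyperbolae should", {
  expect_equal(analytic_kobs_cs(0.5, 0.05, 0.5, 0), 0.55)
  expect_equal(analytic_kobs_cs(0.5, 0.05, 0.5, 1e9), 0.5, tolerance = 1e-6)
  expect_equal(analytic_kobs_cs(0.5, 0.05, 0.5, 10.5), 0.5 + 0.05 / 22,
               tolerance = 1e-12)
  expect_equal(analytic_kobs_if(0.5, 0.05, 2, 0), 0.05)
  expect_equal(analytic_kobs_if(0.5, 0.05, 2, 1e9), 0.55, tolerance = 1e-6)
  expect_equal(analytic_kobs_if(0.5, 0.05, 2, 2), 0.05 + 0.25)
  expect_equal(atpase_to_rate(12), 0.5)
})

test_that("titration profiles carry the CS and IF signatures under excess KaiB", {
  b_grid <- c(0.9, 3.3, 5.7, 8.1, 10.5)
  cs <- kobs_profile(binding_params("CS", k_cf = 0.5, k_cr = 0.3,
                                    k_on = 100, k_off = 100),
                     c_total = 0.2, b_grid)
  expect_true(all(diff(cs$inv_t_half) < 0))
  expect_identical(classify_mechanism(cs), "CS")

  ifp <- kobs_profile(binding_params("IF", k_cf = 0.5, k_cr = 0.05,
                                     k_on = 10, k_off = 20),
                      c_total = 0.2, b_grid)
  expect_true(all(diff(ifp$inv_t_half) > 0))
  expect_identical(classify_mechanism(ifp), "IF")

  # flat profile (no reverse conversion) is ambiguous: both forms degenerate
  flat <- as_kobs_profile(b_grid, rep(0.72, 5))
  expect_identical(classify_mechanism(flat), "ambiguous")
  expect_error(classify_mechanism(as_kobs_profile(c(1, 2), c(1, 0.9))),
               class = "kaicdyn_validation_error")
})

test_that("tight binding saturates the amplitude at equimolar KaiB", {
  p <- binding_params("CS", k_cf = 0.5, k_cr = 0.05, k_on = 100, k_off = 0.1)
  b_grid <- seq(0.9, 10.5, by = 0.4)
  prof <- kobs_profile(p, 3.5, b_grid, times = seq(0, 48, by = 0.2))
  plateau <- max(prof$amplitude)
  first_sat <- prof$b_um[which(prof$amplitude >= 0.95 * plateau)[1]]
  expect_lt(abs(first_sat - 3.5), 0.4 + 1e-9)
  # below saturation the amplitude tracks the titrated KaiB linearly
  sub <- prof$b_um < 3
  expect_gt(cor(prof$b_um[sub], prof$amplitude[sub]), 0.999)
})

test_that("CS profile fitting is self-consistent and flags degeneracy", {
  grid <- c(0.9, 2, 3.3, 5.7, 8.1, 10.5)
  prof <- as_kobs_profile(grid, analytic_kobs_cs(0.5, 0.3, 1.0, grid))
  fit <- fit_cs_profile(prof)
  expect_equal(fit$k_cf, 0.5, tolerance = 1e-6)
  expect_equal(fit$k_cr, 0.3, tolerance = 1e-6)
  expect_equal(fit$kd, 1.0, tolerance = 1e-5)
  expect_true(fit$kd_identifiable)

  flat <- as_kobs_profile(grid, analytic_kobs_cs(0.5, 0, 1.0, grid))
  ffit <- fit_cs_profile(flat)
  expect_false(ffit$kd_identifiable)
  expect_true(is.na(ffit$kd))
  expect_equal(ffit$k_cf, 0.5, tolerance = 1e-9)
})

test_that("exponential relaxation fits recover exact curves and agree with midpoint half-life", {
  tt <- seq(0, 12, by = 0.05)
  cv <- fake_curve(tt, 0.3 + 0.7 * exp(-0.8 * tt))
  fit <- fit_exponential_relaxation(cv)
  expect_equal(fit$rate, 0.8, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.7, tolerance = 1e-6)
  expect_equal(fit$baseline, 0.3, tolerance = 1e-6)
  expect_equal(fit$t_half, extract_half_life(cv), tolerance = 1e-3)
})

test_that("biexponential input yields the least-squares best single exponential", {
  tt <- seq(0, 12, by = 0.05)
  y <- 0.6 * exp(-2 * tt) + 0.4 * exp(-0.5 * tt)
  fit <- fit_exponential_relaxation(fake_curve(tt, y))
  # oracle: profile the rate on a fine grid, solving (a, c) linearly per rate
  rss_at <- function(k) {
    X <- cbind(exp(-k * tt), 1)
    sum(lm.fit(X, y)$residuals^2)
  }
  ks <- seq(0.2, 3, by = 0.002)
  k_oracle <- ks[which.min(vapply(ks, rss_at, numeric(1)))]
  expect_lt(abs(fit$rate - k_oracle), 0.002 + 1e-6)
  expect_lte(sum((fit$amplitude * exp(-fit$rate * tt) + fit$baseline - y)^2),
             rss_at(k_oracle) + 1e-10)
})

test_that("mass is conserved along every trajectory in all schemes", {
  set.seed(17)
  for (mode in c("CS", "IF", "CS_dual")) {
    for (rep in 1:5) {
      p <- binding_params(mode, k_cf = runif(1, 0.1, 2), k_cr = runif(1, 0, 1),
                          k_on = runif(1, 1, 100), k_off = runif(1, 0.1, 50),
                          k_bf = runif(1, 0.5, 5), k_br = runif(1, 0.5, 5))
      e <- mix_experiment(runif(1, 0.5, 5), runif(1, 0.5, 12),
                          seq(0, 18, by = 0.1))
      cv <- simulate_relaxation(p, e)
      sp <- cv$species
      c_tot <- switch(mode, CS = rowSums(sp), IF = rowSums(sp),
                      CS_dual = sp[, 1] + sp[, 2] + sp[, 4])
      expect_lt(max(abs(c_tot - e$c_total)), 1e-6)
      cx <- sp[, ncol(sp)]
      b_bound <- switch(mode, CS = cx, IF = sp[, 2] + sp[, 3],
                        CS_dual = cx)
      expect_true(all(b_bound <= e$b_total + 1e-6))
      expect_true(all(cv$fi_app >= p$fi_bound - 1e-9 &
                        cv$fi_app <= p$fi_free + 1e-9))
    }
  }
})

test_that("a dual KaiB fold-switch keeps the decreasing CS signature when folding is fast", {
  b_grid <- c(0.9, 3.3, 5.7, 8.1, 10.5)
  p <- binding_params("CS_dual", k_cf = 0.5, k_cr = 0.3, k_on = 100,
                      k_off = 100, k_bf = 1, k_br = 1)  # k_bf >= k_cf
  prof <- kobs_profile(p, 0.2, b_grid)
  expect_true(all(diff(prof$inv_t_half) < 0))
  expect_identical(classify_mechanism(prof), "CS")
})
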