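test_that("oscillator_params derives f0/Q from k/gamma and back", {
  p <- oscillator_params(mass = 1e-10, stiffness = 4e-4, damping = 1e-7)
  expect_equal(p$natural_frequency, sqrt(4e-4 / 1e-10) / (2 * pi))
  expect_equal(p$quality_factor, sqrt(1e-10 * 4e-4) / 1e-7)
  q <- oscillator_params(mass = p$mass, natural_frequency = p$natural_frequency,
                         quality_factor = p$quality_factor)
  expect_equal(q$stiffness, p$stiffness, tolerance = 1e-12)
  expect_equal(q$damping, p$damping, tolerance = 1e-12)
  expect_error(oscillator_params(mass = 1e-10), "exactly one of")
  expect_error(oscillator_params(mass = -1, stiffness = 1, damping = 1),
               "mass")
})

test_that("every simulator is deterministic under a fixed seed", {
  p <- oscillator_params(mass = 1e-10, natural_frequency = 300,
                         quality_factor = 2)
  t1 <- simulate_free_fluctuation(p, 0.2, 1e-4, seed = 5)
  t2 <- simulate_free_fluctuation(p, 0.2, 1e-4, seed = 5)
  expect_identical(t1, t2)

  s1 <- simulate_sweep_trial(p, sweep_stimulus("forward", amplitude = 1e-11),
                             seed = 5)
  s2 <- simulate_sweep_trial(p, sweep_stimulus("forward", amplitude = 1e-11),
                             seed = 5)
  expect_identical(s1, s2)

  g1 <- simulate_gating_experiment(seed = 5)
  g2 <- simulate_gating_experiment(seed = 5)
  expect_identical(g1, g2)

  small <- c(full_recovery = 60, male_independent = 20,
             partial_recovery = 10, mvf_only = 110)
  d1 <- simulate_de_tables(de_sim_params(n_genes = 500, seed = 5,
                                         subset_sizes = small,
                                         n_female_up = 50))
  d2 <- simulate_de_tables(de_sim_params(n_genes = 500, seed = 5,
                                         subset_sizes = small,
                                         n_female_up = 50))
  expect_identical(d1, d2)

  ## a seeded call must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_free_fluctuation(p, 0.1, 1e-4, seed = 1))
  expect_identical(runif(1), before)
})

test_that("simulator input validation rejects bad arguments", {
  p <- oscillator_params(mass = 1e-10, natural_frequency = 300,
                         quality_factor = 2)
  expect_error(simulate_free_fluctuation(p, -1, 1e-4), "duration")
  expect_error(simulate_free_fluctuation(p, 1, 0), "dt")
  expect_error(simulate_free_fluctuation(p, 1, 1e-3), "1/\\(20\\*f0\\)")
  expect_error(simulate_sweep_trial(p, sweep_stimulus("forward"),
                                    noise_level = -0.1), "noise_level")
  expect_error(simulate_sweep_trial(p, sweep_stimulus("forward"),
                                    dt = 1e-3), "Nyquist")
  expect_error(simulate_gating_experiment(n_steps = 3), "n_steps")
  expect_error(simulate_gating_experiment(displacement_noise = -1),
               "displacement_noise")
  expect_error(de_sim_params(n_genes = 100, n_female_up = 2000), "exceed")
})

test_that("zero-temperature run is a deterministic ringdown at the damped frequency", {
  q <- 12
  p <- oscillator_params(mass = 1e-10, natural_frequency = 300,
                         quality_factor = q, temperature = 0)
  tr <- simulate_free_fluctuation(p, 0.2, 1e-5, seed = 1,
                                  initial_displacement = 1e-7)
  x <- tr$displacement
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  peaks <- peaks[x[peaks] > 0]
  f_ring <- 1 / (mean(diff(peaks)) * 1e-5)
  expect_equal(f_ring, 300 * sqrt(1 - 1 / (4 * q^2)), tolerance = 2e-3)
  expect_true(all(diff(x[peaks]) < 0)) # monotonically decaying envelope
})

test_that("passive displacement variance satisfies equipartition", {
  ## female active-state tuning, 10 s at dt = 2e-5
  p <- oscillator_params(mass = 77.45e-12, natural_frequency = 220.03,
                         quality_factor = 1.19)
  tr <- simulate_free_fluctuation(p, 10, 2e-5, seed = 42)
  expect_equal(var(tr$displacement), kB * 293 / p$stiffness,
               tolerance = 0.10)
})

test_that("fluctuation-dissipation: doubling gamma keeps <x^2>, halves Q", {
  p1 <- female_passive()
  p2 <- oscillator_params(mass = p1$mass, stiffness = p1$stiffness,
                          damping = 2 * p1$damping)
  t1 <- simulate_free_fluctuation(p1, 8, 2e-5, seed = 2)
  t2 <- simulate_free_fluctuation(p2, 8, 2e-5, seed = 2)
  expect_equal(var(t2$displacement) / var(t1$displacement), 1,
               tolerance = 0.12)
  f1 <- fit_oscillator(compute_spectrum(t1))
  f2 <- fit_oscillator(compute_spectrum(t2))
  expect_equal(f2$q / f1$q, 0.5, tolerance = 0.15)
})

test_that("active boost doubles the fluctuation variance", {
  p0 <- female_passive()
  p1 <- female_passive(active_boost = 1)
  t0 <- simulate_free_fluctuation(p0, 6, 2e-5, seed = 3)
  t1 <- simulate_free_fluctuation(p1, 6, 2e-5, seed = 3)
  expect_equal(var(t1$displacement) / var(t0$displacement), 2,
               tolerance = 0.15)
  expect_identical(t1$state_label, "active")
  expect_identical(t0$state_label, "passive")
})

test_that("SSO mode superposes a limit cycle of the requested amplitude and frequency", {
  p <- oscillator_params(mass = 1e-10, natural_frequency = 350,
                         quality_factor = 2,
                         sso = list(amplitude = 5e-7, frequency = 352.79))
  tr <- simulate_free_fluctuation(p, 2, 2e-5, seed = 1)
  expect_identical(tr$oscillation_label, "SSO")
  ## limit cycle dominates: rms ~ amplitude / sqrt(2)
  expect_equal(sd(tr$displacement), 5e-7 / sqrt(2), tolerance = 0.05)
  sp <- compute_spectrum(tr)
  expect_equal(sp$frequencies[which.max(sp$amplitude)], 352.79,
               tolerance = 0.01)
})

test_that("noise-free sweep trial peaks at the planted resonance", {
  p <- oscillator_params(mass = 124.55e-12, natural_frequency = 445,
                         quality_factor = 20)
  tr <- simulate_sweep_trial(p, sweep_stimulus("forward", amplitude = 2e-11),
                             noise_level = 0, seed = 1)
  bf <- best_frequency_from_sweep(tr$displacement, tr$stimulus, tr$dt)
  ## one envelope sample = the rectified-peak spacing, half a carrier
  ## period, mapped through the sweep rate
  env_sample_hz <- 999 * 1 / (2 * tr$truth$mechanical_bf)
  expect_lt(abs(bf - tr$truth$mechanical_bf), env_sample_hz)
})

test_that("zero-amplitude sweep stimulus yields pure noise at the stated level", {
  p <- female_passive()
  st <- sweep_stimulus("forward", amplitude = 0)
  tr <- simulate_sweep_trial(p, st, noise_level = 0.05, seed = 8,
                             cap_saturation = list(max = 50, midpoint = 400,
                                                   slope = 150))
  ## displacement noise floor is 1 nm -> sd = 0.05 nm; CAP sd = 0.05 * 50
  expect_equal(sd(tr$displacement), 0.05, tolerance = 0.05)
  expect_equal(sd(tr$cap), 0.05 * 50, tolerance = 0.05)
})

test_that("gating experiment geometry matches the step protocol", {
  ex <- simulate_gating_experiment(n_steps = 20, displacement_noise = 0,
                                   seed = 1)
  expect_length(ex$forces, 40) # 20 log-spaced magnitudes per sign
  mags <- abs(ex$forces)
  expect_true(all(diff(mags[1:20]) < 0) && all(diff(mags[21:40]) > 0))
  pos <- mags[21:40]
  expect_equal(sd(diff(log(pos))), 0, tolerance = 1e-10) # log-spaced
  ## noise-free points lie exactly on the model curve
  resid <- ex$forces - gating_force_model(ex$truth, ex$displacements)
  expect_lt(max(abs(resid)) / max(abs(ex$forces)), 1e-9)
  ## CAP saturates with |displacement|
  expect_true(all(diff(ex$cap_amplitudes[21:40]) >= 0))
})

test_that("simulated sensitivity curves carry their planted gain", {
  cv <- simulate_sensitivity_curve(13.95, noise = 0, seed = 1)
  expect_equal(max(cv$sensitivity) / min(cv$sensitivity), 13.95,
               tolerance = 1e-9)
  expect_identical(attr(cv, "truth")$gain, 13.95)
  cv1 <- simulate_sensitivity_curve(1, noise = 0)
  expect_true(all(cv1$sensitivity == cv1$sensitivity[1]))
})

test_that("simulated DE tables plant exactly the requested structure", {
  prm <- de_sim_params(n_genes = 4000,
                       subset_sizes = c(full_recovery = 300,
                                        male_independent = 80,
                                        partial_recovery = 40,
                                        mvf_only = 500),
                       n_female_up = 400, seed = 21)
  sim <- simulate_de_tables(prm)
  expect_identical(nrow(sim$mvf), 4000L)
  cnt <- table(sim$truth$label)
  expect_identical(as.integer(cnt[c("full_recovery", "male_independent",
                                    "partial_recovery", "mvf_only")]),
                   c(300L, 80L, 40L, 500L))
  ## planted significance patterns hold exactly at the threshold
  thr <- prm$fdr_threshold
  fr <- sim$truth$label == "full_recovery"
  expect_true(all(sim$mvf$padj[fr] < thr & sim$mvf$log2fc[fr] > 0))
  expect_true(all(sim$ivf$padj[fr] < thr & sim$ivf$log2fc[fr] > 0))
  expect_true(all(sim$mvi$padj[fr] >= thr))
  fu <- sim$truth$label == "female_up"
  expect_true(all(sim$mvf$padj[fu] < thr & sim$mvf$log2fc[fu] < 0))
})

test_that("trace TSV + sidecar round trip preserves samples and metadata", {
  p <- oscillator_params(mass = 1e-10, natural_frequency = 300,
                         quality_factor = 2)
  tr <- simulate_free_fluctuation(p, 0.1, 1e-4, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace_tsv(tr, path)
  back <- read_trace_tsv(path)
  expect_equal(back$samples, tr$samples, tolerance = 1e-12)
  expect_equal(back$dt, tr$dt, tolerance = 1e-12)
  expect_identical(back$state_label, "passive")
  expect_equal(back$truth$natural_frequency_hz, 300)
})
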