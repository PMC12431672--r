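test_that("noiseless uniform stack demodulates to the instrument-shifted truth", {
  acq <- flim_acquisition()
  inst <- flim_instrument(phase_offset = 0.35, mod_factor = 0.8)
  scene <- uniform_scene(2.0, 800, c(24, 24))
  stk <- simulate_stack(scene, acq, inst, noiseless = TRUE)
  # oracle: general least-squares sinusoid fit per pixel
  fit <- ls_sinusoid_fit(stk$frames, stk$phases)
  truth <- mixture_phasor(flim_mixture(2.0), acq$frequency)
  expect_equal(max(abs(fit$dc - 800)), 0, tolerance = 1e-9)
  expect_equal(max(abs(fit$phase - (truth$phase + 0.35))), 0,
               tolerance = 1e-10)
  expect_equal(max(abs(fit$modulation - 0.8 * truth$modulation)), 0,
               tolerance = 1e-10)
})

test_that("zero intensity gives all-zero frames; fixed seed is bit-exact", {
  acq <- flim_acquisition(n_phases = 5)
  z <- simulate_stack(uniform_scene(1.0, 0, c(8, 8)), acq)
  expect_true(all(z$frames == 0))
  a <- simulate_stack(uniform_scene(1.0, 50, c(16, 16)), acq, seed = 99)
  b <- simulate_stack(uniform_scene(1.0, 50, c(16, 16)), acq, seed = 99)
  expect_identical(a$frames, b$frames)
  expect_true(all(a$frames == round(a$frames)))
})

test_that("Poisson sampling preserves the frame mean", {
  acq <- flim_acquisition(n_phases = 4)
  lambda <- 30
  stk <- simulate_stack(uniform_scene(1.0, lambda, c(128, 128)), acq,
                        flim_instrument(mod_factor = 1e-6), seed = 5)
  n <- 128 * 128
  for (k in 1:4) {
    fm <- mean(stk$frames[, , k])
    ex <- mean(stk$truth$dc) *
      (1 + 1e-6 * stk$truth$modulation[1] * cos(stk$phases[k] - stk$truth$phase[1]))
    expect_lt(abs(fm - ex), 3 * sqrt(ex / n))
  }
})

test_that("reference stack self-calibrates to the reference lifetime", {
  acq <- flim_acquisition(reference_lifetime = 4.0)
  inst <- flim_instrument(phase_offset = 0.7, mod_factor = 0.6)
  ref1 <- reference_stack(acq, inst, photons = 500, dim = c(16, 16),
                          noiseless = TRUE)
  ref2 <- reference_stack(acq, inst, photons = 900, dim = c(16, 16),
                          noiseless = TRUE)
  rec <- flim_reconstruct(ref1, ref2)
  expect_equal(mean(rec$lifetime$tau_phi), 4.0, tolerance = 1e-10)
  expect_equal(mean(rec$lifetime$tau_mod), 4.0, tolerance = 1e-10)
  # raw phase shifts with the instrument offset; calibrated lifetime does not
  inst2 <- flim_instrument(phase_offset = 1.4, mod_factor = 0.6)
  ref3 <- reference_stack(acq, inst2, photons = 500, dim = c(16, 16),
                          noiseless = TRUE)
  raw1 <- demodulate(ref1); raw3 <- demodulate(ref3)
  expect_equal(mean(raw3$phase - raw1$phase), 0.7, tolerance = 1e-10)
  ref4 <- reference_stack(acq, inst2, photons = 900, dim = c(16, 16),
                          noiseless = TRUE)
  rec2 <- flim_reconstruct(ref3, ref4)
  expect_equal(mean(rec2$lifetime$tau_phi), 4.0, tolerance = 1e-10)
})

test_that("halving brightness halves DC but leaves raw phase/modulation", {
  acq <- flim_acquisition()
  a <- demodulate(reference_stack(acq, photons = 1000, dim = c(8, 8),
                                  noiseless = TRUE))
  b <- demodulate(reference_stack(acq, photons = 500, dim = c(8, 8),
                                  noiseless = TRUE))
  expect_equal(b$dc, a$dc / 2, tolerance = 1e-12)
  expect_equal(b$phase, a$phase, tolerance = 1e-12)
  expect_equal(b$modulation, a$modulation, tolerance = 1e-12)
})

test_that("edge target FWHM tracks the generating PSF width", {
  img0 <- edge_target(c(4, 64), pixel_size = 0.5, psf_fwhm = 0)
  expect_setequal(unique(as.vector(img0)), c(10, 1000))
  img <- edge_target(c(8, 512), pixel_size = 0.2, psf_fwhm = 2.0)
  r <- measure_resolution(img, 0, 4, 511, 4, 0.2)
  expect_equal(r$fwhm, 2.0, tolerance = 0.05 / 2.0)
  img2 <- edge_target(c(8, 512), pixel_size = 0.2, psf_fwhm = 4.0)
  r2 <- measure_resolution(img2, 0, 4, 511, 4, 0.2)
  expect_equal(r2$fwhm / r$fwhm, 2.0, tolerance = 0.02)
})

test_that("two-population scene records deterministic ground truth", {
  mixes <- list(flim_mixture(1.0), flim_mixture(3.0))
  sc <- two_population_scene(dim = c(64, 64), n_cells = c(4, 4),
                             mixtures = mixes, seed = 3)
  sc2 <- two_population_scene(dim = c(64, 64), n_cells = c(4, 4),
                              mixtures = mixes, seed = 3)
  expect_identical(sc$labels, sc2$labels)
  expect_identical(sc$intensity, sc2$intensity)
  expect_equal(nrow(sc$cells), 8)
  expect_setequal(unique(sc$cells$population), c(1, 2))
  # cell pixels carry their population's mixture
  for (i in seq_len(nrow(sc$cells))) {
    px <- sc$labels == i
    if (any(px))
      expect_true(all(sc$regions[px] == sc$cells$population[i]))
  }
  # zero cells -> empty scene errors cleanly downstream
  sc0 <- two_population_scene(dim = c(32, 32), n_cells = c(0, 0),
                              mixtures = mixes, seed = 1)
  expect_true(all(sc0$intensity == 0))
  stk <- simulate_stack(sc0, flim_acquisition(), noiseless = TRUE)
  expect_error(summarize_masked(
    lifetime_image(calibrate(demodulate(stk),
                             demodulate(reference_stack(flim_acquisition(),
                                                        photons = 500,
                                                        dim = c(32, 32),
                                                        noiseless = TRUE)))),
    matrix(TRUE, 32, 32)), "empty mask")
})

test_that("PSF blur leaves a uniform scene's demodulation unchanged", {
  acq <- flim_acquisition(n_phases = 7)
  sc <- uniform_scene(1.5, 600, c(24, 24))
  sc$psf_fwhm <- 2.0
  stk <- simulate_stack(sc, acq, noiseless = TRUE)
  f <- demodulate(stk)
  truth <- mixture_phasor(flim_mixture(1.5), acq$frequency)
  expect_equal(max(abs(f$phase - truth$phase)), 0, tolerance = 1e-6)
  expect_equal(max(abs(f$dc - 600)), 0, tolerance = 1e-6)
})
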