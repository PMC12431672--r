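test_that("expected reference phasor matches the closed forms and limits", {
  p <- reference_phasor(4.0, 20e6)
  expect_equal(p$phase, 0.46577, tolerance = 1e-4)
  expect_equal(p$modulation, 0.89346, tolerance = 1e-4)
  p0 <- reference_phasor(0, 20e6)
  expect_equal(p0$phase, 0); expect_equal(p0$modulation, 1)
  pf <- reference_phasor(4.0, 1e-6)  # static limit f -> 0
  expect_equal(pf$phase, 0, tolerance = 1e-12)
  expect_equal(pf$modulation, 1, tolerance = 1e-12)
})

test_that("instrument phase offset and modulation factor cancel in calibration", {
  acq <- flim_acquisition()
  scene <- uniform_scene(2.5, 700, c(12, 12))
  for (inst in list(flim_instrument(0, 1),
                    flim_instrument(0.7, 1),
                    flim_instrument(0.7, 0.5),
                    flim_instrument(-2.9, 0.31))) {
    smp <- simulate_stack(scene, acq, inst, noiseless = TRUE)
    ref <- reference_stack(acq, inst, photons = 400, dim = c(12, 12),
                           noiseless = TRUE)
    cal <- calibrate(demodulate(smp), demodulate(ref))
    truth <- mixture_phasor(flim_mixture(2.5), acq$frequency)
    expect_equal(max(abs(cal$phase - truth$phase)), 0, tolerance = 1e-10)
    expect_equal(max(abs(cal$modulation - truth$modulation)), 0,
                 tolerance = 1e-10)
  }
})

test_that("self-calibration returns the reference phasor exactly", {
  acq <- flim_acquisition()
  inst <- flim_instrument(0.4, 0.9)
  a <- reference_stack(acq, inst, photons = 300, dim = c(10, 10),
                       noiseless = TRUE)
  b <- reference_stack(acq, inst, photons = 800, dim = c(10, 10),
                       noiseless = TRUE)
  truth <- reference_phasor(acq$reference_lifetime, acq$frequency)
  for (mode in c("pixel", "global")) {
    cal <- calibrate(demodulate(a), demodulate(b), reference_mode = mode)
    expect_equal(max(abs(cal$phase - truth$phase)), 0, tolerance = 1e-10)
    expect_equal(max(abs(cal$modulation - truth$modulation)), 0,
                 tolerance = 1e-10)
  }
})

test_that("lifetime conversions invert the phasor relations and gate domains", {
  w <- 2 * pi * 20e6 * 1e-9
  expect_equal(lifetime_from_phase(0, 20e6), 0)
  expect_equal(lifetime_from_phase(0.46577, 20e6), 4.0, tolerance = 1e-4)
  expect_true(is.na(lifetime_from_phase(-0.05, 20e6)))
  expect_true(is.na(lifetime_from_phase(pi / 2, 20e6)))
  expect_equal(lifetime_from_modulation(1, 20e6), 0)
  expect_equal(lifetime_from_modulation(0.89346, 20e6), 4.0,
               tolerance = 1e-4)
  expect_true(is.na(lifetime_from_modulation(1.02, 20e6)))
  expect_true(is.na(lifetime_from_modulation(0, 20e6)))
  expect_true(is.na(lifetime_from_modulation(-0.1, 20e6)))
  # vectorized with sentinel passthrough
  v <- lifetime_from_phase(c(0.1, -0.1, NA, 0.4), 20e6)
  expect_equal(is.na(v), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(v[1], tan(0.1) / w, tolerance = 1e-12)
})

test_that("noiseless round trip recovers lifetimes across the working range", {
  acq <- flim_acquisition()
  inst <- flim_instrument(0.3, 0.7)
  ref <- reference_stack(acq, inst, photons = 600, dim = c(8, 8),
                         noiseless = TRUE)
  for (tau in c(0.5, 1, 2, 4, 8)) {
    smp <- simulate_stack(uniform_scene(tau, 600, c(8, 8)), acq, inst,
                          noiseless = TRUE)
    lt <- flim_reconstruct(smp, ref)$lifetime
    expect_equal(max(abs(lt$tau_phi - tau)), 0, tolerance = 1e-6)
    expect_equal(max(abs(lt$tau_mod - tau)), 0, tolerance = 1e-6)
  }
})

test_that("two-component phantoms give tau_phi < tau_mod at every pixel", {
  acq <- flim_acquisition()
  ref <- reference_stack(acq, photons = 600, dim = c(8, 8),
                         noiseless = TRUE)
  smp <- simulate_stack(uniform_scene(nadh_mixture(0.6), 600, c(8, 8)),
                        acq, noiseless = TRUE)
  lt <- flim_reconstruct(smp, ref)$lifetime
  expect_true(all(lt$tau_phi < lt$tau_mod))
})

test_that("calibrating noisy reference realizations is unbiased at high flux", {
  acq <- flim_acquisition()
  # 1e5 photons per pixel per stack -> 4000 per frame at K = 25
  a <- reference_stack(acq, photons = 4000, dim = c(64, 64), seed = 51)
  b <- reference_stack(acq, photons = 4000, dim = c(64, 64), seed = 52)
  lt <- flim_reconstruct(a, b)$lifetime
  expect_equal(mean(lt$tau_phi, na.rm = TRUE), 4.0, tolerance = 0.01)
  expect_equal(mean(lt$tau_mod, na.rm = TRUE), 4.0, tolerance = 0.01)
})

test_that("lifetime maps are invariant to global intensity rescaling", {
  acq <- flim_acquisition()
  ref <- reference_stack(acq, photons = 500, dim = c(8, 8), noiseless = TRUE)
  smp <- simulate_stack(uniform_scene(3.0, 500, c(8, 8)), acq,
                        noiseless = TRUE)
  smp9 <- smp; smp9$frames <- smp$frames * 9
  lt <- flim_reconstruct(smp, ref)$lifetime
  lt9 <- flim_reconstruct(smp9, ref)$lifetime
  expect_equal(lt9$tau_phi, lt$tau_phi, tolerance = 1e-12)
  expect_equal(lt9$tau_mod, lt$tau_mod, tolerance = 1e-12)
})
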