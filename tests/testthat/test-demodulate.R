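make_stack <- function(A, b, phi, K = 25, dim = c(6, 6),
                       acq = flim_acquisition(n_phases = K)) {
  theta <- phase_steps(K)
  fr <- array(0, c(dim, K))
  for (k in seq_len(K))
    fr[, , k] <- A * (1 + b * cos(theta[k] - phi))
  phase_stack(fr, theta, acq)
}

test_that("DFT demodulation recovers the generating sinusoid exactly", {
  stk <- make_stack(100, 0.5, 0.3)
  f <- demodulate(stk)
  expect_equal(max(abs(f$dc - 100)), 0, tolerance = 1e-10)
  expect_equal(max(abs(f$modulation - 0.5)), 0, tolerance = 1e-10)
  expect_equal(max(abs(f$phase - 0.3)), 0, tolerance = 1e-10)
  # g/s consistency and phasor norm
  expect_equal(f$modulation, sqrt(f$g^2 + f$s^2), tolerance = 1e-12)
  # works at the minimum K
  f3 <- demodulate(make_stack(50, 0.4, -1.2, K = 3))
  expect_equal(max(abs(f3$phase - (-1.2))), 0, tolerance = 1e-10)
  expect_equal(max(abs(f3$modulation - 0.4)), 0, tolerance = 1e-10)
})

test_that("constant frames are flagged invalid, not an exception", {
  stk <- make_stack(100, 0, 0)
  f <- demodulate(stk)
  expect_true(all(f$valid))          # dc = 100 is fine
  expect_equal(max(f$modulation), 0, tolerance = 1e-12)
  z <- make_stack(0, 0, 0)
  fz <- demodulate(z)
  expect_false(any(fz$valid))
  expect_true(all(is.na(fz$g)))
  expect_error(phase_stack(array(1, c(4, 4, 2)), c(0, pi),
                           flim_acquisition()), "K >= 3")
})

test_that("demodulation is linear in intensity scaling", {
  stk <- make_stack(40, 0.6, 1.1)
  stk7 <- stk; stk7$frames <- stk$frames * 7
  f <- demodulate(stk); f7 <- demodulate(stk7)
  expect_equal(f7$dc, f$dc * 7, tolerance = 1e-12)
  expect_equal(f7$phase, f$phase, tolerance = 1e-12)
  expect_equal(f7$modulation, f$modulation, tolerance = 1e-12)
})

test_that("DFT demodulation equals the least-squares fit on random stacks", {
  set.seed(21)
  for (rep in 1:10) {
    K <- sample(3:30, 1)
    dimv <- c(5, 4)
    theta <- phase_steps(K)
    A <- matrix(runif(20, 10, 200), 5, 4)
    b <- matrix(runif(20, 0, 0.95), 5, 4)
    phi <- matrix(runif(20, -pi, pi), 5, 4)
    fr <- array(0, c(dimv, K))
    for (k in seq_len(K)) fr[, , k] <- A * (1 + b * cos(theta[k] - phi))
    # add arbitrary non-sinusoidal perturbation? no: equivalence holds for
    # any data at uniform steps, so perturb freely
    fr <- fr + array(runif(length(fr), 0, 5), dim(fr))
    stk <- phase_stack(fr, theta, flim_acquisition(n_phases = K))
    f <- demodulate(stk, dc_min = 0)
    o <- ls_sinusoid_fit(fr, theta)
    expect_equal(f$dc, o$dc, tolerance = 1e-9)
    expect_equal(f$modulation, o$modulation, tolerance = 1e-9)
    expect_equal(f$phase, o$phase, tolerance = 1e-9)
  }
})

test_that("adding a constant offset image changes modulation but not phase", {
  stk <- make_stack(80, 0.5, 0.9)
  off <- stk; off$frames <- stk$frames + 25
  f <- demodulate(stk); fo <- demodulate(off)
  expect_equal(fo$phase, f$phase, tolerance = 1e-10)
  expect_equal(fo$dc, f$dc + 25, tolerance = 1e-10)
  expect_lt(max(fo$modulation), max(f$modulation))
})

test_that("phase noise scales as 1/sqrt(photons) under shot noise", {
  acq <- flim_acquisition()
  sd_at <- function(photons_per_frame, seed) {
    stk <- simulate_stack(uniform_scene(4.0, photons_per_frame, c(64, 64)),
                          acq, seed = seed)
    f <- demodulate(stk, dc_min = 0)
    sd(f$phase)
  }
  r <- sd_at(40, 31) / sd_at(400, 32)
  expect_equal(r, sqrt(10), tolerance = 0.2)
})

test_that("flat-field normalizes vignetting and flags dead reference pixels", {
  acq <- flim_acquisition()
  vig <- vignetting_field(c(32, 32), 0.5)
  scene <- flim_scene(matrix(2500, 32, 32), flim_mixture(2.0),
                      illumination = vig)
  smp <- simulate_stack(scene, acq, seed = 41)
  ref <- reference_stack(acq, photons = 2500, dim = c(32, 32),
                         illumination = vig, seed = 42)
  ni <- flat_field(demodulate(smp), demodulate(ref))
  expect_lt(sd(ni) / mean(ni), 0.01)   # uniform to < 1% RMS
  # identical fields give exactly 1
  f <- demodulate(smp)
  expect_equal(as.vector(flat_field(f, f)), rep(1, 32 * 32),
               tolerance = 1e-12)
  # a zero reference pixel invalidates only that pixel
  rf <- demodulate(ref)
  rf$dc[3, 7] <- 0
  ni2 <- flat_field(f, rf)
  expect_true(is.na(ni2[3, 7]))
  expect_equal(sum(is.na(ni2)), 1L)
  expect_error(flat_field(f, demodulate(reference_stack(acq, photons = 10,
                                                        dim = c(8, 8)))),
               "shapes differ")
})
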