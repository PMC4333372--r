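# simulate module: PSF width law, frame rendering, calibration stacks and
# Brownian / two-state path generation.

test_that("psfWidth follows the astigmatic width law", {
  psf <- PsfModel()
  # minimum at the axis' own focal plane equals sigma0
  expect_equal(psfWidth(psf, -psf@focalSeparation / 2, "x"), psf@sigma0)
  expect_equal(psfWidth(psf, psf@focalSeparation / 2, "y"), psf@sigma0)
  # equal widths at the effective focal plane
  expect_equal(psfWidth(psf, 0, "x"), psfWidth(psf, 0, "y"))
  # mirror symmetry about the effective focus
  expect_equal(psfWidth(psf, 0.4, "x"), psfWidth(psf, -0.4, "y"))
  # strictly increasing away from the own focal plane
  z <- seq(-0.4, 1.5, by = 0.1)
  expect_true(all(diff(psfWidth(psf, z, "x")) > 0))
})

test_that("renderFrame conserves photons and hits the width ratio", {
  psf <- PsfModel(); cam <- CameraModel()
  # photons = 0, noise off -> uniform background
  img0 <- renderOne(2.52, 2.52, 0, 0, psf, cam)
  expect_true(all(abs(img0 - cam@backgroundMean) < 1e-12))
  # photon conservation within 0.5%
  img <- renderOne(2.52, 2.52, 0.2, 10000, psf, cam)
  expect_lt(abs(sum(img - cam@backgroundMean) / 10000 - 1), 0.005)
  # emitter at z = +0.4: fitted width ratio matches the model within 2%
  img4 <- renderOne(2.52, 2.52, 0.4, 20000, psf, cam)
  g <- gaussianFitSpot(img4, c(11, 11), window = 15L)
  ratioTrue <- psfWidth(psf, 0.4, "x") / psfWidth(psf, 0.4, "y")
  expect_true(g$converged)
  expect_lt(abs(g$sigmaX / g$sigmaY / ratioTrue - 1), 0.02)
  # emitter outside the field and negative photons are rejected
  expect_error(renderOne(-1, 2.52, 0, 100, psf, cam), "field")
  expect_error(renderOne(2.52, 2.52, 0, -5, psf, cam), "photon")
})

test_that("renderCalibrationStack produces the documented stack", {
  fix <- calibFixture()
  # range -1..+1 step 0.05 -> 41 slices
  expect_equal(dim(fix$stack)[3], 41L)
  expect_equal(fix$z, seq(-1, 1, by = 0.05))
  # center slice: equal fitted x/y widths (noise-free)
  mid <- which(fix$z == 0)
  g <- gaussianFitSpot(fix$stack[, , mid], c(11, 11), window = 15L)
  expect_lt(abs(g$sigmaX / g$sigmaY - 1), 1e-3)
  # per-slice SNR >= 50 on the high-photon stack (peak over background,
  # divided by background s.d.)
  snr <- apply(fix$stack, 3, function(m)
    (max(m) - fix$cam@backgroundMean) / fix$cam@backgroundSd)
  expect_true(all(snr >= 50))
  expect_error(renderCalibrationStack(fix$psf, fix$cam, zMin = 1, zMax = -1),
               "range|zMin")
})

test_that("simulatePath has correct increments, occupancy and determinism", {
  # D = 0 -> constant position
  m0 <- MotionModel(diffusion = 0, dims = "xy")
  p0 <- simulatePath(m0, 50, seed = 4)
  expect_true(all(p0$positions == 0))
  # single state: per-axis increment variance = 2 D dt within 3 s.e.
  D <- 1; dt <- 0.0165
  m1 <- MotionModel(diffusion = D, dims = "xyz", frameInterval = dt)
  p1 <- simulatePath(m1, 10000, seed = 7)
  for (ax in 1:3) {
    v <- var(diff(p1$positions[, ax]))
    se <- 2 * D * dt * sqrt(2 / (10000 - 1))
    expect_lt(abs(v - 2 * D * dt), 3 * se)
  }
  # empirical MSD at small lags matches 2 dim D m dt
  tr <- Trajectory(frame = seq_len(nrow(p1$positions)),
                   x = p1$positions[, 1], y = p1$positions[, 2],
                   z = p1$positions[, 3], frameInterval = dt)
  ms <- msdCurve(tr, dims = "xyz", maxLag = 4L)
  expect_true(all(abs(ms$msd / (6 * D * ms$lag * dt) - 1) < 0.1))
  # two states, zero switching -> labels constant
  m2 <- MotionModel(diffusion = c(1, 0.1), switchRates = matrix(0, 2, 2),
                    dims = "xy", frameInterval = dt)
  p2 <- simulatePath(m2, 100, startState = 2L, seed = 5)
  expect_true(all(p2$states == 2L))
  # occupancy converges to kBA / (kAB + kBA) within 3 s.e. (two-state
  # Markov chain variance with autocorrelation factor (1+rho)/(1-rho))
  kAB <- 3; kBA <- 6
  m3 <- MotionModel(diffusion = c(1, 0.1),
                    switchRates = matrix(c(0, kBA, kAB, 0), 2, 2),
                    dims = "xy", frameInterval = dt)
  n <- 20000L
  p3 <- simulatePath(m3, n, seed = 11)
  occ <- mean(p3$states == 1L)
  pAB <- 1 - exp(-kAB * dt); pBA <- 1 - exp(-kBA * dt)
  pi1 <- pBA / (pAB + pBA)
  rho <- 1 - pAB - pBA
  se <- sqrt(pi1 * (1 - pi1) / n * (1 + rho) / (1 - rho))
  expect_lt(abs(occ - pi1), 3 * se)
  # bit-reproducibility
  expect_identical(simulatePath(m3, 100, seed = 42),
                   simulatePath(m3, 100, seed = 42))
})

test_that("simulateJumps draws from the stated mixture", {
  r2 <- simulateJumps(40000, D = c(0.2, 2), fractions = c(0.3, 0.7),
                      dt = 0.02, dims = 2L, seed = 9)
  comp <- attr(r2, "component")
  expect_equal(length(r2), 40000L)
  expect_lt(abs(mean(comp == 1) - 0.3), 3 * sqrt(0.3 * 0.7 / 40000))
  # per-component mean r2 = 2 dims D dt
  expect_lt(abs(mean(r2[comp == 1]) / (4 * 0.2 * 0.02) - 1), 0.05)
  expect_lt(abs(mean(r2[comp == 2]) / (4 * 2 * 0.02) - 1), 0.05)
  expect_identical(
    as.numeric(simulateJumps(10, 1, 1, 0.02, seed = 3)),
    as.numeric(simulateJumps(10, 1, 1, 0.02, seed = 3)))
})

test_that("photonsForSnr realizes the requested peak SNR", {
  psf <- PsfModel(); cam <- CameraModel()
  ph <- photonsForSnr(psf, cam, 8)
  img <- renderOne(2.52, 2.52, 0, ph, psf, cam)  # emitter at a pixel center
  snr <- (max(img) - cam@backgroundMean) / cam@backgroundSd
  expect_lt(abs(snr - 8), 0.01)
})
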