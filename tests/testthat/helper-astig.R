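# Shared fixtures and brute-force oracles for the astigTrack test suite.

# Exhaustive-enumeration oracle for the run-length statistic: probability
# that n Bernoulli(p) trials contain no run of >= k successes, summed over
# all 2^n state sequences. Tractable for n <= 16.
enumProbNoRun <- function(n, k, p) {
  if (k > n) return(1)
  seqs <- 0:(2^n - 1)
  # max run of 1-bits: repeatedly AND with the left-shifted value
  y <- seqs
  maxRun <- integer(length(seqs))
  repeat {
    nz <- y != 0L
    if (!any(nz)) break
    maxRun[nz] <- maxRun[nz] + 1L
    y <- bitwAnd(y, bitwShiftL(y, 1L))
  }
  # number of successes (popcount)
  nA <- integer(length(seqs))
  t <- seqs
  for (b in seq_len(n)) {
    nA <- nA + t %% 2L
    t <- t %/% 2L
  }
  sum((p^nA * (1 - p)^(n - nA))[maxRun < k])
}

# One noise-free high-photon calibration (stack, templates, curve), built
# once per test run and shared across files.
.astigCache <- new.env(parent = emptyenv())

calibFixture <- function() {
  if (!is.null(.astigCache$fix)) return(.astigCache$fix)
  psf <- PsfModel()
  cam <- CameraModel()
  st <- renderCalibrationStack(psf, cam, photons = 20000, noise = FALSE)
  tp <- extractTemplates(st$stack, st$z)
  curve <- fitCalibration(st$stack, st$z, tp[[1]], tp[[2]])
  .astigCache$fix <- list(psf = psf, cam = cam, stack = st$stack, z = st$z,
                          t1 = tp[[1]], t2 = tp[[2]], curve = curve)
  .astigCache$fix
}

# Calibration slopes from frame-averaged noisy stacks at SNR 5 and 50
# (3 seeds each); cached because the acceptance suite and the calibrate
# module tests share the measurement.
snrSlopes <- function() {
  if (!is.null(.astigCache$snr)) return(.astigCache$snr)
  psf <- PsfModel(); cam <- CameraModel()
  slopeAt <- function(snr, seed, fps) {
    ph <- photonsForSnr(psf, cam, snr)
    st <- renderCalibrationStack(psf, cam, photons = ph, noise = TRUE,
                                 framesPerSlice = fps, seed = seed)
    tp <- extractTemplates(st$stack, st$z)
    calSlope(fitCalibration(st$stack, st$z, tp[[1]], tp[[2]]))
  }
  .astigCache$snr <- list(
    a5 = vapply(1:3, function(s) slopeAt(5, 100 + s, 400L), numeric(1)),
    a50 = vapply(1:3, function(s) slopeAt(50, 200 + s, 100L), numeric(1)))
  .astigCache$snr
}

# Render one noise-free emitter at (x, y, z) micron in a size x size frame.
renderOne <- function(x, y, z, photons, psf, cam, size = 21L,
                      noise = FALSE, seed = NULL) {
  renderFrame(data.frame(x = x, y = y, z = z, photons = photons),
              psf, cam, size = c(size, size), noise = noise, seed = seed)
}
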