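# Synthetic data generation: astigmatic PSF rendering, calibration stacks and
# Brownian / two-state trajectories. All stochastic functions accept a seed
# and restore the caller's RNG state.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' PSF width along one axis at a given axial position
#'
#' Gaussian-beam width law per axis: the x focal plane sits at
#' \code{-focalSeparation/2}, the y focal plane at \code{+focalSeparation/2},
#' and each width grows as \eqn{\sigma_0\sqrt{1 + ((z - z_f)/d)^2}} away from
#' its own focal plane. At z = 0 (the effective focal plane) both widths are
#' equal.
#'
#' @param model a \code{\link{PsfModel}}.
#' @param z axial position(s) relative to the effective focal plane (micron).
#' @param axis \code{"x"} or \code{"y"}.
#' @return PSF standard deviation(s) in micron.
#' @export
psfWidth <- function(model, z, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(is(model, "PsfModel"))
  validObject(model)
  zf <- if (axis == "x") -model@focalSeparation / 2 else
    model@focalSeparation / 2
  model@sigma0 * sqrt(1 + ((z - zf) / model@depthScale)^2)
}

# Fraction of an emitter's photons falling in the brightest pixel when the
# emitter sits at a pixel center; used for SNR bookkeeping.
peakPixelFraction <- function(psf, cam, z = 0) {
  ps <- cam@pixelSize
  sx <- psfWidth(psf, z, "x"); sy <- psfWidth(psf, z, "y")
  fx <- pnorm(ps / 2, 0, sx) - pnorm(-ps / 2, 0, sx)
  fy <- pnorm(ps / 2, 0, sy) - pnorm(-ps / 2, 0, sy)
  fx * fy
}

#' Photon count producing a requested peak SNR
#'
#' SNR is defined as the expected peak pixel amplitude above the mean
#' background, divided by the background standard deviation.
#'
#' @param psf a \code{\link{PsfModel}}.
#' @param cam a \code{\link{CameraModel}}.
#' @param snr requested signal-to-noise ratio.
#' @param z axial position of the emitter (micron).
#' @return photons per signal.
#' @export
photonsForSnr <- function(psf, cam, snr, z = 0) {
  snr * cam@backgroundSd / peakPixelFraction(psf, cam, z)
}

#' Render one astigmatic image frame
#'
#' Each emitter contributes an elliptical Gaussian with axis widths given by
#' \code{\link{psfWidth}} at its axial position, integrated exactly over the
#' pixel grid, on top of the camera background. With \code{noise = TRUE},
#' the signal receives Poisson shot noise inflated by the EM excess factor,
#' the background is Gaussian with the camera's mean and s.d., and Gaussian
#' read noise is added.
#'
#' Coordinates are in micron with the origin at the image corner; the center
#' of pixel (row i, column j) is at y = (i - 0.5) and x = (j - 0.5) times the
#' pixel size. Matrices are indexed [row = y, column = x].
#'
#' @param emitters data.frame with columns \code{x}, \code{y}, \code{z}
#'   (micron; z relative to the effective focal plane) and \code{photons}.
#' @param psf a \code{\link{PsfModel}}.
#' @param cam a \code{\link{CameraModel}}.
#' @param size integer(2), image size in pixels (rows, columns).
#' @param noise logical, add camera noise.
#' @param seed optional integer seed (RNG state is restored).
#' @return numeric matrix of pixel values (photons).
#' @export
renderFrame <- function(emitters, psf, cam, size = c(21L, 21L), noise = TRUE,
                        seed = NULL) {
  stopifnot(is(psf, "PsfModel"), is(cam, "CameraModel"))
  size <- as.integer(size)
  ps <- cam@pixelSize
  if (any(emitters$photons < 0)) stop("photon counts must be non-negative")
  if (nrow(emitters) > 0 &&
      any(emitters$x < 0 | emitters$x > size[2] * ps |
          emitters$y < 0 | emitters$y > size[1] * ps))
    stop("emitter position outside the image field")
  signal <- matrix(0, size[1], size[2])
  xEdges <- (0:size[2]) * ps
  yEdges <- (0:size[1]) * ps
  for (e in seq_len(nrow(emitters))) {
    sx <- psfWidth(psf, emitters$z[e], "x")
    sy <- psfWidth(psf, emitters$z[e], "y")
    fx <- diff(pnorm(xEdges, emitters$x[e], sx))
    fy <- diff(pnorm(yEdges, emitters$y[e], sy))
    signal <- signal + emitters$photons[e] * (fy %o% fx)
  }
  if (!noise) return(signal + cam@backgroundMean)
  withSeed(seed, {
    shot <- cam@emExcessFactor * (matrix(rpois(length(signal), signal),
                                         size[1]) - signal)
    bg <- matrix(rnorm(length(signal), cam@backgroundMean, cam@backgroundSd),
                 size[1])
    rn <- if (cam@readNoiseSd > 0)
      matrix(rnorm(length(signal), 0, cam@readNoiseSd), size[1]) else 0
    signal + shot + bg + rn
  })
}

#' Render an axial calibration stack
#'
#' One centered emitter per slice, stepped through the focal region the way a
#' bead sample is scanned with a piezo stage (50 nm default step).
#'
#' @param psf a \code{\link{PsfModel}}.
#' @param cam a \code{\link{CameraModel}}.
#' @param zMin,zMax axial range (micron), \code{zMin < zMax}.
#' @param step axial step (micron).
#' @param photons photons per signal in each slice.
#' @param size image size in pixels (odd; the emitter sits at the center of
#'   the central pixel).
#' @param noise logical, add camera noise.
#' @param framesPerSlice number of exposures averaged per slice (>= 1), the
#'   way a static bead is integrated during a real calibration scan.
#' @param seed optional integer seed.
#' @return list with \code{stack} (rows x cols x slices array) and \code{z}
#'   (numeric vector of slice positions).
#' @export
renderCalibrationStack <- function(psf, cam, zMin = -1, zMax = 1,
                                   step = 0.05, photons = 5000,
                                   size = 21L, noise = FALSE,
                                   framesPerSlice = 1L, seed = NULL) {
  if (zMin >= zMax) stop("'zMin' must be smaller than 'zMax'")
  if (step <= 0) stop("'step' must be positive")
  size <- as.integer(size)
  if (size %% 2L == 0L) stop("'size' must be odd")
  framesPerSlice <- as.integer(framesPerSlice)
  if (framesPerSlice < 1L) stop("'framesPerSlice' must be >= 1")
  z <- zMin + step * 0:floor((zMax - zMin) / step + 1e-9)
  center <- (size / 2) * cam@pixelSize  # center of the central pixel
  stack <- array(0, c(size, size, length(z)))
  em <- data.frame(x = center, y = center, z = 0, photons = photons)
  withSeed(seed, {
    for (i in seq_along(z)) {
      em$z <- z[i]
      acc <- renderFrame(em, psf, cam, size = c(size, size), noise = noise)
      if (noise && framesPerSlice > 1L) {
        for (f in seq_len(framesPerSlice - 1L))
          acc <- acc + renderFrame(em, psf, cam, size = c(size, size),
                                   noise = TRUE)
        acc <- acc / framesPerSlice
      }
      stack[, , i] <- acc
    }
  })
  list(stack = stack, z = z)
}

#' Simulate a Brownian path with optional mobility-state switching
#'
#' Per-axis Gaussian increments with variance \eqn{2 D \Delta t} where D is
#' the diffusion coefficient of the current state. States switch as a
#' discrete-time Markov chain with per-frame probabilities
#' \eqn{1 - e^{-k_{ij}\Delta t}}.
#'
#' @param motion a \code{\link{MotionModel}}.
#' @param nSteps number of displacement steps (>= 1); the path has
#'   \code{nSteps + 1} positions.
#' @param startState initial state index.
#' @param start numeric start position (length 2 or 3 matching \code{dims});
#'   defaults to the origin.
#' @param seed optional integer seed.
#' @return list with \code{positions} (matrix, \code{nSteps + 1} rows) ,
#'   \code{states} (integer vector per position) and \code{t} (times in s).
#' @export
simulatePath <- function(motion, nSteps, startState = 1L, start = NULL,
                         seed = NULL) {
  stopifnot(is(motion, "MotionModel"))
  validObject(motion)
  if (nSteps < 1) stop("'nSteps' must be >= 1")
  dims <- if (motion@dims == "xy") 2L else 3L
  if (is.null(start)) start <- rep(0, dims)
  ns <- length(motion@diffusion)
  dt <- motion@frameInterval
  # per-frame transition matrix
  P <- diag(ns)
  if (ns > 1L) {
    for (i in seq_len(ns)) {
      off <- setdiff(seq_len(ns), i)
      pr <- 1 - exp(-motion@switchRates[i, off] * dt)
      P[i, off] <- pr
      P[i, i] <- 1 - sum(pr)
      if (P[i, i] < 0) stop("switching rates too large for the frame interval")
    }
  }
  withSeed(seed, {
    states <- integer(nSteps + 1L)
    states[1L] <- as.integer(startState)
    if (ns > 1L) {
      for (i in seq_len(nSteps))
        states[i + 1L] <- sample.int(ns, 1L, prob = P[states[i], ])
    } else states[] <- 1L
    sdStep <- sqrt(2 * motion@diffusion[states[-(nSteps + 1L)]] * dt)
    steps <- matrix(rnorm(nSteps * dims, 0, rep(sdStep, dims)),
                    nSteps, dims)
    cum <- apply(steps, 2, cumsum)
    if (nSteps == 1L) cum <- matrix(cum, 1L)
    positions <- rbind(start, sweep(cum, 2, start, "+"))
    dimnames(positions) <- list(NULL, c("x", "y", "z")[seq_len(dims)])
    rownames(positions) <- NULL
    list(positions = positions, states = states, t = (0:nSteps) * dt)
  })
}

#' Squared jumps drawn directly from a mobility mixture
#'
#' Convenience generator for the jump-distance model: each squared
#' displacement is drawn from the mixture distribution whose survival
#' function is \eqn{\sum_i a_i e^{-r^2/(4 D_i \Delta t)}} (2D kernel) or the
#' corresponding 3-dimensional chi-square law, with independent
#' per-jump component membership.
#'
#' @param n number of jumps.
#' @param D diffusion coefficients per component (micron^2/s).
#' @param fractions component fractions (sum to 1).
#' @param dt lag time (s).
#' @param dims 2 or 3.
#' @param seed optional integer seed.
#' @return numeric vector of squared displacements (micron^2), with the
#'   drawn component index as attribute \code{"component"}.
#' @export
simulateJumps <- function(n, D, fractions, dt, dims = 2L, seed = NULL) {
  stopifnot(length(D) == length(fractions),
            abs(sum(fractions) - 1) < 1e-8, all(D > 0))
  withSeed(seed, {
    comp <- sample.int(length(D), n, replace = TRUE, prob = fractions)
    scale <- 2 * D[comp] * dt  # per-axis variance
    r2 <- scale * stats::rchisq(n, df = dims)
    attr(r2, "component") <- comp
    r2
  })
}
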