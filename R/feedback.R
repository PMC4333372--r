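# Simulated axial feedback loop: per-frame re-centering of the focal plane
# on the tracked particle, with configurable latency and gain, and
# reconstruction of absolute coordinates from the stage trace.

#' Stage trace of a feedback-tracking run
#'
#' Per-frame axial stage position and commanded move, together with the loop
#' parameters used.
#'
#' @slot frame integer vector of frame indices.
#' @slot stageZ numeric vector, stage (focal-plane) position in specimen
#'   coordinates (micron) during each frame.
#' @slot move numeric vector, move commanded after each frame (micron).
#' @slot latency integer(1), frames between estimate and applied move (>= 1).
#' @slot gain numeric(1), proportional feedback gain.
#' @export
setClass("StageTrace",
  representation(frame = "integer", stageZ = "numeric", move = "numeric",
                 latency = "integer", gain = "numeric"))

setValidity("StageTrace", function(object) {
  msg <- NULL
  n <- length(object@frame)
  if (length(object@stageZ) != n || length(object@move) != n)
    msg <- c(msg, "stageZ and move must have one entry per frame")
  if (object@latency < 1L) msg <- c(msg, "'latency' must be >= 1")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "StageTrace", function(object) {
  cat("StageTrace:", length(object@frame), "frames, latency",
      object@latency, "frame(s), gain", object@gain, "\n")
})

#' Proportional feedback step
#'
#' The sample-stage move that re-centers the focal plane on the particle:
#' \code{-gain * zRel}. Moving the sample stage by \code{m} displaces the
#' focal plane by \code{-m} in specimen coordinates, so with the convention
#' \code{zRel = zAbs - stageZ} (where \code{stageZ} is the focal-plane
#' position in specimen coordinates) this move re-centers the particle.
#' Out-of-range estimates hold the current position.
#'
#' @param zRel estimated axial offset of the particle from the focal plane
#'   (micron).
#' @param gain proportional gain.
#' @param inRange logical; FALSE holds the stage.
#' @return commanded sample-stage move (micron).
#' @export
feedbackStep <- function(zRel, gain = 1, inRange = TRUE) {
  ifelse(inRange & is.finite(zRel), -gain * zRel, 0)
}

#' Absolute axial coordinate from relative localization and stage position
#'
#' @param zRel axial localizations relative to the focal plane (micron).
#' @param stageZ focal-plane (stage) positions in specimen coordinates
#'   (micron), same length.
#' @return absolute axial coordinates \code{stageZ + zRel}.
#' @export
absoluteZ <- function(zRel, stageZ) {
  if (length(zRel) != length(stageZ))
    stop("'zRel' and 'stageZ' must have equal length")
  stageZ + zRel
}

# Lean single-emitter renderer used inside the closed loop (no data.frame
# plumbing; draws from the current RNG stream).
renderSpot <- function(x, y, z, photons, psf, cam, size, noise = TRUE) {
  ps <- cam@pixelSize
  zf <- psf@focalSeparation / 2
  sx <- psf@sigma0 * sqrt(1 + ((z + zf) / psf@depthScale)^2)
  sy <- psf@sigma0 * sqrt(1 + ((z - zf) / psf@depthScale)^2)
  fx <- diff(pnorm((0:size) * ps, x, sx))
  fy <- diff(pnorm((0:size) * ps, y, sy))
  signal <- photons * (fy %o% fx)
  if (!noise) return(signal + cam@backgroundMean)
  npx <- size * size
  signal + cam@emExcessFactor * (rpois(npx, signal) - signal) +
    rnorm(npx, cam@backgroundMean, cam@backgroundSd) +
    (if (cam@readNoiseSd > 0) rnorm(npx, 0, cam@readNoiseSd) else 0)
}

#' Run a simulated closed axial feedback loop
#'
#' Per frame: the particle performs one Brownian step, is rendered at its
#' position relative to the current focal plane, localized (peak + centroid
#' + template metric), and the axial estimate is converted into a stage move
#' applied after the configured latency. The run terminates with a loss flag
#' when the particle leaves the axial capture range or localization fails on
#' three consecutive frames. The lateral rendering window follows the last
#' lateral estimate, emulating the search-radius behavior of real-time
#' tracking.
#'
#' @param motion a \code{\link{MotionModel}} (use \code{dims = "xyz"} for
#'   free diffusion).
#' @param psf a \code{\link{PsfModel}}.
#' @param cam a \code{\link{CameraModel}}.
#' @param curve a \code{\link{CalibrationCurve}}.
#' @param nFrames maximum number of frames.
#' @param latency frames between localization and applied move (>= 1).
#' @param gain proportional feedback gain.
#' @param captureRange axial half-range (micron) beyond which the particle
#'   is lost.
#' @param photons photons per signal.
#' @param startOffset initial axial offset of the particle from the focal
#'   plane (micron).
#' @param noise logical, camera noise on.
#' @param windowSize rendering window side (pixels, odd).
#' @param maxNoDetect consecutive localization failures before declaring
#'   loss.
#' @param seed optional integer seed.
#' @return list with \code{localizations} (data.frame: frame, x_um, y_um,
#'   zrel_um, zabs_um, xi1, xi2, photons, in_range, detected),
#'   \code{stage} (a \code{\link{StageTrace}}), \code{truth} (data.frame:
#'   frame, x, y, z), \code{lost} (logical), \code{framesRetained}.
#' @export
runClosedLoop <- function(motion, psf, cam, curve, nFrames, latency = 1L,
                          gain = 1, captureRange = 1, photons = 300,
                          startOffset = 0, noise = TRUE, windowSize = 17L,
                          maxNoDetect = 3L, seed = NULL) {
  stopifnot(is(motion, "MotionModel"), is(curve, "CalibrationCurve"))
  latency <- as.integer(latency)
  if (latency < 1L) stop("'latency' must be >= 1")
  windowSize <- as.integer(windowSize)
  ps <- cam@pixelSize
  centerUm <- (windowSize / 2) * ps
  dt <- motion@frameInterval
  D <- motion@diffusion[1]
  sdStep <- sqrt(2 * D * dt)
  # precompute calibration constants once; the loop uses the S4-free core
  t1px <- curve@template1@pixels
  t2px <- curve@template2@pixels
  span <- sort(curve@a * curve@zRange + curve@b)

  withSeed(seed, {
    # particle absolute position; lateral origin of the rendering window
    pos <- c(0, 0, startOffset)
    origin <- c(pos[1] - centerUm, pos[2] - centerUm)
    stageZ <- 0
    pending <- numeric(nFrames + latency)  # moves scheduled per frame index

    n <- nFrames
    frameV <- seq_len(n)
    stageV <- moveV <- zrelV <- xV <- yV <- xi1V <- xi2V <- phV <-
      rep(NA_real_, n)
    detV <- inRangeV <- rep(FALSE, n)
    txV <- tyV <- tzV <- rep(NA_real_, n)
    lost <- FALSE
    lastFrame <- 0L
    noDetect <- 0L

    for (f in seq_len(n)) {
      if (f > 1L) pos <- pos + rnorm(3, 0, sdStep)
      # commanded sample-stage move m displaces the focal plane by -m in
      # specimen coordinates
      stageZ <- stageZ - pending[f]
      zRelTrue <- pos[3] - stageZ
      txV[f] <- pos[1]; tyV[f] <- pos[2]; tzV[f] <- pos[3]
      stageV[f] <- stageZ
      if (abs(zRelTrue) > captureRange) {
        if (f == 1L) stop("particle outside the capture range at start")
        lost <- TRUE
        break
      }
      xl <- pos[1] - origin[1]; yl <- pos[2] - origin[2]
      if (xl < ps || xl > (windowSize - 1) * ps ||
          yl < ps || yl > (windowSize - 1) * ps) {
        lost <- TRUE  # lateral escape from the tracking window
        break
      }
      img <- renderSpot(xl, yl, zRelTrue, photons, psf, cam, windowSize,
                        noise)
      guess <- c(round(yl / ps + 0.5), round(xl / ps + 0.5))
      pk <- findPeak(img, guess, radius = 4L)
      move <- 0
      if (pk$detected) {
        ctr <- centroidXY(img, c(pk$row, pk$col), 11L, ps)
        ax <- .axialCore(img, c(pk$row, pk$col), t1px, t2px,
                         curve@a, curve@b, span, 2L)
        if (ctr$detected && ax$detected) {
          noDetect <- 0L
          detV[f] <- TRUE
          xV[f] <- origin[1] + ctr$x
          yV[f] <- origin[2] + ctr$y
          zrelV[f] <- ax$z
          xi1V[f] <- ax$xi1; xi2V[f] <- ax$xi2
          inRangeV[f] <- ax$inRange
          phV[f] <- ctr$photonsRaw / cam@emExcessFactor^2
          move <- feedbackStep(ax$z, gain, ax$inRange)
          # recenter the lateral window on the estimate
          origin <- c(xV[f] - centerUm, yV[f] - centerUm)
        } else noDetect <- noDetect + 1L
      } else noDetect <- noDetect + 1L
      moveV[f] <- move
      pending[f + latency] <- pending[f + latency] + move
      lastFrame <- f
      if (noDetect >= maxNoDetect) {
        lost <- TRUE
        break
      }
    }

    keep <- seq_len(max(lastFrame, 1L))
    stage <- new("StageTrace", frame = frameV[keep],
                 stageZ = stageV[keep],
                 move = ifelse(is.na(moveV[keep]), 0, moveV[keep]),
                 latency = latency, gain = gain)
    list(
      localizations = data.frame(
        frame = frameV[keep], x_um = xV[keep], y_um = yV[keep],
        zrel_um = zrelV[keep],
        zabs_um = stageV[keep] + zrelV[keep],
        xi1 = xi1V[keep], xi2 = xi2V[keep], photons = phV[keep],
        in_range = inRangeV[keep], detected = detV[keep]),
      stage = stage,
      truth = data.frame(frame = frameV[keep], x = txV[keep], y = tyV[keep],
                         z = tzV[keep]),
      lost = lost,
      framesRetained = lastFrame)
  })
}
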