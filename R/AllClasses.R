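#' @useDynLib astigTrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats pnorm pchisq rnorm rpois rexp runif sd lm coef optim
#'   uniroot ecdf var
#' @importFrom utils read.csv write.csv head tail
NULL

#' Parametric astigmatic point-spread-function model
#'
#' Describes the width of an astigmatic PSF along x and y as a function of
#' the axial position \code{z} relative to the effective focal plane (the
#' plane of equal widths, defined as z = 0). Each axis follows the
#' Gaussian-beam law \eqn{\sigma(z) = \sigma_0 \sqrt{1 + ((z - z_f)/d)^2}}
#' with the x focal plane at \eqn{z_f = -s/2} and the y focal plane at
#' \eqn{+s/2}, where \eqn{s} is the focal-plane separation introduced by the
#' cylindrical lens.
#'
#' @slot sigma0 numeric(1), PSF width at an axis' own focal plane (micron).
#' @slot depthScale numeric(1), axial length over which the width grows by
#'   \eqn{\sqrt 2} (micron).
#' @slot focalSeparation numeric(1), distance between the x and y focal
#'   planes (micron); the amount of astigmatism.
#' @export
setClass("PsfModel",
  representation(sigma0 = "numeric", depthScale = "numeric",
                 focalSeparation = "numeric"),
  prototype(sigma0 = 0.16, depthScale = 0.4, focalSeparation = 0.8))

setValidity("PsfModel", function(object) {
  msg <- NULL
  if (length(object@sigma0) != 1L || object@sigma0 <= 0)
    msg <- c(msg, "'sigma0' must be a single positive number")
  if (length(object@depthScale) != 1L || object@depthScale <= 0)
    msg <- c(msg, "'depthScale' must be a single positive number")
  if (length(object@focalSeparation) != 1L || object@focalSeparation < 0)
    msg <- c(msg, "'focalSeparation' must be a single non-negative number")
  if (is.null(msg)) TRUE else msg
})

#' @param sigma0,depthScale,focalSeparation see slot documentation.
#' @return a \code{PsfModel} object.
#' @rdname PsfModel-class
#' @export
PsfModel <- function(sigma0 = 0.16, depthScale = 0.4, focalSeparation = 0.8) {
  new("PsfModel", sigma0 = sigma0, depthScale = depthScale,
      focalSeparation = focalSeparation)
}

#' Camera / detector noise model
#'
#' Pixel values are photon-calibrated. A noise-free rendering is the expected
#' photon count (signal plus background mean). With noise enabled, the signal
#' receives Poisson shot noise inflated by the EM-register excess factor, the
#' background is Gaussian with the given mean and standard deviation, and an
#' optional Gaussian read-noise term is added.
#'
#' @slot pixelSize numeric(1), object-space pixel pitch (micron/pixel).
#' @slot backgroundMean numeric(1), mean background (photons/pixel).
#' @slot backgroundSd numeric(1), background standard deviation
#'   (photons/pixel).
#' @slot readNoiseSd numeric(1), read noise (photons r.m.s.).
#' @slot emExcessFactor numeric(1), multiplicative excess-noise factor of
#'   electron multiplication (unitless; sqrt(2) for an EMCCD at high gain).
#' @export
setClass("CameraModel",
  representation(pixelSize = "numeric", backgroundMean = "numeric",
                 backgroundSd = "numeric", readNoiseSd = "numeric",
                 emExcessFactor = "numeric"),
  prototype(pixelSize = 0.24, backgroundMean = 5, backgroundSd = 2,
            readNoiseSd = 0, emExcessFactor = sqrt(2)))

setValidity("CameraModel", function(object) {
  msg <- NULL
  if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
  vals <- c(object@backgroundMean, object@backgroundSd, object@readNoiseSd,
            object@emExcessFactor)
  if (any(vals < 0)) msg <- c(msg, "noise parameters must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' @param pixelSize,backgroundMean,backgroundSd,readNoiseSd,emExcessFactor
#'   see slot documentation.
#' @return a \code{CameraModel} object.
#' @rdname CameraModel-class
#' @export
CameraModel <- function(pixelSize = 0.24, backgroundMean = 5,
                        backgroundSd = 2, readNoiseSd = 0,
                        emExcessFactor = sqrt(2)) {
  new("CameraModel", pixelSize = pixelSize, backgroundMean = backgroundMean,
      backgroundSd = backgroundSd, readNoiseSd = readNoiseSd,
      emExcessFactor = emExcessFactor)
}

#' Brownian motion model with optional discrete mobility states
#'
#' One diffusion coefficient per mobility state and a matrix of switching
#' rates between states. State switching is simulated as a discrete-time
#' Markov chain with per-frame transition probability
#' \eqn{1 - e^{-k \Delta t}} for each off-diagonal rate \eqn{k}.
#'
#' @slot diffusion numeric vector, one diffusion coefficient per state
#'   (micron^2/s).
#' @slot switchRates square numeric matrix of switching rates (1/s);
#'   entry [i, j] is the rate from state i to state j. Diagonal ignored.
#' @slot dims character(1), \code{"xy"} (membrane-like 2D) or \code{"xyz"}
#'   (free 3D diffusion).
#' @slot frameInterval numeric(1), time between frames (s).
#' @export
setClass("MotionModel",
  representation(diffusion = "numeric", switchRates = "matrix",
                 dims = "character", frameInterval = "numeric"),
  prototype(diffusion = 1, switchRates = matrix(0, 1, 1), dims = "xyz",
            frameInterval = 0.0165))

setValidity("MotionModel", function(object) {
  msg <- NULL
  ns <- length(object@diffusion)
  if (ns < 1L || any(object@diffusion < 0))
    msg <- c(msg, "'diffusion' must hold non-negative coefficients")
  if (!all(dim(object@switchRates) == c(ns, ns)))
    msg <- c(msg, "'switchRates' must be a square matrix matching the number of states")
  if (any(object@switchRates < 0)) msg <- c(msg, "switching rates must be >= 0")
  if (!object@dims %in% c("xy", "xyz")) msg <- c(msg, "'dims' must be 'xy' or 'xyz'")
  if (object@frameInterval <= 0) msg <- c(msg, "'frameInterval' must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @param diffusion,switchRates,dims,frameInterval see slot documentation;
#'   \code{switchRates} may be omitted for a single-state model.
#' @return a \code{MotionModel} object.
#' @rdname MotionModel-class
#' @export
MotionModel <- function(diffusion = 1, switchRates = NULL, dims = "xyz",
                        frameInterval = 0.0165) {
  ns <- length(diffusion)
  if (is.null(switchRates)) switchRates <- matrix(0, ns, ns)
  new("MotionModel", diffusion = diffusion, switchRates = switchRates,
      dims = dims, frameInterval = frameInterval)
}

#' PSF template for normalized-covariance matching
#'
#' A small odd-sized square subimage centered on the intensity peak of a
#' calibration slice, carrying its nominal axial offset from the effective
#' focal plane.
#'
#' @slot pixels numeric matrix, odd square (typically 9x9 to 11x11).
#' @slot offset numeric(1), nominal axial position of the slice the template
#'   was extracted from (micron).
#' @export
setClass("PsfTemplate",
  representation(pixels = "matrix", offset = "numeric"))

setValidity("PsfTemplate", function(object) {
  d <- dim(object@pixels)
  msg <- NULL
  if (d[1] != d[2]) msg <- c(msg, "template must be square")
  if (d[1] %% 2L == 0L) msg <- c(msg, "template side length must be odd")
  if (sd(object@pixels) == 0) msg <- c(msg, "template must not be constant")
  if (is.null(msg)) TRUE else msg
})

#' @param pixels,offset see slot documentation.
#' @return a \code{PsfTemplate} object.
#' @rdname PsfTemplate-class
#' @export
PsfTemplate <- function(pixels, offset) {
  new("PsfTemplate", pixels = pixels, offset = offset)
}

#' Linear axial calibration curve
#'
#' Holds the two PSF templates and the parameters (a, b) of the linear
#' relation metric = a * z + b between the normalized-covariance contrast
#' metric \eqn{(\xi_2 - \xi_1)/(\xi_1 + \xi_2)} and the axial position,
#' valid between the two astigmatic focal planes.
#'
#' @slot a numeric(1), slope (1/micron).
#' @slot b numeric(1), offset (unitless).
#' @slot template1,template2 \code{PsfTemplate}s at the negative and
#'   positive axial offset.
#' @slot zRange numeric(2), axial validity range of the linear metric
#'   (micron).
#' @slot diagnostics list with the per-slice metric values, fitted residuals
#'   and the z positions used in the fit.
#' @export
setClass("CalibrationCurve",
  representation(a = "numeric", b = "numeric", template1 = "PsfTemplate",
                 template2 = "PsfTemplate", zRange = "numeric",
                 diagnostics = "list"))

setValidity("CalibrationCurve", function(object) {
  msg <- NULL
  if (object@a == 0) msg <- c(msg, "slope 'a' must be non-zero")
  if (length(object@zRange) != 2L || diff(object@zRange) <= 0)
    msg <- c(msg, "'zRange' must be an increasing pair")
  if (is.null(msg)) TRUE else msg
})

#' Single-particle trajectory
#'
#' A gap-free, time-ordered series of absolute 3D positions. Frames must
#' increase strictly by one. Axial positions are absolute (stage position
#' plus relative localization) when assembled from feedback-tracking data.
#'
#' @slot id character(1), trajectory identifier.
#' @slot frame integer vector of frame indices (consecutive).
#' @slot t numeric vector of times (s).
#' @slot x,y,z numeric vectors of coordinates (micron); z is absolute.
#' @slot photons numeric vector of per-localization photon estimates (may be
#'   NA when unknown).
#' @export
setClass("Trajectory",
  representation(id = "character", frame = "integer", t = "numeric",
                 x = "numeric", y = "numeric", z = "numeric",
                 photons = "numeric"))

setValidity("Trajectory", function(object) {
  n <- length(object@frame)
  msg <- NULL
  if (any(lengths(list(object@t, object@x, object@y, object@z,
                       object@photons)) != n))
    msg <- c(msg, "all coordinate vectors must share one length")
  if (n >= 2L && any(diff(object@frame) != 1L))
    msg <- c(msg, "frames must increase strictly by 1 (no gaps)")
  if (is.null(msg)) TRUE else msg
})

#' @param id,frame,t,x,y,z,photons see slot documentation.
#' @return a \code{Trajectory} object.
#' @rdname Trajectory-class
#' @export
Trajectory <- function(frame, x, y, z, t = NULL, id = "1",
                       photons = rep(NA_real_, length(frame)),
                       frameInterval = NULL) {
  frame <- as.integer(frame)
  if (is.null(t)) {
    if (is.null(frameInterval))
      stop("supply either 't' or 'frameInterval'")
    t <- frame * frameInterval
  }
  new("Trajectory", id = as.character(id), frame = frame, t = as.numeric(t),
      x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
      photons = as.numeric(photons))
}

#' Temporal sequence of squared jump distances
#'
#' Squared displacements between successive localizations of one trajectory,
#' in the chosen dimensionality, retained in temporal order so that
#' run-length (dwell-time) statistics can be applied.
#'
#' @slot r2 numeric vector of squared displacements (micron^2), in order.
#' @slot dt numeric(1), lag time between the paired localizations (s).
#' @slot dims integer(1), 2 or 3 — dimensionality used to form displacements.
#' @slot trajId character(1), source trajectory.
#' @export
setClass("JumpSequence",
  representation(r2 = "numeric", dt = "numeric", dims = "integer",
                 trajId = "character"))

setValidity("JumpSequence", function(object) {
  msg <- NULL
  if (any(object@r2 < 0)) msg <- c(msg, "squared displacements must be >= 0")
  if (object@dt <= 0) msg <- c(msg, "'dt' must be > 0")
  if (!object@dims %in% c(2L, 3L)) msg <- c(msg, "'dims' must be 2 or 3")
  if (is.null(msg)) TRUE else msg
})

#' Mixture fit of the cumulative jump-distance distribution
#'
#' Result of fitting \eqn{P(r^2, \Delta t) = 1 - \sum_i a_i
#' e^{-r^2/(4 D_i \Delta t)}} (2D kernel; a chi-square kernel is used for 3D
#' displacements) to the empirical distribution of squared jumps.
#' Components are sorted by increasing diffusion coefficient and fractions
#' sum to one.
#'
#' @slot D numeric vector of diffusion coefficients (micron^2/s), ascending.
#' @slot fractions numeric vector of component fractions, summing to 1.
#' @slot se list with delta-method standard errors for D and fractions.
#' @slot sse numeric(1), residual sum of squares against the empirical CDF.
#' @slot converged logical(1).
#' @slot dt numeric(1), lag time (s).
#' @slot dims integer(1), kernel dimensionality.
#' @slot nJumps integer(1), number of squared displacements fitted.
#' @export
setClass("MobilityFit",
  representation(D = "numeric", fractions = "numeric", se = "list",
                 sse = "numeric", converged = "logical", dt = "numeric",
                 dims = "integer", nJumps = "integer"))

setValidity("MobilityFit", function(object) {
  msg <- NULL
  if (abs(sum(object@fractions) - 1) > 1e-8)
    msg <- c(msg, "fractions must sum to 1")
  if (any(object@fractions < -1e-12 | object@fractions > 1 + 1e-12))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (any(object@D <= 0)) msg <- c(msg, "diffusion coefficients must be > 0")
  if (is.unsorted(object@D)) msg <- c(msg, "components must be sorted by D")
  if (is.null(msg)) TRUE else msg
})

#' Binary mobility-state classification of a jump sequence
#'
#' Thresholding the squared displacements at \code{r2lim} assigns each jump
#' to state A (small jumps, \eqn{r^2 \le r^2_{lim}}) or state B. Under the
#' null hypothesis of i.i.d. jumps the labels form Bernoulli trials with
#' success probability pA equal to the empirical CDF at the threshold.
#'
#' @slot r2lim numeric(1), squared-displacement threshold (micron^2).
#' @slot stateA logical vector, TRUE for jumps in state A.
#' @slot pA numeric(1), empirical probability of state A.
#' @slot n integer(1), number of jumps.
#' @export
setClass("StateSequence",
  representation(r2lim = "numeric", stateA = "logical", pA = "numeric",
                 n = "integer"))

setValidity("StateSequence", function(object) {
  msg <- NULL
  if (object@n != length(object@stateA))
    msg <- c(msg, "'n' must equal the number of labels")
  if (abs(object@pA - mean(object@stateA)) > 1e-12)
    msg <- c(msg, "'pA' must equal the fraction of A labels")
  if (is.null(msg)) TRUE else msg
})

#' Transition-frequency statistics of a state sequence
#'
#' Compares the observed number of A/B transitions with the expectation
#' \eqn{\langle s' \rangle = 2 p_A p_B n} and standard deviation
#' \eqn{\sigma_{s'} = \sqrt{p_A p_B n}} for jumps drawn independently from
#' the empirical jump-distance distribution. A transition deficit (observed
#' below expected) indicates retention in one mobility state.
#'
#' @slot s integer(1), observed transitions.
#' @slot sExpected numeric(1), expected transitions under the i.i.d. null.
#' @slot sigma numeric(1), standard deviation of the null.
#' @slot zDeficit numeric(1), (expected - observed)/sigma.
#' @slot pTail numeric(1), one-sided standard-normal tail probability of the
#'   deficit.
#' @slot degenerate logical(1), TRUE when pA is 0 or 1 and the statistics
#'   are undefined.
#' @export
setClass("TransitionStats",
  representation(s = "integer", sExpected = "numeric", sigma = "numeric",
                 zDeficit = "numeric", pTail = "numeric",
                 degenerate = "logical"))
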