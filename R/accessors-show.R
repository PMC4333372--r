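#' @name accessors
#' @title Accessor generics for astigTrack objects
#' @description Slot access for the S4 containers: calibration parameters,
#'   trajectory columns, fit components and state-sequence summaries.
#' @param object an astigTrack S4 object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("calSlope", function(object) standardGeneric("calSlope"))
#' @rdname accessors
#' @export
setMethod("calSlope", "CalibrationCurve", function(object) object@a)

#' @rdname accessors
#' @export
setGeneric("calOffset", function(object) standardGeneric("calOffset"))
#' @rdname accessors
#' @export
setMethod("calOffset", "CalibrationCurve", function(object) object@b)

#' @rdname accessors
#' @export
setGeneric("calRange", function(object) standardGeneric("calRange"))
#' @rdname accessors
#' @export
setMethod("calRange", "CalibrationCurve", function(object) object@zRange)

#' @rdname accessors
#' @export
setGeneric("templates", function(object) standardGeneric("templates"))
#' @rdname accessors
#' @export
setMethod("templates", "CalibrationCurve", function(object)
  list(object@template1, object@template2))

#' @rdname accessors
#' @export
setGeneric("nLocalizations", function(object) standardGeneric("nLocalizations"))
#' @rdname accessors
#' @export
setMethod("nLocalizations", "Trajectory", function(object) length(object@frame))

#' Coordinates of a trajectory as a data.frame
#' @param x a \code{Trajectory}.
#' @param ... ignored.
#' @return data.frame with frame, t_s, x_um, y_um, z_um, photons.
#' @export
setMethod("as.data.frame", "Trajectory", function(x, ...) {
  data.frame(traj_id = x@id, frame = x@frame, t_s = x@t, x_um = x@x,
             y_um = x@y, z_um = x@z, photons = x@photons)
})

#' @rdname accessors
#' @export
setGeneric("diffusionCoefficients", function(object)
  standardGeneric("diffusionCoefficients"))
#' @rdname accessors
#' @export
setMethod("diffusionCoefficients", "MobilityFit", function(object) object@D)
#' @rdname accessors
#' @export
setMethod("diffusionCoefficients", "MotionModel", function(object)
  object@diffusion)

#' @rdname accessors
#' @export
setGeneric("componentFractions", function(object)
  standardGeneric("componentFractions"))
#' @rdname accessors
#' @export
setMethod("componentFractions", "MobilityFit", function(object)
  object@fractions)

#' @rdname accessors
#' @export
setGeneric("stateProbability", function(object)
  standardGeneric("stateProbability"))
#' @rdname accessors
#' @export
setMethod("stateProbability", "StateSequence", function(object) object@pA)

setMethod("show", "PsfModel", function(object) {
  cat("PsfModel: sigma0 =", object@sigma0, "um, depth scale =",
      object@depthScale, "um, focal separation =", object@focalSeparation,
      "um\n")
})

setMethod("show", "CameraModel", function(object) {
  cat("CameraModel:", object@pixelSize, "um/px, background",
      object@backgroundMean, "+/-", object@backgroundSd,
      "photons/px, EM excess", round(object@emExcessFactor, 3), "\n")
})

setMethod("show", "MotionModel", function(object) {
  cat("MotionModel:", length(object@diffusion), "state(s), D = [",
      paste(object@diffusion, collapse = ", "), "] um^2/s,",
      object@dims, "motion, dt =", object@frameInterval, "s\n")
})

setMethod("show", "PsfTemplate", function(object) {
  cat("PsfTemplate:", nrow(object@pixels), "x", ncol(object@pixels),
      "px at z =", object@offset, "um\n")
})

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve: metric = a*z + b with a =",
      signif(object@a, 4), "/um, b =", signif(object@b, 4),
      "; valid z in [", object@zRange[1], ",", object@zRange[2], "] um\n")
})

setMethod("show", "Trajectory", function(object) {
  n <- length(object@frame)
  cat("Trajectory", object@id, "with", n, "localizations")
  if (n > 1) cat(", duration", signif(diff(range(object@t)), 4), "s")
  cat("\n")
})

setMethod("show", "JumpSequence", function(object) {
  cat("JumpSequence:", length(object@r2), "squared displacements (",
      object@dims, "D ) at dt =", object@dt, "s from trajectory",
      object@trajId, "\n")
})

setMethod("show", "MobilityFit", function(object) {
  cat("MobilityFit (", object@dims, "D kernel,", object@nJumps,
      "jumps, dt =", object@dt, "s )\n")
  for (i in seq_along(object@D))
    cat(sprintf("  D%d = %.4g um^2/s  fraction = %.3f\n", i, object@D[i],
                object@fractions[i]))
  if (!object@converged) cat("  [fit did not converge]\n")
})

setMethod("show", "StateSequence", function(object) {
  cat("StateSequence: n =", object@n, "jumps, threshold r2 =", object@r2lim,
      "um^2, pA =", signif(object@pA, 4), "\n")
})

setMethod("show", "TransitionStats", function(object) {
  if (object@degenerate) {
    cat("TransitionStats: degenerate (single state observed)\n")
  } else {
    cat(sprintf(
      "TransitionStats: s = %d observed, expected %.2f +/- %.2f (deficit %.2f sigma, one-sided p = %.4g)\n",
      object@s, object@sExpected, object@sigma, object@zDeficit,
      object@pTail))
  }
})
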