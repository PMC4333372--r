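# Post-processing pipeline: detect all particles per frame by template
# matching, link localizations into trajectories with a conservative
# nearest-neighbor rule, and reconstruct absolute coordinates from the
# stage trace.

#' Detect all particles in a frame by template matching
#'
#' Computes the normalized covariance maps with both calibration templates,
#' takes the pixelwise maximum, finds local maxima above a threshold with
#' non-maximum suppression within one template width, and refines each
#' candidate by centroid and axial-metric localization.
#'
#' @param image numeric matrix.
#' @param curve a \code{\link{CalibrationCurve}}.
#' @param cam a \code{\link{CameraModel}}.
#' @param threshold minimum covariance value for a detection.
#' @param minSep minimum separation between detections in pixels (default:
#'   one template width).
#' @return data.frame of localizations (possibly empty): x_um, y_um,
#'   zrel_um, xi1, xi2, photons, snr, in_range, peak_row, peak_col, score.
#' @export
detectParticles <- function(image, curve, cam, threshold = 0.3,
                            minSep = NULL) {
  t1 <- curve@template1@pixels
  half <- (nrow(t1) - 1L) %/% 2L
  if (is.null(minSep)) minSep <- nrow(t1)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      zrel_um = numeric(0), xi1 = numeric(0),
                      xi2 = numeric(0), photons = numeric(0),
                      snr = numeric(0), in_range = logical(0),
                      peak_row = integer(0), peak_col = integer(0),
                      score = numeric(0))
  if (nrow(image) < nrow(t1) || ncol(image) < ncol(t1)) return(empty)
  m1 <- normalizedCovariance(image, t1)
  m2 <- normalizedCovariance(image, curve@template2@pixels)
  score <- pmax(m1, m2)
  nr <- nrow(score); nc <- ncol(score)
  cand <- which(score > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  # strict local maxima over the 8-neighborhood
  isMax <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- score[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
    score[r, c] >= max(nb)
  }, logical(1))
  cand <- cand[isMax, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  sc <- score[cand]
  ord <- order(sc, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; sc <- sc[ord]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      d <- sqrt((cand[later, 1] - cand[i, 1])^2 +
                (cand[later, 2] - cand[i, 2])^2)
      keep[later][d < minSep] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]; sc <- sc[keep]
  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    peak <- c(cand[i, 1] + half, cand[i, 2] + half)  # map -> image pixel
    loc <- localizeParticle(image, peak, curve, cam, searchRadius = 2L)
    if (loc$detected) {
      loc$score <- sc[i]
      out[[i]] <- loc[, setdiff(names(loc), "detected")]
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Link localizations into trajectories by conservative nearest neighbors
#'
#' Localizations in consecutive frames are linked when they are each other's
#' unique link candidates within the displacement limit. Whenever a
#' trajectory end or a new localization has two or more candidates within
#' the limit (an ambiguous situation), all trajectories involved are
#' terminated at that frame and the localizations start new trajectories.
#' Linking distance is measured in 3D by default, or laterally only.
#'
#' @param locs data.frame with columns \code{frame}, \code{x_um},
#'   \code{y_um} and an axial column (\code{zCol}).
#' @param maxDisp displacement limit between consecutive frames (micron).
#' @param dims \code{"xyz"} (3D distance) or \code{"xy"}.
#' @param zCol name of the axial coordinate column.
#' @param frameInterval frame time (s) used to fill trajectory time stamps.
#' @param minLength minimum number of localizations for a returned
#'   trajectory.
#' @return list of \code{\link{Trajectory}} objects.
#' @export
linkNearestNeighbor <- function(locs, maxDisp, dims = c("xyz", "xy"),
                                zCol = "zrel_um", frameInterval = 1,
                                minLength = 1L) {
  dims <- match.arg(dims)
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(locs)))
  if (!zCol %in% names(locs)) stop("missing axial column '", zCol, "'")
  locs <- locs[order(locs$frame), , drop = FALSE]
  frames <- sort(unique(locs$frame))
  done <- list()
  active <- list()  # each: list(frame=, x=, y=, z=, photons=)
  nextId <- 1L
  phCol <- if ("photons" %in% names(locs)) "photons" else NULL
  newTraj <- function(row) {
    tr <- list(id = as.character(nextId), frame = row$frame, x = row$x_um,
               y = row$y_um, z = row[[zCol]],
               photons = if (is.null(phCol)) NA_real_ else row[[phCol]])
    nextId <<- nextId + 1L
    tr
  }
  finish <- function(tr) {
    if (length(tr$frame) >= minLength) done[[length(done) + 1L]] <<- tr
  }
  for (f in frames) {
    cur <- locs[locs$frame == f, , drop = FALSE]
    # retire trajectories whose end is not in the immediately previous frame
    if (length(active) > 0L) {
      ends <- vapply(active, function(tr) tail(tr$frame, 1L), numeric(1))
      stale <- ends != f - 1L
      for (tr in active[stale]) finish(tr)
      active <- active[!stale]
    }
    if (length(active) == 0L) {
      for (i in seq_len(nrow(cur))) active[[length(active) + 1L]] <-
        newTraj(cur[i, , drop = FALSE])
      next
    }
    ex <- vapply(active, function(tr) tail(tr$x, 1L), numeric(1))
    ey <- vapply(active, function(tr) tail(tr$y, 1L), numeric(1))
    ez <- vapply(active, function(tr) tail(tr$z, 1L), numeric(1))
    nNew <- nrow(cur)
    d2 <- outer(ex, cur$x_um, "-")^2 + outer(ey, cur$y_um, "-")^2
    if (dims == "xyz") d2 <- d2 + outer(ez, cur[[zCol]], "-")^2
    within <- sqrt(d2) <= maxDisp
    dim(within) <- dim(d2)
    candPerEnd <- rowSums(within)
    candPerNew <- colSums(within)
    linkedNew <- rep(FALSE, nNew)
    keepActive <- list()
    for (a in seq_along(active)) {
      j <- which(within[a, ])
      ok <- length(j) == 1L && candPerNew[j] == 1L
      if (ok) {
        row <- cur[j, , drop = FALSE]
        tr <- active[[a]]
        tr$frame <- c(tr$frame, row$frame)
        tr$x <- c(tr$x, row$x_um); tr$y <- c(tr$y, row$y_um)
        tr$z <- c(tr$z, row[[zCol]])
        tr$photons <- c(tr$photons,
                        if (is.null(phCol)) NA_real_ else row[[phCol]])
        keepActive[[length(keepActive) + 1L]] <- tr
        linkedNew[j] <- TRUE
      } else {
        finish(active[[a]])  # no candidate, lost, or ambiguous: terminate
      }
    }
    active <- keepActive
    for (i in which(!linkedNew)) active[[length(active) + 1L]] <-
      newTraj(cur[i, , drop = FALSE])
  }
  for (tr in active) finish(tr)
  lapply(done, function(tr)
    Trajectory(frame = tr$frame, x = tr$x, y = tr$y, z = tr$z,
               t = tr$frame * frameInterval, id = tr$id,
               photons = tr$photons))
}

#' Reconstruct absolute axial coordinates from the stage trace
#'
#' Replaces each trajectory's relative axial coordinate with
#' \code{stageZ + zRel} using the stage position of the matching frame, and
#' fills the time column from the frame interval.
#'
#' @param trajectories list of \code{\link{Trajectory}} objects whose z
#'   column holds focal-plane-relative localizations.
#' @param stage a \code{\link{StageTrace}} covering all trajectory frames.
#' @param frameInterval frame time (s).
#' @return list of \code{\link{Trajectory}} objects with absolute z.
#' @export
assembleAbsolute <- function(trajectories, stage, frameInterval) {
  stopifnot(is(stage, "StageTrace"))
  lapply(trajectories, function(tr) {
    idx <- match(tr@frame, stage@frame)
    if (anyNA(idx))
      stop("stage trace does not cover frames of trajectory ", tr@id)
    Trajectory(frame = tr@frame, x = tr@x, y = tr@y,
               z = absoluteZ(tr@z, stage@stageZ[idx]),
               t = tr@frame * frameInterval, id = tr@id,
               photons = tr@photons)
  })
}
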