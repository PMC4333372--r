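# File formats: multi-frame grayscale TIFF movies, trajectory and stage
# CSV tables, and calibration-curve JSON.

#' Read a multi-frame grayscale TIFF movie
#'
#' @param path TIFF file.
#' @return rows x cols x frames numeric array of pixel values.
#' @export
readMovie <- function(path) {
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                     error = function(e) stop("not a readable TIFF: ",
                                              conditionMessage(e)))
  if (length(frames) == 0L) stop("TIFF contains no frames")
  if (length(dim(frames[[1]])) > 2L)
    stop("RGB/multi-channel TIFF input is not supported")
  arr <- array(0, c(dim(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) {
    if (!all(dim(frames[[i]]) == dim(frames[[1]])))
      stop("frames differ in size")
    arr[, , i] <- frames[[i]]
  }
  arr
}

#' Write a multi-frame grayscale TIFF movie
#'
#' Pixel values (photons) are stored as 16-bit unsigned integers; values are
#' rounded and clipped to [0, 65535]. Integer-valued stacks round-trip
#' losslessly.
#'
#' @param stack rows x cols x frames array (a single matrix is accepted).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMovie <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  if (length(dim(stack)) != 3L || dim(stack)[3] < 1L)
    stop("'stack' must be a non-empty rows x cols x frames array")
  frames <- lapply(seq_len(dim(stack)[3]), function(i) {
    m <- pmin(pmax(round(stack[, , i]), 0), 65535)
    if (!is.matrix(m)) dim(m) <- dim(stack)[1:2]  # single-row/column frame
    m / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

trajColumns <- c("traj_id", "frame", "t_s", "x_um", "y_um", "zrel_um",
                 "zabs_um", "photons")

#' Write trajectories to CSV
#'
#' Schema: traj_id, frame, t_s, x_um, y_um, zrel_um, zabs_um, photons. The
#' trajectory's axial coordinate is written as zabs_um; zrel_um is filled
#' from the stage trace when one is supplied.
#'
#' @param trajectories list of \code{\link{Trajectory}} objects.
#' @param path output CSV file.
#' @param stage optional \code{\link{StageTrace}} used to recover the
#'   focal-plane-relative axial coordinate.
#' @return the path, invisibly.
#' @export
writeTrajectories <- function(trajectories, path, stage = NULL) {
  rows <- lapply(trajectories, function(tr) {
    zrel <- rep(NA_real_, length(tr@frame))
    if (!is.null(stage)) {
      idx <- match(tr@frame, stage@frame)
      zrel <- tr@z - stage@stageZ[idx]
    }
    data.frame(traj_id = tr@id, frame = tr@frame, t_s = tr@t, x_um = tr@x,
               y_um = tr@y, zrel_um = zrel, zabs_um = tr@z,
               photons = tr@photons)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Validates the schema (see \code{\link{writeTrajectories}}; the photons
#' column is optional), rejects duplicate (traj_id, frame) pairs, and
#' requires strictly consecutive frames per trajectory.
#'
#' @param path CSV file.
#' @return list of \code{\link{Trajectory}} objects (z taken from zabs_um,
#'   falling back to zrel_um when zabs_um is absent or all-NA).
#' @export
readTrajectories <- function(path) {
  df <- read.csv(path)
  required <- c("traj_id", "frame", "t_s", "x_um", "y_um")
  for (col in required)
    if (!col %in% names(df)) stop("missing required column '", col, "'")
  if (!"zabs_um" %in% names(df) && !"zrel_um" %in% names(df))
    stop("missing required column 'zabs_um'")
  if (anyDuplicated(df[, c("traj_id", "frame")]))
    stop("duplicate (traj_id, frame) entries")
  zcol <- if ("zabs_um" %in% names(df) && !all(is.na(df$zabs_um)))
    "zabs_um" else "zrel_um"
  ph <- if ("photons" %in% names(df)) df$photons else
    rep(NA_real_, nrow(df))
  out <- lapply(split(seq_len(nrow(df)), df$traj_id), function(i) {
    i <- i[order(df$frame[i])]
    Trajectory(frame = df$frame[i], x = df$x_um[i], y = df$y_um[i],
               z = df[[zcol]][i], t = df$t_s[i],
               id = as.character(df$traj_id[i][1]), photons = ph[i])
  })
  unname(out)
}

#' Write / read a stage trace as CSV
#'
#' Columns: frame, stage_z_um, move_um. Loop parameters (latency, gain) are
#' re-supplied on read.
#'
#' @param stage a \code{\link{StageTrace}}.
#' @param path CSV file.
#' @return the path, invisibly.
#' @export
writeStageTrace <- function(stage, path) {
  write.csv(data.frame(frame = stage@frame, stage_z_um = stage@stageZ,
                       move_um = stage@move), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStageTrace
#' @param latency,gain loop parameters of the recorded run.
#' @export
readStageTrace <- function(path, latency = 1L, gain = 1) {
  df <- read.csv(path)
  for (col in c("frame", "stage_z_um", "move_um"))
    if (!col %in% names(df)) stop("missing required column '", col, "'")
  new("StageTrace", frame = as.integer(df$frame), stageZ = df$stage_z_um,
      move = df$move_um, latency = as.integer(latency), gain = gain)
}

#' Write / read a calibration curve as JSON
#'
#' Stores the slope and offset of the linear axial metric, the validity
#' range, and both template pixel arrays with their nominal offsets.
#'
#' @param curve a \code{\link{CalibrationCurve}}.
#' @param path JSON file.
#' @return the path, invisibly.
#' @export
writeCalibration <- function(curve, path) {
  jsonlite::write_json(list(
    a = curve@a, b = curve@b, z_range = curve@zRange,
    template1 = list(offset = curve@template1@offset,
                     pixels = curve@template1@pixels),
    template2 = list(offset = curve@template2@offset,
                     pixels = curve@template2@pixels)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationCurve", a = j$a, b = j$b,
      template1 = PsfTemplate(as.matrix(j$template1$pixels),
                              j$template1$offset),
      template2 = PsfTemplate(as.matrix(j$template2$pixels),
                              j$template2$offset),
      zRange = j$z_range, diagnostics = list())
}
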