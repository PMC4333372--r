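# Axial calibration: PSF template extraction, normalized covariance and the
# linear metric (xi2 - xi1)/(xi1 + xi2) = a * z + b.

#' Normalized covariance (ZNCC) map of an image against a template
#'
#' Computes the zero-mean normalized cross-correlation (Pearson correlation)
#' between the template and every template-sized patch of the image. Values
#' lie in [-1, 1] and are invariant under affine intensity transforms of the
#' patch. Positions where the patch (or the template) has zero variance are
#' defined as 0.
#'
#' @param image numeric matrix.
#' @param template a \code{\link{PsfTemplate}} or numeric matrix.
#' @return numeric matrix of size \code{dim(image) - dim(template) + 1};
#'   entry (i, j) corresponds to the patch with top-left pixel (i, j). The
#'   attribute \code{"center"} gives the offset (in pixels) from a map entry
#'   to the center of its patch.
#' @export
normalizedCovariance <- function(image, template) {
  tm <- if (is(template, "PsfTemplate")) template@pixels else template
  if (nrow(tm) > nrow(image) || ncol(tm) > ncol(image))
    stop("image must be at least as large as the template")
  map <- .znccMapCpp(image, tm)
  attr(map, "center") <- c((nrow(tm) - 1L) %/% 2L, (ncol(tm) - 1L) %/% 2L)
  map
}

#' Extract the two PSF templates from a calibration stack
#'
#' Takes the slices nearest to \code{-offset} and \code{+offset} (within half
#' a slice step) and cuts an odd square subimage centered on the intensity
#' peak of each.
#'
#' @param stack rows x cols x slices array (e.g. from
#'   \code{\link{renderCalibrationStack}}).
#' @param z numeric vector of slice axial positions (micron).
#' @param offset nominal template offset (micron); templates are taken at
#'   -offset and +offset.
#' @param size odd template side length in pixels.
#' @return list of two \code{\link{PsfTemplate}}s (negative offset first).
#' @export
extractTemplates <- function(stack, z, offset = 0.4, size = 11L) {
  size <- as.integer(size)
  if (size %% 2L == 0L) stop("template 'size' must be odd")
  step <- if (length(z) > 1L) stats::median(diff(z)) else Inf
  half <- (size - 1L) %/% 2L
  # 3x3 box filter used only to locate the peak: suppresses single-pixel
  # noise spikes that would otherwise hijack the argmax on low-SNR stacks
  smooth3 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    p <- matrix(0, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- m
    acc <- matrix(0, nr, nc)
    for (dr in 0:2) for (dc in 0:2)
      acc <- acc + p[dr + seq_len(nr), dc + seq_len(nc)]
    acc
  }
  grab <- function(zTarget) {
    i <- which.min(abs(z - zTarget))
    if (abs(z[i] - zTarget) > step / 2 + 1e-9)
      stop("requested template offset lies outside the stack's z range")
    slice <- stack[, , i]
    pk <- arrayInd(which.max(smooth3(slice)), dim(slice))
    r <- pk[1]; c <- pk[2]
    if (r - half < 1L || r + half > nrow(slice) ||
        c - half < 1L || c + half > ncol(slice))
      stop("template window extends beyond the image; use a larger field")
    PsfTemplate(slice[(r - half):(r + half), (c - half):(c + half)],
                offset = z[i])
  }
  list(grab(-offset), grab(offset))
}

# First occurrence of the maximum in row-major order (documented tie-break
# for "the pixel with the highest sum").
argmaxRowMajor <- function(m) {
  idx <- which(t(m) == max(m))[1]
  row <- (idx - 1L) %/% ncol(m) + 1L
  col <- idx - (row - 1L) * ncol(m)
  c(row, col)
}

# xi1/xi2 for one image: covariance maps with both templates, value pair at
# the map pixel maximizing xi1 + xi2. Returns the pair plus the
# patch-center pixel (image coordinates).
xiPair <- function(image, t1, t2) {
  m1 <- normalizedCovariance(image, t1)
  m2 <- normalizedCovariance(image, t2)
  s <- m1 + m2
  rc <- argmaxRowMajor(s)
  row <- rc[1]; col <- rc[2]
  ctr <- attr(m1, "center")
  list(xi1 = m1[row, col], xi2 = m2[row, col],
       peak = c(row + ctr[1], col + ctr[2]))
}

# The axial contrast metric with the documented guards: negative covariances
# are floored at 1e-6 before forming the ratio; positions where both values
# are below 0.1 are flagged out-of-range.
xiMetric <- function(xi1, xi2, floor = 1e-6, minXi = 0.1) {
  usable <- (xi1 >= minXi) | (xi2 >= minXi)
  x1 <- pmax(xi1, floor)
  x2 <- pmax(xi2, floor)
  list(metric = (x2 - x1) / (x1 + x2), usable = usable)
}

#' Fit the linear axial calibration curve
#'
#' For every slice of a calibration stack the two normalized covariance
#' values \eqn{\xi_1, \xi_2} are evaluated at the pixel with the highest sum,
#' and the contrast metric \eqn{(\xi_2 - \xi_1)/(\xi_1 + \xi_2)} is fitted
#' against the axial position with a least-squares line, restricted to the
#' inter-focal region spanned by the two template offsets.
#'
#' @param stack rows x cols x slices array.
#' @param z numeric vector of slice positions (micron).
#' @param t1,t2 \code{\link{PsfTemplate}}s at negative / positive offset.
#' @return a \code{\link{CalibrationCurve}}.
#' @export
fitCalibration <- function(stack, z, t1, t2) {
  stopifnot(is(t1, "PsfTemplate"), is(t2, "PsfTemplate"))
  nz <- dim(stack)[3]
  if (nz != length(z)) stop("'z' must have one entry per slice")
  xi1 <- xi2 <- numeric(nz)
  for (i in seq_len(nz)) {
    p <- xiPair(stack[, , i], t1, t2)
    xi1[i] <- p$xi1; xi2[i] <- p$xi2
  }
  met <- xiMetric(xi1, xi2)
  zRange <- sort(c(t1@offset, t2@offset))
  use <- met$usable & z >= zRange[1] - 1e-9 & z <= zRange[2] + 1e-9
  if (sum(use) < 3L) stop("fewer than 3 usable calibration slices")
  fit <- lm(metric ~ z, data = data.frame(z = z[use],
                                          metric = met$metric[use]))
  a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  if (a == 0) stop("degenerate calibration: zero slope")
  new("CalibrationCurve", a = a, b = b, template1 = t1, template2 = t2,
      zRange = zRange,
      diagnostics = list(
        z = z, xi1 = xi1, xi2 = xi2, metric = met$metric,
        usable = met$usable, used = use,
        residuals = unname(stats::residuals(fit)),
        zUsed = z[use]))
}
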