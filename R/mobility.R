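# Diffusion analysis: temporal jump sequences, MSD curves, and single- or
# multi-component cumulative jump-distance distribution (CJDD) fits,
# including a global fit with shared diffusion coefficients across
# trajectories.

#' Temporal sequence of squared jump distances of a trajectory
#'
#' @param traj a \code{\link{Trajectory}}.
#' @param dims \code{"xy"} for lateral displacements (the usual choice in
#'   vivo, where lateral precision exceeds axial) or \code{"xyz"} for full
#'   3D Euclidean displacements (membrane tracking on a curved surface).
#' @param lag frame lag (>= 1) between the paired localizations.
#' @return a \code{\link{JumpSequence}}.
#' @export
jumpSequence <- function(traj, dims = c("xy", "xyz"), lag = 1L) {
  dims <- match.arg(dims)
  stopifnot(is(traj, "Trajectory"))
  n <- length(traj@frame)
  lag <- as.integer(lag)
  if (n < lag + 1L) stop("trajectory too short for the requested lag")
  i <- seq_len(n - lag)
  r2 <- (traj@x[i + lag] - traj@x[i])^2 + (traj@y[i + lag] - traj@y[i])^2
  d <- 2L
  if (dims == "xyz") {
    r2 <- r2 + (traj@z[i + lag] - traj@z[i])^2
    d <- 3L
  }
  dt <- if (n >= 2L) (traj@t[2] - traj@t[1]) * lag else lag
  new("JumpSequence", r2 = unname(r2), dt = dt, dims = d, trajId = traj@id)
}

#' Time-averaged mean square displacement curve
#'
#' @param traj a \code{\link{Trajectory}}.
#' @param dims \code{"xy"} or \code{"xyz"}.
#' @param maxLag largest frame lag (must be < trajectory length).
#' @return data.frame with columns \code{lag}, \code{tau} (s), \code{msd}
#'   (micron^2) and \code{nPairs}.
#' @export
msdCurve <- function(traj, dims = c("xy", "xyz"), maxLag = 10L) {
  dims <- match.arg(dims)
  n <- length(traj@frame)
  maxLag <- as.integer(maxLag)
  if (maxLag >= n) stop("'maxLag' must be smaller than the trajectory length")
  dt <- traj@t[2] - traj@t[1]
  res <- lapply(seq_len(maxLag), function(l) {
    i <- seq_len(n - l)
    m <- (traj@x[i + l] - traj@x[i])^2 + (traj@y[i + l] - traj@y[i])^2
    if (dims == "xyz") m <- m + (traj@z[i + l] - traj@z[i])^2
    c(lag = l, tau = l * dt, msd = mean(m), nPairs = n - l)
  })
  as.data.frame(do.call(rbind, res))
}

#' Diffusion coefficient from a linear MSD fit
#'
#' Weighted least-squares line \eqn{MSD = 2 d D \tau + c} through the first
#' \code{nPoints} lags; the intercept absorbs static localization noise.
#' Weights are the pair counts per lag.
#'
#' @param curve data.frame from \code{\link{msdCurve}}.
#' @param nPoints number of initial lags to fit (>= 2).
#' @param dims dimensionality of the displacements (2 or 3).
#' @return list with \code{D} (micron^2/s), \code{Dse}, \code{offset} and
#'   the underlying \code{fit}.
#' @export
fitMsd <- function(curve, nPoints = 5L, dims = 2L) {
  nPoints <- min(as.integer(nPoints), nrow(curve))
  if (nPoints < 2L) stop("need at least two lags to fit")
  d <- curve[seq_len(nPoints), ]
  fit <- lm(msd ~ tau, data = d, weights = d$nPairs)
  sl <- summary(fit)$coefficients
  list(D = unname(coef(fit)[2]) / (2 * dims),
       Dse = sl["tau", "Std. Error"] / (2 * dims),
       offset = unname(coef(fit)[1]), fit = fit)
}

# Survival function of the squared displacement for free diffusion:
# exp(-r2/(4 D dt)) in 2D; the 3-dimensional analogue is the chi-square
# (df = 3) upper tail of r2 / (2 D dt).
cjddSurvival <- function(r2, D, dt, dims = 2L) {
  if (dims == 2L) exp(-r2 / (4 * D * dt))
  else pchisq(r2 / (2 * D * dt), df = dims, lower.tail = FALSE)
}

#' Model cumulative jump-distance distribution
#'
#' \eqn{P(r^2, \Delta t) = 1 - \sum_i a_i e^{-r^2/(4 D_i \Delta t)}} for 2D
#' displacements; for 3D Euclidean displacements the exponential kernel is
#' replaced by the chi-square (df = 3) survival function.
#'
#' @param r2 squared displacements (micron^2).
#' @param D diffusion coefficients (micron^2/s).
#' @param fractions component fractions (sum to 1).
#' @param dt lag time (s).
#' @param dims 2 or 3.
#' @return model CDF values.
#' @export
cjddModel <- function(r2, D, fractions, dt, dims = 2L) {
  s <- 0
  for (i in seq_along(D))
    s <- s + fractions[i] * cjddSurvival(r2, D[i], dt, dims)
  1 - s
}

softmax <- function(w) {
  e <- exp(c(w, 0) - max(c(w, 0)))
  e / sum(e)
}

# Empirical CDF support: sorted unique r2 values with their ECDF heights
# and fit weights. "variance" weights are the inverse pointwise ECDF
# variance 1/(p(1-p)) (capped; the 1/n factor is constant and irrelevant to
# the minimizer), "none" gives the unweighted fit.
ecdfPoints <- function(r2, weights = c("variance", "none")) {
  weights <- match.arg(weights)
  x <- sort(unique(r2))
  p <- ecdf(r2)(x)
  w <- if (weights == "variance") 1 / pmax(p * (1 - p), 1e-3) else
    rep(1, length(x))
  list(x = x, p = p, w = w)
}

# Deterministic multi-start seeds: all ascending m-subsets of a log-spaced
# D grid, in fixed order.
dSeedSets <- function(m, gridN = 6L, range = c(0.01, 20)) {
  g <- exp(seq(log(range[1]), log(range[2]), length.out = gridN))
  combn(g, m, simplify = FALSE)
}

# Box constraints for the mixture optimizations: log-D within a generous
# physical range around the multi-start grid (prevents single-jump spike
# components with unphysical D), softmax weights bounded to avoid overflow.
.logDBounds <- log(c(1e-3, 1e2))
.wBound <- 30

# Bounded multi-start minimization shared by the CJDD fitters: nD leading
# log-D parameters, nW trailing softmax weights.
.cjddOptim <- function(obj, m, nW, maxit = 500L) {
  lower <- c(rep(.logDBounds[1], m), rep(-.wBound, nW))
  upper <- c(rep(.logDBounds[2], m), rep(.wBound, nW))
  best <- NULL
  for (Ds in dSeedSets(m)) {
    theta0 <- c(log(Ds), rep(0, nW))
    fit <- tryCatch(
      optim(theta0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  best
}

#' Fit a mixture model to the cumulative jump-distance distribution
#'
#' Least squares of the model CDF against the empirical CDF evaluated at the
#' sorted unique squared displacements. Fractions are constrained to the
#' simplex via a softmax parameterization and diffusion coefficients are
#' kept positive on the log scale. A fixed grid of log-spaced initial D
#' values makes the multi-start deterministic.
#'
#' By default residuals are weighted by the inverse pointwise variance of
#' the empirical CDF, \eqn{1/(p(1-p))}: measured on synthetic two-component
#' mixtures with a 2x coefficient ratio, this markedly reduces the
#' finite-sample bias of the slow component compared to the unweighted fit
#' (which over-weights the mid-CDF region); \code{weights = "none"} gives
#' the plain unweighted fit.
#'
#' @param r2 numeric vector of squared displacements, or a
#'   \code{\link{JumpSequence}}.
#' @param dt lag time (s); taken from the jump sequence if omitted.
#' @param nComponents number of mobility components.
#' @param dims 2 or 3 (kernel dimensionality); taken from the jump sequence
#'   if omitted.
#' @param minJumpsPerComponent floor on data size per requested component.
#' @param weights \code{"variance"} (default) or \code{"none"}.
#' @return a \code{\link{MobilityFit}}.
#' @export
fitCJDD <- function(r2, dt = NULL, nComponents = 1L, dims = NULL,
                    minJumpsPerComponent = 50L,
                    weights = c("variance", "none")) {
  weights <- match.arg(weights)
  if (is(r2, "JumpSequence")) {
    if (is.null(dt)) dt <- r2@dt
    if (is.null(dims)) dims <- r2@dims
    r2 <- r2@r2
  }
  if (is.null(dims)) dims <- 2L
  if (is.null(dt)) stop("'dt' is required")
  m <- as.integer(nComponents)
  if (length(r2) < m * minJumpsPerComponent)
    stop("too few jumps (", length(r2), ") for ", m, " component(s)")
  ep <- ecdfPoints(r2, weights)
  obj <- function(theta) {
    D <- exp(theta[seq_len(m)])
    a <- if (m > 1L) softmax(theta[(m + 1L):(2L * m - 1L)]) else 1
    sum(ep$w * (ep$p - cjddModel(ep$x, D, a, dt, dims))^2)
  }
  best <- .cjddOptim(obj, m, m - 1L)
  if (is.null(best)) stop("CJDD fit failed to converge from all starts")
  theta <- best$par
  D <- exp(theta[seq_len(m)])
  a <- if (m > 1L) softmax(theta[(m + 1L):(2L * m - 1L)]) else 1
  ord <- order(D)
  # delta-method standard errors from the Gauss-Newton covariance
  se <- list(D = rep(NA_real_, m), fractions = rep(NA_real_, m))
  hess <- tryCatch(optim(theta, obj, method = "BFGS", hessian = TRUE,
                         control = list(maxit = 1))$hessian,
                   error = function(e) NULL)
  if (!is.null(hess)) {
    s2 <- best$value / max(length(ep$x) - length(theta), 1L)
    cv <- tryCatch(2 * s2 * solve(hess), error = function(e) NULL)
    if (!is.null(cv) && all(is.finite(diag(cv))) && all(diag(cv) >= 0)) {
      seTheta <- sqrt(diag(cv))
      se$D <- (D * seTheta[seq_len(m)])[ord]
      if (m > 1L) {
        # softmax Jacobian d a_i / d w_j = a_i (delta_ij - a_j)
        J <- matrix(0, m, m - 1L)
        for (i in seq_len(m)) for (j in seq_len(m - 1L))
          J[i, j] <- a[i] * ((i == j) - a[j])
        cva <- J %*% cv[(m + 1L):(2L * m - 1L), (m + 1L):(2L * m - 1L),
                        drop = FALSE] %*% t(J)
        se$fractions <- sqrt(pmax(diag(cva), 0))[ord]
      } else se$fractions <- 0
    }
  }
  new("MobilityFit", D = unname(D[ord]),
      fractions = unname(if (m > 1L) a[ord] else 1),
      se = se, sse = best$value, converged = best$convergence == 0,
      dt = dt, dims = as.integer(dims), nJumps = length(r2))
}

#' Global mixture fit with shared diffusion coefficients
#'
#' Fits one shared set of diffusion coefficients to the cumulative
#' jump-distance distributions of several trajectories, with free component
#' fractions per trajectory; the objective is the summed per-trajectory CDF
#' residual. Fractions for the pooled data (all squared displacements
#' together, with the shared D fixed) are reported as well.
#'
#' @param jumps list of \code{\link{JumpSequence}} objects (or numeric
#'   vectors of squared displacements).
#' @param dt lag time (s); required when plain vectors are supplied.
#' @param nComponents number of shared mobility components.
#' @param dims 2 or 3.
#' @param weights \code{"variance"} (default) or \code{"none"}; see
#'   \code{\link{fitCJDD}}.
#' @return list with \code{D} (shared, ascending), \code{fractions}
#'   (trajectories x components matrix), \code{pooled} (a
#'   \code{\link{MobilityFit}} for the pooled data at fixed D), \code{sse}
#'   and \code{converged}.
#' @export
globalFitCJDD <- function(jumps, dt = NULL, nComponents = 2L, dims = NULL,
                          weights = c("variance", "none")) {
  weights <- match.arg(weights)
  if (length(jumps) < 2L) stop("need at least two trajectories")
  asR2 <- function(j) if (is(j, "JumpSequence")) j@r2 else j
  if (is.null(dt)) {
    dts <- vapply(jumps, function(j)
      if (is(j, "JumpSequence")) j@dt else NA_real_, numeric(1))
    dt <- dts[1]
    if (anyNA(dts) || any(abs(dts - dt) > 1e-12))
      stop("jump sequences must share one lag time")
  }
  if (is.null(dims)) {
    dims <- if (is(jumps[[1]], "JumpSequence")) jumps[[1]]@dims else 2L
  }
  m <- as.integer(nComponents)
  tN <- length(jumps)
  eps <- lapply(jumps, function(j) ecdfPoints(asR2(j), weights))
  if (m == 2L) {
    # fractions enter the model linearly, so for two components the
    # per-trajectory slow fraction given (D1, D2) has a closed form
    # (simplex-clipped linear least squares); profiling it out leaves a
    # two-parameter outer problem, which is faster and better conditioned
    # than the joint optimization and has the same minimizer.
    profA <- function(ep, D) {
      y <- 1 - ep$p                      # empirical survival
      k1 <- cjddSurvival(ep$x, D[1], dt, dims)
      k2 <- cjddSurvival(ep$x, D[2], dt, dims)
      d <- k1 - k2
      den <- sum(ep$w * d * d)
      a <- if (den <= 0) 0.5 else sum(ep$w * (y - k2) * d) / den
      min(max(a, 0), 1)
    }
    sseA <- function(ep, D, a) {
      mod <- a * cjddSurvival(ep$x, D[1], dt, dims) +
        (1 - a) * cjddSurvival(ep$x, D[2], dt, dims)
      sum(ep$w * (1 - ep$p - mod)^2)
    }
    obj <- function(theta) {
      D <- exp(theta)
      tot <- 0
      for (ti in seq_len(tN))
        tot <- tot + sseA(eps[[ti]], D, profA(eps[[ti]], D))
      tot
    }
    best <- .cjddOptim(obj, m, 0L, maxit = 1000L)
    if (is.null(best)) stop("global CJDD fit failed from all starts")
    theta <- best$par
    D <- exp(theta)
    ord <- order(D)
    fr <- matrix(NA_real_, tN, m)
    for (ti in seq_len(tN)) {
      a <- profA(eps[[ti]], D)
      fr[ti, ] <- c(a, 1 - a)[ord]
    }
  } else {
    obj <- function(theta) {
      D <- exp(theta[seq_len(m)])
      tot <- 0
      for (ti in seq_len(tN)) {
        w <- if (m > 1L)
          theta[m + (ti - 1L) * (m - 1L) + seq_len(m - 1L)] else numeric(0)
        a <- if (m > 1L) softmax(w) else 1
        tot <- tot + sum(eps[[ti]]$w * (eps[[ti]]$p -
                          cjddModel(eps[[ti]]$x, D, a, dt, dims))^2)
      }
      tot
    }
    best <- .cjddOptim(obj, m, tN * (m - 1L), maxit = 1000L)
    if (is.null(best)) stop("global CJDD fit failed from all starts")
    theta <- best$par
    D <- exp(theta[seq_len(m)])
    ord <- order(D)
    fr <- matrix(1, tN, m)
    if (m > 1L) {
      for (ti in seq_len(tN)) {
        w <- theta[m + (ti - 1L) * (m - 1L) + seq_len(m - 1L)]
        fr[ti, ] <- softmax(w)[ord]
      }
    }
  }
  pooledR2 <- unlist(lapply(jumps, asR2))
  pooled <- fitFractionsFixedD(pooledR2, sort(D), dt, dims, weights)
  list(D = unname(sort(D)), fractions = fr, pooled = pooled,
       sse = best$value, converged = best$convergence == 0)
}

# Fractions-only CJDD fit with the diffusion coefficients held fixed.
fitFractionsFixedD <- function(r2, D, dt, dims = 2L,
                               weights = c("variance", "none")) {
  m <- length(D)
  ep <- ecdfPoints(r2, match.arg(weights))
  if (m == 1L) {
    return(new("MobilityFit", D = D, fractions = 1,
               se = list(D = NA_real_, fractions = 0),
               sse = sum(ep$w * (ep$p - cjddModel(ep$x, D, 1, dt, dims))^2),
               converged = TRUE, dt = dt, dims = as.integer(dims),
               nJumps = length(r2)))
  }
  obj <- function(w) {
    a <- softmax(w)
    sum(ep$w * (ep$p - cjddModel(ep$x, D, a, dt, dims))^2)
  }
  fit <- optim(rep(0, m - 1L), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  a <- softmax(fit$par)
  se <- list(D = rep(NA_real_, m), fractions = rep(NA_real_, m))
  h <- tryCatch(stats::optimHess(fit$par, obj), error = function(e) NULL)
  if (!is.null(h)) {
    s2 <- fit$value / max(length(ep$x) - (m - 1L), 1L)
    cv <- tryCatch(2 * s2 * solve(h), error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) >= 0)) {
      J <- matrix(0, m, m - 1L)
      for (i in seq_len(m)) for (j in seq_len(m - 1L))
        J[i, j] <- a[i] * ((i == j) - a[j])
      se$fractions <- sqrt(pmax(diag(J %*% cv %*% t(J)), 0))
    }
  }
  new("MobilityFit", D = D, fractions = unname(a), se = se,
      sse = fit$value, converged = fit$convergence == 0, dt = dt,
      dims = as.integer(dims), nJumps = length(r2))
}

# Mixture density of the squared displacement: exponential components with
# mean 4 D dt in 2D, scaled chi-square (df = 3) in 3D.
.cjddDensity <- function(r2, D, fractions, dt, dims = 2L) {
  s <- 0
  for (i in seq_along(D)) {
    s <- s + fractions[i] * (
      if (dims == 2L) exp(-r2 / (4 * D[i] * dt)) / (4 * D[i] * dt)
      else dchisq(r2 / (2 * D[i] * dt), df = dims) / (2 * D[i] * dt))
  }
  s
}

#' Maximum-likelihood mixture fit of the jump-distance distribution
#'
#' Cross-check for \code{\link{fitCJDD}}: fits the same mixture model by
#' maximizing the likelihood of the squared displacements instead of least
#' squares against the empirical CDF. Same parameterization (log-D,
#' softmax fractions) and deterministic multi-start.
#'
#' @inheritParams fitCJDD
#' @return a \code{\link{MobilityFit}} (standard errors from the observed
#'   information when available).
#' @export
fitCJDDML <- function(r2, dt = NULL, nComponents = 1L, dims = NULL,
                      minJumpsPerComponent = 50L) {
  if (is(r2, "JumpSequence")) {
    if (is.null(dt)) dt <- r2@dt
    if (is.null(dims)) dims <- r2@dims
    r2 <- r2@r2
  }
  if (is.null(dims)) dims <- 2L
  if (is.null(dt)) stop("'dt' is required")
  m <- as.integer(nComponents)
  if (length(r2) < m * minJumpsPerComponent)
    stop("too few jumps (", length(r2), ") for ", m, " component(s)")
  obj <- function(theta) {
    D <- exp(theta[seq_len(m)])
    a <- if (m > 1L) softmax(theta[(m + 1L):(2L * m - 1L)]) else 1
    -sum(log(pmax(.cjddDensity(r2, D, a, dt, dims), 1e-300)))
  }
  best <- .cjddOptim(obj, m, m - 1L)
  if (is.null(best)) stop("ML fit failed to converge from all starts")
  theta <- best$par
  D <- exp(theta[seq_len(m)])
  a <- if (m > 1L) softmax(theta[(m + 1L):(2L * m - 1L)]) else 1
  ord <- order(D)
  se <- list(D = rep(NA_real_, m), fractions = rep(NA_real_, m))
  h <- tryCatch(stats::optimHess(theta, obj), error = function(e) NULL)
  if (!is.null(h)) {
    cv <- tryCatch(solve(h), error = function(e) NULL)
    if (!is.null(cv) && all(is.finite(diag(cv))) && all(diag(cv) >= 0)) {
      seTheta <- sqrt(diag(cv))
      se$D <- (D * seTheta[seq_len(m)])[ord]
      if (m > 1L) {
        J <- matrix(0, m, m - 1L)
        for (i in seq_len(m)) for (j in seq_len(m - 1L))
          J[i, j] <- a[i] * ((i == j) - a[j])
        cva <- J %*% cv[(m + 1L):(2L * m - 1L), (m + 1L):(2L * m - 1L),
                        drop = FALSE] %*% t(J)
        se$fractions <- sqrt(pmax(diag(cva), 0))[ord]
      } else se$fractions <- 0
    }
  }
  new("MobilityFit", D = unname(D[ord]),
      fractions = unname(if (m > 1L) a[ord] else 1),
      se = se, sse = best$value, converged = best$convergence == 0,
      dt = dt, dims = as.integer(dims), nJumps = length(r2))
}

#' Histogram-based mixture fit of the jump-distance distribution
#'
#' The binned alternative to the cumulative fit: squared displacements are
#' histogrammed and the per-bin relative frequencies are fitted by least
#' squares against the model bin probabilities (differences of the model
#' CDF at the bin edges).
#'
#' @inheritParams fitCJDD
#' @param nBins number of equal-probability bins (quantile edges).
#' @return a \code{\link{MobilityFit}} (no standard errors).
#' @export
fitJDDHistogram <- function(r2, dt = NULL, nComponents = 1L, dims = NULL,
                            nBins = 30L, minJumpsPerComponent = 50L) {
  if (is(r2, "JumpSequence")) {
    if (is.null(dt)) dt <- r2@dt
    if (is.null(dims)) dims <- r2@dims
    r2 <- r2@r2
  }
  if (is.null(dims)) dims <- 2L
  if (is.null(dt)) stop("'dt' is required")
  m <- as.integer(nComponents)
  if (length(r2) < m * minJumpsPerComponent)
    stop("too few jumps (", length(r2), ") for ", m, " component(s)")
  edges <- unique(quantile(r2, probs = seq(0, 1, length.out = nBins + 1L),
                           names = FALSE))
  edges[1] <- 0; edges[length(edges)] <- Inf
  counts <- tabulate(findInterval(r2, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  freq <- counts / length(r2)
  binProb <- function(D, a) {
    cdf <- cjddModel(edges, D, a, dt, dims)
    cdf[length(edges)] <- 1
    diff(cdf)
  }
  obj <- function(theta) {
    D <- exp(theta[seq_len(m)])
    a <- if (m > 1L) softmax(theta[(m + 1L):(2L * m - 1L)]) else 1
    sum((freq - binProb(D, a))^2)
  }
  best <- .cjddOptim(obj, m, m - 1L)
  if (is.null(best)) stop("histogram fit failed to converge from all starts")
  theta <- best$par
  D <- exp(theta[seq_len(m)])
  a <- if (m > 1L) softmax(theta[(m + 1L):(2L * m - 1L)]) else 1
  ord <- order(D)
  new("MobilityFit", D = unname(D[ord]),
      fractions = unname(if (m > 1L) a[ord] else 1),
      se = list(D = rep(NA_real_, m), fractions = rep(NA_real_, m)),
      sse = best$value, converged = best$convergence == 0,
      dt = dt, dims = as.integer(dims), nJumps = length(r2))
}
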