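# Mobility-state statistics on single trajectories: threshold
# classification of the jump sequence, exact Bernoulli run-length dwell
# significance, the transition-frequency test, and a global threshold scan.

#' Classify a jump sequence into two mobility states
#'
#' Jumps with squared displacement at or below the threshold belong to
#' state A (reduced mobility), the rest to state B. The state-A probability
#' is the empirical CDF of the squared displacements at the threshold, so
#' that under the null the labels are i.i.d. Bernoulli trials.
#'
#' @param jumps a \code{\link{JumpSequence}} or numeric vector of squared
#'   displacements (micron^2).
#' @param r2lim squared-displacement threshold (micron^2).
#' @return a \code{\link{StateSequence}}.
#' @export
classifyJumps <- function(jumps, r2lim) {
  r2 <- if (is(jumps, "JumpSequence")) jumps@r2 else jumps
  if (length(r2) < 1L) stop("need at least one jump")
  a <- r2 <= r2lim
  new("StateSequence", r2lim = r2lim, stateA = a, pA = mean(a),
      n = length(a))
}

#' Probability that n Bernoulli trials contain no success run of length k
#'
#' Exact alternating-sum expression for the probability that a sequence of
#' \code{n} independent trials with success probability \code{p} contains no
#' run of \code{k} or more consecutive successes:
#' \deqn{\sum_{m=0}^{\lfloor (n+1)/(k+1) \rfloor} (-1)^m p^{mk}
#'   (1-p)^{m-1} \left[ \binom{n-mk}{m-1} + (1-p) \binom{n-mk}{m} \right]}
#' with binomial coefficients of negative lower index equal to zero.
#'
#' Evaluated literally in floating point, the alternating sum cancels
#' catastrophically when \code{k} is small relative to \code{n} (individual
#' terms grow combinatorially while the result stays in [0, 1]). The value
#' is therefore computed through the algebraically equivalent first-passage
#' recurrence \eqn{a_i = a_{i-1} - (1-p) p^k a_{i-k-1}} (with \eqn{a_i = 1}
#' for \eqn{i < k} and \eqn{a_k = 1 - p^k}), which is exact and stable for
#' all arguments; the literal sum is retained internally and agrees in its
#' stable regime.
#'
#' @param n number of trials (>= 1).
#' @param k run length (>= 1).
#' @param p success probability in [0, 1].
#' @return probability in [0, 1].
#' @seealso \code{\link{dwellSignificance}} for the complementary
#'   probability used as dwell-time significance.
#' @export
probNoRun <- function(n, k, p) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a single probability in [0, 1]")
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L || k < 1L) stop("'n' and 'k' must be >= 1")
  if (k > n) return(1)
  if (p == 0) return(1)
  if (p == 1) return(0)
  pk <- p^k
  qpk <- (1 - p) * pk
  a <- numeric(n + 1L)            # a[i + 1] = P(no run of >= k in i trials)
  a[seq_len(k)] <- 1              # i = 0 .. k-1
  a[k + 1L] <- 1 - pk             # i = k
  if (n > k) for (i in (k + 1L):n)
    a[i + 1L] <- a[i] - qpk * a[i - k]
  min(max(a[n + 1L], 0), 1)
}

# Literal evaluation of the printed alternating sum (log-domain terms).
# Reference implementation: agrees with probNoRun when the terms decay
# (large k), but cancels catastrophically for small k at large n. Used in
# tests only.
.probNoRunSum <- function(n, k, p) {
  n <- as.integer(n); k <- as.integer(k)
  if (k > n) return(1)
  if (p == 0) return(1)
  if (p == 1) return(0)
  mmax <- (n + 1L) %/% (k + 1L)
  total <- 1  # m = 0 term
  if (mmax >= 1L) {
    m <- seq_len(mmax)
    top <- n - m * k
    l1 <- ifelse(top >= m - 1L, lchoose(top, m - 1L), -Inf)
    l2 <- ifelse(top >= m, log1p(-p) + lchoose(top, m), -Inf)
    hi <- pmax(l1, l2)
    lsum <- ifelse(is.infinite(hi) & hi < 0, -Inf,
                   hi + log(exp(l1 - hi) + exp(l2 - hi)))
    logTerm <- m * k * log(p) + (m - 1L) * log1p(-p) + lsum
    total <- total + sum((-1)^m * exp(logTerm))
  }
  min(max(total, 0), 1)
}

#' Dwell-time significance from exact run-length statistics
#'
#' The probability that a sequence of \code{n} i.i.d. Bernoulli-classified
#' jumps contains at least one run of \code{k} or more same-state jumps,
#' i.e. one minus \code{\link{probNoRun}}. Long dwell times in one mobility
#' state yield small values; values below 0.05 are conventionally regarded
#' as significant deviations from random Brownian behavior. The statistic
#' is non-increasing in \code{k} and non-decreasing in \code{p} and
#' \code{n}.
#'
#' @inheritParams probNoRun
#' @return significance P' in [0, 1].
#' @export
dwellSignificance <- function(n, k, p) {
  1 - probNoRun(n, k, p)
}

#' Identify dwell times and their significance in a state sequence
#'
#' All maximal runs of consecutive same-state jumps are annotated with the
#' exact run-length significance computed from the whole-sequence state
#' probability (state A uses pA, state B uses 1 - pA).
#'
#' @param seq a \code{\link{StateSequence}}.
#' @param alpha significance level used for flagging.
#' @return data.frame with columns \code{start}, \code{length},
#'   \code{state} ("A"/"B"), \code{r2lim}, \code{pValue},
#'   \code{significant}.
#' @export
findDwells <- function(seq, alpha = 0.05) {
  stopifnot(is(seq, "StateSequence"))
  if (seq@n < 2L) stop("need at least two jumps")
  r <- rle(seq@stateA)
  start <- cumsum(c(1L, head(r$lengths, -1L)))
  p <- ifelse(r$values, seq@pA, 1 - seq@pA)
  pv <- vapply(seq_along(r$lengths), function(i)
    dwellSignificance(seq@n, r$lengths[i], p[i]), numeric(1))
  data.frame(start = start, length = r$lengths,
             state = ifelse(r$values, "A", "B"),
             r2lim = seq@r2lim, pValue = pv,
             significant = pv < alpha)
}

#' Global scan for significant dwell times over all thresholds
#'
#' Evaluates every candidate threshold (midpoints between sorted distinct
#' squared displacements), collects all dwell events significant at
#' \code{alpha}, and deduplicates events with overlapping index ranges,
#' keeping the lowest P' value. Significance is raw (per event);
#' an optional Bonferroni correction over the number of distinct thresholds
#' can be applied.
#'
#' @param jumps a \code{\link{JumpSequence}} or numeric vector of squared
#'   displacements (at least 10 jumps).
#' @param alpha significance level.
#' @param states which dwell states to report ("A" = reduced mobility,
#'   default both).
#' @param bonferroni logical; divide alpha by the number of thresholds.
#' @return data.frame of deduplicated significant events (possibly empty):
#'   \code{start}, \code{length}, \code{state}, \code{r2lim},
#'   \code{pValue}.
#' @export
scanThresholds <- function(jumps, alpha = 0.05, states = c("A", "B"),
                           bonferroni = FALSE) {
  r2 <- if (is(jumps, "JumpSequence")) jumps@r2 else jumps
  if (length(r2) < 10L) stop("need at least 10 jumps for a threshold scan")
  u <- sort(unique(r2))
  if (length(u) < 2L) return(data.frame(
    start = integer(0), length = integer(0), state = character(0),
    r2lim = numeric(0), pValue = numeric(0)))
  thresholds <- (head(u, -1L) + tail(u, -1L)) / 2
  lim <- if (bonferroni) alpha / length(thresholds) else alpha
  n <- length(r2)
  # smallest run length significant at lim for state probability p
  # (dwellSignificance is non-increasing in k), NA when none is
  kMin <- function(p) {
    if (dwellSignificance(n, n, p) >= lim) return(NA_integer_)
    if (dwellSignificance(n, 1L, p) < lim) return(1L)
    lo <- 1L; hi <- n
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (dwellSignificance(n, mid, p) < lim) hi <- mid else lo <- mid
    }
    hi
  }
  events <- list()
  for (th in thresholds) {
    a <- r2 <= th
    pA <- mean(a)
    r <- rle(a)
    start <- cumsum(c(1L, head(r$lengths, -1L)))
    kA <- if ("A" %in% states) kMin(pA) else NA_integer_
    kB <- if ("B" %in% states) kMin(1 - pA) else NA_integer_
    hit <- (r$values & !is.na(kA) & r$lengths >= kA) |
      (!r$values & !is.na(kB) & r$lengths >= kB)
    if (!any(hit)) next
    idx <- which(hit)
    pv <- vapply(idx, function(i)
      dwellSignificance(n, r$lengths[i], if (r$values[i]) pA else 1 - pA),
      numeric(1))
    events[[length(events) + 1L]] <- data.frame(
      start = start[idx], length = r$lengths[idx],
      state = ifelse(r$values[idx], "A", "B"), r2lim = th, pValue = pv)
  }
  if (length(events) == 0L) return(data.frame(
    start = integer(0), length = integer(0), state = character(0),
    r2lim = numeric(0), pValue = numeric(0)))
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$pValue), , drop = FALSE]
  keep <- logical(nrow(ev))
  accepted <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(ev))) {
    lo <- ev$start[i]; hi <- ev$start[i] + ev$length[i] - 1L
    overlap <- nrow(accepted) > 0 &&
      any(accepted[, 1] <= hi & accepted[, 2] >= lo)
    if (!overlap) {
      keep[i] <- TRUE
      accepted <- rbind(accepted, c(lo, hi))
    }
  }
  out <- ev[keep, c("start", "length", "state", "r2lim", "pValue")]
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Transition-frequency statistics of a state sequence
#'
#' Counts the observed transitions between states A and B and compares them
#' with the i.i.d. expectation \eqn{\langle s' \rangle = 2 p_A p_B n} and
#' its standard deviation \eqn{\sqrt{p_A p_B n}}. A significant deficit of
#' transitions indicates retention in one of the states on the timescale of
#' the frame interval, even when individual dwell times are too short to be
#' flagged.
#'
#' @param seq a \code{\link{StateSequence}}.
#' @return a \code{\link{TransitionStats}} object; degenerate (flagged) when
#'   all jumps fall into one state.
#' @export
transitionStats <- function(seq) {
  stopifnot(is(seq, "StateSequence"))
  s <- sum(diff(seq@stateA) != 0)
  pA <- seq@pA; pB <- 1 - pA; n <- seq@n
  if (pA <= 0 || pA >= 1) {
    return(new("TransitionStats", s = 0L, sExpected = 0, sigma = 0,
               zDeficit = NaN, pTail = NaN, degenerate = TRUE))
  }
  sExp <- 2 * pA * pB * n
  sig <- sqrt(pA * pB * n)
  z <- (sExp - s) / sig
  new("TransitionStats", s = as.integer(s), sExpected = sExp, sigma = sig,
      zDeficit = z, pTail = pnorm(z, lower.tail = FALSE),
      degenerate = FALSE)
}

#' Transition-deficit curve over a range of thresholds
#'
#' Computes observed and expected transition counts for a grid of
#' squared-displacement thresholds, as used to locate mobility states by
#' their transition deficit.
#'
#' @param jumps a \code{\link{JumpSequence}} or numeric vector.
#' @param thresholds numeric vector of thresholds; defaults to the interior
#'   distinct squared displacements.
#' @return data.frame: r2lim, s, sExpected, sigma, zDeficit, pTail.
#' @export
scanTransitions <- function(jumps, thresholds = NULL) {
  r2 <- if (is(jumps, "JumpSequence")) jumps@r2 else jumps
  if (is.null(thresholds)) {
    u <- sort(unique(r2))
    thresholds <- u[-length(u)]
  }
  rows <- lapply(thresholds, function(th) {
    ts <- transitionStats(classifyJumps(r2, th))
    data.frame(r2lim = th, s = ts@s, sExpected = ts@sExpected,
               sigma = ts@sigma, zDeficit = ts@zDeficit, pTail = ts@pTail)
  })
  do.call(rbind, rows)
}
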