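# states module: threshold classification, exact run-length significance,
# dwell detection, threshold scan and transition-frequency statistics.

test_that("classifyJumps defines pA as the ECDF at the threshold", {
  r2 <- c(5, 1, 4, 2, 6, 3, 8, 7, 10, 9)
  sq <- classifyJumps(r2, r2lim = 5.5)
  expect_s4_class(sq, "StateSequence")
  expect_equal(sq@pA, 0.5)            # median threshold, even n
  expect_equal(sq@stateA, r2 <= 5.5)
  expect_equal(sq@n, 10L)
  expect_equal(stateProbability(sq), ecdf(r2)(5.5))
  expect_error(classifyJumps(numeric(0), 1), "at least one")
})

test_that("probNoRun reproduces the printed examples and guards its input", {
  expect_equal(probNoRun(1, 1, 0.3), 0.7)
  expect_equal(probNoRun(2, 2, 0.5), 0.75)
  expect_equal(probNoRun(3, 5, 0.5), 1)   # k > n
  expect_equal(probNoRun(10, 2, 0), 1)
  expect_equal(probNoRun(10, 2, 1), 0)
  expect_error(probNoRun(10, 2, -0.1), "probability")
  expect_error(probNoRun(10, 2, 1.4), "probability")
  expect_equal(dwellSignificance(2, 2, 0.5), 0.25)
})

test_that("probNoRun matches exhaustive enumeration for small n", {
  for (n in c(4L, 8L, 12L)) for (k in c(1L, 2L, n %/% 2L, n))
    for (p in c(0.1, 0.5, 0.9))
      expect_lt(abs(probNoRun(n, k, p) - enumProbNoRun(n, k, p)), 1e-12)
})

test_that("the literal alternating sum agrees in its stable regime", {
  sumImpl <- astigTrack:::.probNoRunSum
  for (case in list(c(40, 10, 0.6), c(60, 12, 0.4), c(221, 26, 0.58))) {
    a <- probNoRun(case[1], case[2], case[3])
    b <- sumImpl(case[1], case[2], case[3])
    expect_lt(abs(a - b) / a, 1e-10)
  }
})

test_that("dwellSignificance is monotone in k, p and n", {
  ks <- 2:12
  ps <- seq(0.1, 0.9, by = 0.2)
  ns <- c(30L, 60L, 120L)
  for (p in ps) for (n in ns) {
    v <- vapply(ks, function(k) dwellSignificance(n, k, p), numeric(1))
    expect_true(all(diff(v) <= 1e-15))         # non-increasing in k
  }
  for (n in ns) for (k in c(3L, 6L)) {
    v <- vapply(ps, function(p) dwellSignificance(n, k, p), numeric(1))
    expect_true(all(diff(v) >= -1e-15))        # non-decreasing in p
  }
  for (p in ps) for (k in c(3L, 6L)) {
    v <- vapply(ns, function(n) dwellSignificance(n, k, p), numeric(1))
    expect_true(all(diff(v) >= -1e-15))        # non-decreasing in n
  }
})

test_that("Monte-Carlo run frequency matches dwellSignificance (n = 221)", {
  # calibrate p* as in the worked example, then verify the exact result
  # against direct simulation within 3 binomial standard errors
  pStar <- uniroot(function(p) dwellSignificance(221, 26, p) - 5.2e-5,
                   c(0.3, 0.8), tol = 1e-12)$root
  target <- dwellSignificance(221, 26, pStar)
  nSim <- 1e5L; n <- 221L; k <- 26L
  set.seed(81)
  hits <- 0L
  for (chunk in seq_len(10L)) {
    m <- matrix(rbinom(n * (nSim / 10L), 1L, pStar), nrow = n)
    cs <- rbind(0, apply(m, 2, cumsum))
    ws <- cs[(k + 1L):(n + 1L), , drop = FALSE] -
      cs[1L:(n + 1L - k), , drop = FALSE]
    hits <- hits + sum(colSums(ws == k) > 0L)
  }
  se <- sqrt(target * (1 - target) / nSim)
  expect_lt(abs(hits / nSim - target), 3 * se)
})

test_that("findDwells annotates maximal runs and flags a real dwell", {
  # alternating labels: all runs length 1, none significant
  alt <- classifyJumps(rep(c(0.1, 10), 10), r2lim = 1)
  d <- findDwells(alt)
  expect_true(all(d$length == 1L))
  expect_false(any(d$significant))
  expect_equal(sum(d$length), 20L)
  # all-A sequence: degenerate p = 1 handled without error, P' = 1
  allA <- classifyJumps(rep(0.1, 8), r2lim = 1)
  dA <- findDwells(allA)
  expect_equal(nrow(dA), 1L)
  expect_equal(dA$pValue, 1)
  expect_error(findDwells(classifyJumps(0.1, 1)), "two")
  # Brownian jumps with an inserted 30-frame immobile segment (n = 250)
  dt <- 0.0165
  fast <- simulateJumps(220, D = 1, fractions = 1, dt = dt, seed = 82)
  slow <- simulateJumps(30, D = 0.02, fractions = 1, dt = dt, seed = 83)
  r2 <- append(fast, slow, after = 100)
  sq <- classifyJumps(r2, r2lim = 0.01)
  dd <- findDwells(sq)
  hit <- dd$state == "A" & dd$significant &
    dd$start <= 131 & dd$start + dd$length - 1 >= 101
  expect_true(any(hit))
})

test_that("scanThresholds detects inserted slow segments with power > 80%", {
  expect_error(scanThresholds(1:5), "10 jumps")
  dt <- 0.0165
  detected <- vapply(1:20, function(s) {
    fast <- simulateJumps(270, D = 1, fractions = 1, dt = dt, seed = 8000 + s)
    slow <- simulateJumps(30, D = 0.02, fractions = 1, dt = dt,
                          seed = 8100 + s)
    r2 <- append(fast, slow, after = 150)
    ev <- scanThresholds(r2, alpha = 0.05, states = "A")
    nrow(ev) > 0 &&
      any(ev$start <= 181 & ev$start + ev$length - 1 >= 151)
  }, logical(1))
  expect_gt(mean(detected), 0.8)
})

test_that("transitionStats implements Eqs. 5-6 with the printed n", {
  # pA = 0.5, n = 100: expected transitions 50, sigma 5
  sq <- classifyJumps(as.numeric(1:100), r2lim = 50.5)
  ts <- transitionStats(sq)
  expect_equal(ts@sExpected, 50)
  expect_equal(ts@sigma, 5)
  expect_false(ts@degenerate)
  expect_equal(ts@pTail, pnorm(ts@zDeficit, lower.tail = FALSE))
  # alternating sequence: s = n - 1
  alt <- classifyJumps(rep(c(0.1, 10), 50), r2lim = 1)
  expect_equal(transitionStats(alt)@s, 99L)
  # a 2-sigma deficit corresponds to a tail probability of ~0.0228
  expect_lt(pnorm(2, lower.tail = FALSE), 0.023)
  # single-state sequence: degenerate, flagged
  deg <- transitionStats(classifyJumps(rep(0.1, 10), 1))
  expect_true(deg@degenerate)
  expect_equal(deg@s, 0L)
})

test_that("i.i.d. transition counts average 2 pA pB (n - 1)", {
  # the printed expectation 2 pA pB n counts n pairs; an i.i.d. sequence of
  # n labels has n - 1 consecutive pairs, so the exact mean is
  # 2 p (1 - p) (n - 1) (the O(1/n) difference is a documented convention)
  p <- 0.3; n <- 100L; m <- 2000L
  set.seed(84)
  s <- vapply(seq_len(m), function(i) {
    lab <- rbinom(n, 1L, p)
    sum(diff(lab) != 0L)
  }, numeric(1))
  exact <- 2 * p * (1 - p) * (n - 1)
  expect_lt(abs(mean(s) - exact), 3 * sd(s) / sqrt(m))
  # and it is NOT within 3 s.e. of the n-pair version, confirming that the
  # difference is real but O(1/n)
  expect_lt(abs(mean(s) - 2 * p * (1 - p) * n) / exact, 0.02)
})

test_that("scanTransitions traces the deficit over thresholds", {
  dt <- 0.0165
  fast <- simulateJumps(150, D = 1, fractions = 1, dt = dt, seed = 85)
  slow <- simulateJumps(50, D = 0.02, fractions = 1, dt = dt, seed = 86)
  r2 <- append(fast, slow, after = 75)
  sc <- scanTransitions(r2, thresholds = c(0.005, 0.01, 0.05))
  expect_equal(nrow(sc), 3L)
  expect_true(all(sc$s <= sc$sExpected))  # blocked slow segment: deficit
  expect_gt(max(sc$zDeficit), 2)
})
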