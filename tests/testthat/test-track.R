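# track module: frame-wide detection, conservative nearest-neighbor linking
# and absolute-coordinate assembly.

# locs data.frame shorthand for linker tests: one row per localization,
# lateral positions in micron, z = 0.
mkLocs <- function(frame, x, y = 0, z = 0) {
  data.frame(frame = frame, x_um = x, y_um = y, zrel_um = z)
}

test_that("detectParticles finds separated emitters and nothing in blanks", {
  fix <- calibFixture()
  ph <- photonsForSnr(fix$psf, fix$cam, 6)
  em <- data.frame(x = c(2.2, 7.0, 4.6), y = c(2.4, 3.1, 7.3),
                   z = c(-0.15, 0, 0.2), photons = ph)
  img <- renderFrame(em, fix$psf, fix$cam, size = c(40L, 40L), noise = TRUE,
                     seed = 51)
  det <- detectParticles(img, fix$curve, fix$cam)
  expect_equal(nrow(det), 3L)
  # each emitter matched within one pixel laterally
  ps <- fix$cam@pixelSize
  for (i in 1:3) {
    d <- sqrt((det$x_um - em$x[i])^2 + (det$y_um - em$y[i])^2)
    expect_lt(min(d), ps)
  }
  # blank (background-only) frame -> empty result
  blank <- renderFrame(em[0, ], fix$psf, fix$cam, size = c(40L, 40L),
                       noise = TRUE, seed = 52)
  expect_equal(nrow(detectParticles(blank, fix$curve, fix$cam)), 0L)
  # threshold above the achievable score -> empty result
  expect_equal(nrow(detectParticles(img, fix$curve, fix$cam,
                                    threshold = 1.01)), 0L)
})

test_that("linkNearestNeighbor links unique mutual candidates", {
  locs <- mkLocs(frame = 1:5, x = c(0, 0.2, 0.4, 0.6, 0.8))
  tr <- linkNearestNeighbor(locs, maxDisp = 0.5)
  expect_length(tr, 1L)
  expect_equal(tr[[1]]@frame, 1:5)
  expect_equal(tr[[1]]@x, locs$x_um)
  # a jump beyond the displacement limit splits the trajectory
  locs2 <- mkLocs(frame = 1:5, x = c(0, 0.2, 2.0, 2.2, 2.4))
  tr2 <- linkNearestNeighbor(locs2, maxDisp = 0.5)
  expect_length(tr2, 2L)
  expect_equal(sort(vapply(tr2, function(t) length(t@frame), integer(1))),
               c(2L, 3L))
  # minLength filters short fragments
  tr3 <- linkNearestNeighbor(locs2, maxDisp = 0.5, minLength = 3L)
  expect_length(tr3, 1L)
})

test_that("ambiguous encounters terminate all trajectories involved", {
  locs <- rbind(mkLocs(1, c(0, 3)), mkLocs(2, c(0.8, 2.2)),
                mkLocs(3, c(1.3, 1.7)))
  tr <- linkNearestNeighbor(locs, maxDisp = 1.0)
  # frames 1-2 link uniquely; at frame 3 both ends see two candidates, so
  # both trajectories terminate and the frame-3 points start fresh
  expect_length(tr, 4L)
  lens <- sort(vapply(tr, function(t) length(t@frame), integer(1)))
  expect_equal(lens, c(1L, 1L, 2L, 2L))
  ends <- vapply(tr, function(t) tail(t@frame, 1L), numeric(1))
  expect_equal(sort(ends), c(2, 2, 3, 3))
})

test_that("linking is invariant to the row order within frames", {
  set.seed(53)
  locs <- rbind(mkLocs(1, c(0, 3, 6)), mkLocs(2, c(0.1, 3.1, 6.1)),
                mkLocs(3, c(0.2, 3.2, 6.2)))
  canon <- function(trs) {
    key <- vapply(trs, function(t)
      paste(t@frame, round(t@x, 9), collapse = ";"), character(1))
    sort(key)
  }
  tr1 <- linkNearestNeighbor(locs, maxDisp = 0.5)
  shuf <- locs[sample(nrow(locs)), ]
  tr2 <- linkNearestNeighbor(shuf, maxDisp = 0.5)
  expect_identical(canon(tr1), canon(tr2))
})

test_that("assembleAbsolute applies the stage trace per frame", {
  locs <- mkLocs(1:4, x = c(0, 0.1, 0.2, 0.3), z = c(0.1, -0.1, 0.05, 0))
  tr <- linkNearestNeighbor(locs, maxDisp = 0.5)
  stage <- new("StageTrace", frame = 1:4, stageZ = c(0, 0.5, 1.0, 1.5),
               move = rep(0, 4), latency = 1L, gain = 1)
  abs1 <- assembleAbsolute(tr, stage, frameInterval = 0.02)
  expect_equal(abs1[[1]]@z, c(0.1, 0.4, 1.05, 1.5))
  expect_equal(abs1[[1]]@t, (1:4) * 0.02)
  # zero stage leaves z unchanged
  stage0 <- new("StageTrace", frame = 1:4, stageZ = rep(0, 4),
                move = rep(0, 4), latency = 1L, gain = 1)
  expect_equal(assembleAbsolute(tr, stage0, 0.02)[[1]]@z, locs$zrel_um)
  # missing frames in the trace -> error
  stageShort <- new("StageTrace", frame = 1:3, stageZ = rep(0, 3),
                    move = rep(0, 3), latency = 1L, gain = 1)
  expect_error(assembleAbsolute(tr, stageShort, 0.02), "cover")
})

test_that("a sparse synthetic movie yields essentially unfragmented tracks", {
  fix <- calibFixture()
  ph <- photonsForSnr(fix$psf, fix$cam, 8)
  nF <- 60
  motion <- MotionModel(diffusion = 0.02, frameInterval = 0.0165)
  starts <- list(c(2.4, 2.4), c(7.2, 3.6), c(4.8, 7.2))
  paths <- lapply(seq_along(starts), function(i)
    simulatePath(motion, nF - 1, start = c(starts[[i]], 0), seed = 60 + i))
  locs <- vector("list", nF)
  for (f in seq_len(nF)) {
    em <- do.call(rbind, lapply(paths, function(p)
      data.frame(x = p$positions[f, 1], y = p$positions[f, 2],
                 z = p$positions[f, 3], photons = ph)))
    img <- renderFrame(em, fix$psf, fix$cam, size = c(40L, 40L),
                       noise = TRUE, seed = 600 + f)
    d <- detectParticles(img, fix$curve, fix$cam)
    if (nrow(d) > 0) d$frame <- f
    locs[[f]] <- d
  }
  locs <- do.call(rbind, locs[vapply(locs, nrow, integer(1)) > 0])
  # the displacement limit must budget for centroid noise (~0.15 um/axis at
  # this SNR), not just the diffusion step, to avoid spurious splits
  trs <- linkNearestNeighbor(locs, maxDisp = 0.8, dims = "xy",
                             frameInterval = 0.0165)
  # >= 95% of localizations detected, and the 3 longest trajectories
  # cover >= 95% of them (minimal fragmentation)
  expect_gt(nrow(locs), 0.95 * 3 * nF)
  lens <- sort(vapply(trs, function(t) length(t@frame), integer(1)),
               decreasing = TRUE)
  expect_gte(sum(lens[1:3]) / nrow(locs), 0.95)
})
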