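# Stripe tracing, frame-pair matching, coverage and event statistics.

test_that("traceStripes recovers programmed stripes and their lengths", {
  cell <- paperCell(origin = c(20, 30))
  occ <- data.frame(id = 1:3, row = c(0L, 1L, 3L),
                    slotMin = c(0L, 2L, -1L), slotMax = c(9L, 6L, 4L))
  clean <- renderTopograph(occ, RepeatUnitTemplate(), fullLayers(), cell,
                           cleanScan(c(128L, 128L)))
  tr <- traceStripes(clean, cell)
  expect_equal(nrow(tr), 3L)
  expect_setequal(tr$row, c(0, 1, 3))
  expect_equal(tr$length_nm[tr$row == 0], 10 * 3.6)   # 10 slots x a/3
  expect_equal(tr$slotMin[tr$row == 1], 2)
  expect_equal(tr$slotMax[tr$row == 1], 6)

  # same result with instrument blur and noise
  noisy <- renderTopograph(occ, RepeatUnitTemplate(), fullLayers(), cell,
                           ScanParams(imageShape = c(128L, 128L),
                                      seed = 6L))
  expect_equal(traceStripes(noisy, cell)[, c("row", "slotMin", "slotMax")],
               tr[, c("row", "slotMin", "slotMax")])

  # bare membrane has nothing to trace
  bare <- renderTopograph(occ[0, ], RepeatUnitTemplate(), fullLayers(),
                          cell, ScanParams(imageShape = c(128L, 128L),
                                           seed = 2L))
  expect_equal(nrow(traceStripes(bare, cell)), 0L)
})

test_that("matchAndMeasure classifies end growth, gaps and stripe turnover", {
  cell <- paperCell()
  mk <- function(id, row, s0, s1)
    data.frame(id = id, row = row, slotMin = s0, slotMax = s1,
               length_nm = (s1 - s0 + 1) * 3.6, x0 = 0, y0 = 0, x1 = 1,
               y1 = 0)
  # growth by 3 slots at one end: one association of 10.8 nm
  rec <- matchAndMeasure(mk(1, 0, 0, 13), mk(1, 0, 0, 16), cell)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$event, "assoc")
  expect_equal(rec$length_nm, 10.8)

  # gap opens inside a stripe: one dissociation of the gap length
  rec2 <- matchAndMeasure(mk(1, 0, 0, 19),
                          rbind(mk(1, 0, 0, 8), mk(2, 0, 12, 19)), cell)
  expect_equal(nrow(rec2), 1L)
  expect_equal(rec2$event, "dissoc")
  expect_equal(rec2$length_nm, 3 * 3.6)

  # vanished stripe: dissociation of the full length
  rec3 <- matchAndMeasure(mk(1, 0, 0, 5), mk(1, 0, 0, 5)[0, ], cell)
  expect_equal(rec3$event, "dissoc")
  expect_equal(rec3$length_nm, 6 * 3.6)

  # new stripe: association of the full length
  rec4 <- matchAndMeasure(mk(1, 0, 0, 5),
                          rbind(mk(1, 0, 0, 5), mk(2, 2, 4, 7)), cell)
  expect_equal(rec4$event, "assoc")
  expect_equal(rec4$length_nm, 4 * 3.6)
})

test_that("measured kinetics equal the generator event log (oracle)", {
  for (clean in c(TRUE, FALSE)) {
    mv <- demoMovie(nFrames = 10L, seed = 5L, clean = clean)
    cfg <- demoConfig(nFrames = 10L, seed = 5L)
    mk <- measureMovieKinetics(mv$stack, cfg$lattice, minLength = 3)
    frames <- 2:10
    gtA <- eventTotals(mv$eventLog, "frame", c("assoc", "nucleate"), frames)
    gtD <- eventTotals(mv$eventLog, "frame", "dissoc", frames)
    meA <- eventTotals(mk$records, "frame_t1", "assoc", frames)
    meD <- eventTotals(mk$records, "frame_t1", "dissoc", frames)
    expect_equal(meA, gtA)
    expect_equal(meD, gtD)
    # per-event length multisets agree too (slot-pitch quantization)
    gtLen <- sort(mv$eventLog$length_nm)
    meLen <- sort(mk$records$length_nm)
    expect_equal(meLen, gtLen)
  }
})

test_that("traced-length conservation holds for every analyzed movie", {
  mv <- demoMovie(nFrames = 10L, seed = 5L)
  cfg <- demoConfig(nFrames = 10L, seed = 5L)
  mk <- measureMovieKinetics(mv$stack, cfg$lattice, minLength = 3)
  total <- vapply(mk$traces, function(tr) sum(tr$length_nm), numeric(1))
  sgn <- ifelse(mk$records$event == "dissoc", -1, 1)
  expect_equal(total[[length(total)]] - total[[1]],
               sum(sgn * mk$records$length_nm))
})

test_that("cumulativeCoverage accumulates signed increments", {
  rec <- data.frame(frame_t = c(1, 1, 2, 2), frame_t1 = c(2, 2, 3, 3),
                    stripe_id = 1, event = c("assoc", "dissoc", "assoc",
                                             "dissoc"),
                    slots = 1, length_nm = c(10, 0, 5, 3))
  cov <- cumulativeCoverage(rec, frameInterval = 2)
  expect_equal(cov$coverage_nm, c(10, 12))
  expect_equal(cov$time_s, c(4, 6))

  zero <- rec; zero$length_nm <- 0
  expect_equal(cumulativeCoverage(zero)$coverage_nm, c(0, 0))

  neg <- data.frame(frame_t = 1, frame_t1 = 2, stripe_id = 1,
                    event = "dissoc", slots = 2, length_nm = 7.2)
  expect_equal(cumulativeCoverage(neg)$coverage_nm, -7.2)
})

test_that("unitSizeStats summarizes event-length classes", {
  rec <- data.frame(frame_t = 1, frame_t1 = 2, stripe_id = 1,
                    event = c("assoc", "assoc", "assoc"),
                    slots = 1:3, length_nm = c(3.6, 7.2, 10.8))
  us <- unitSizeStats(rec)
  expect_equal(us$association@median, 7.2)
  expect_null(us$dissociation)
  expect_true("dissociation" %in% attr(us, "empty"))

  same <- data.frame(frame_t = 1, frame_t1 = 2, stripe_id = 1,
                     event = rep(c("assoc", "dissoc"), 3), slots = 1,
                     length_nm = 3.6)
  us2 <- unitSizeStats(same)
  expect_equal(us2$both@median, 3.6)
  expect_equal(us2$both@notch, 0)
})

test_that("unit-size medians track the programmed event distribution", {
  # deterministic-rate oracle: Poisson(4) net-of-Poisson(0) end increments
  cell <- paperCell()
  mov <- simulateGrowth(cell, GrowthParams(kAssoc = 4, kDissoc = 0,
                                           kNucleate = 0),
                        nFrames = 40, seed = 23)
  el <- eventLog(mov)
  us <- unitSizeStats(el)
  # median event size ~ Poisson(4) median (4 slots = 14.4 nm), within the
  # notch interval of the sample median
  expect_lt(abs(us$association@median - 4 * 3.6), us$association@notch + 1.8)
})

test_that("gaussianFit recovers parameters and degrades gracefully", {
  x <- seq(-6, 6, 0.25)
  y <- 3 * exp(-(x - 0.7)^2 / (2 * 1.3^2)) + 0.5
  f <- gaussianFit(x, y)
  expect_true(f$converged)
  expect_equal(c(f$amplitude, f$centre, f$width, f$offset),
               c(3, 0.7, 1.3, 0.5), tolerance = 1e-6)
  expect_lt(f$residualNorm, 1e-8)

  fc <- gaussianFit(x, rep(2.5, length(x)))
  expect_true(fc$converged)
  expect_equal(fc$amplitude, 0)
  expect_equal(fc$offset, 2.5)

  # parameter error shrinks as the noise level drops
  err <- vapply(c(0.3, 0.003), function(s) {
    set.seed(7)
    fn <- gaussianFit(x, y + rnorm(length(x), sd = s))
    abs(fn$centre - 0.7) + abs(fn$width - 1.3)
  }, numeric(1))
  expect_lt(err[2], err[1])
})
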