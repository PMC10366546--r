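# Synthetic movie generator: growth kinetics, rendering, composition.

test_that("growth without removal never shrinks and frozen rates freeze", {
  cell <- paperCell()
  mov <- simulateGrowth(cell, GrowthParams(kAssoc = 2, kDissoc = 0,
                                           kNucleate = 0),
                        nFrames = 12, seed = 7)
  lens <- vapply(seq_len(nFrames(mov)), function(f) {
    fr <- getFrame(mov, f)
    sum(fr$slotMax - fr$slotMin + 1)
  }, numeric(1))
  expect_true(all(diff(lens) >= 0))

  frozen <- simulateGrowth(cell, GrowthParams(kAssoc = 0, kDissoc = 0,
                                              kNucleate = 0),
                           nFrames = 6, seed = 7)
  for (f in 2:6)
    expect_identical(getFrame(frozen, f), getFrame(frozen, 1))
  expect_equal(nrow(eventLog(frozen)), 0L)
})

test_that("deterministic single-end growth logs the closed-form length", {
  # 2 slots/end/frame, 1 active end, 5 growth steps, pitch 3.6 nm -> 36 nm
  cell <- paperCell()
  mov <- simulateGrowth(cell, GrowthParams(kAssoc = 2, kDissoc = 0,
                                           kNucleate = 0),
                        nFrames = 6, deterministic = TRUE,
                        activeEnds = "plus")
  el <- eventLog(mov)
  expect_equal(sum(el$length_nm[el$event == "assoc"]), 36)
  expect_equal(unique(el$end), "plus")
})

test_that("event log satisfies exact per-stripe conservation", {
  cell <- paperCell(origin = c(64, 64))
  layers <- LayerModel(membraneMask = list(shape = "disc",
                                           centre = c(64, 64), radius = 40))
  init <- data.frame(id = 1:2, row = c(0L, 2L), slotMin = c(-3L, 0L),
                     slotMax = c(3L, 4L))
  mov <- simulateGrowth(cell, GrowthParams(kAssoc = 2, kDissoc = 1.5,
                                           kNucleate = 0.2,
                                           edgeInstabilityFactor = 3),
                        nFrames = 25, seed = 13, init = init,
                        layers = layers)
  el <- eventLog(mov)
  last <- getFrame(mov, nFrames(mov))
  ids <- unique(c(init$id, el$stripe_id))
  for (id in ids) {
    init_len <- if (id %in% init$id)
      init$slotMax[init$id == id] - init$slotMin[init$id == id] + 1 else 0
    ev <- el[el$stripe_id == id, , drop = FALSE]
    gained <- sum(ev$slots[ev$event %in% c("assoc", "nucleate")])
    lost <- sum(ev$slots[ev$event == "dissoc"])
    final <- if (id %in% last$id)
      last$slotMax[last$id == id] - last$slotMin[last$id == id] + 1 else 0
    expect_identical(as.integer(final), as.integer(init_len + gained - lost))
  }
})

test_that("growth is reproducible under a fixed seed", {
  cell <- paperCell()
  g <- GrowthParams(kAssoc = 3, kDissoc = 1, kNucleate = 0.1)
  m1 <- simulateGrowth(cell, g, 10, seed = 21)
  m2 <- simulateGrowth(cell, g, 10, seed = 21)
  expect_identical(eventLog(m1), eventLog(m2))
  expect_identical(getFrame(m1, 10), getFrame(m2, 10))
})

test_that("rendered layers reproduce mica/membrane/protein heights", {
  cell <- paperCell(origin = c(32, 32))
  layers <- LayerModel(membraneThickness = 7, proteinHeight = 5,
                       membraneMask = list(shape = "disc",
                                           centre = c(32, 32), radius = 24))
  scan <- cleanScan(c(128L, 128L))
  empty <- renderTopograph(data.frame(id = integer(), row = integer(),
                                      slotMin = integer(),
                                      slotMax = integer()),
                           RepeatUnitTemplate(), layers, cell, scan)
  expect_identical(max(heights(empty)), 7)
  expect_identical(min(heights(empty)), 0)

  occ <- data.frame(id = 1L, row = 0L, slotMin = -2L, slotMax = 2L)
  topo <- renderTopograph(occ, RepeatUnitTemplate(), layers, cell, scan)
  # protein top sits at membrane + protrusion = 12 nm above mica, and
  # with blur and noise off heights take only the programmed level set
  expect_identical(max(heights(topo)), 12)
  expect_setequal(unique(as.vector(heights(topo))), c(0, 7, 11.85, 12))
})

test_that("occupancy outside the membrane patch is rejected", {
  cell <- paperCell(origin = c(32, 32))
  layers <- LayerModel(membraneMask = list(shape = "disc",
                                           centre = c(32, 32), radius = 10))
  occ <- data.frame(id = 1L, row = 0L, slotMin = 0L, slotMax = 9L)
  expect_error(
    renderTopograph(occ, RepeatUnitTemplate(), layers, cell,
                    cleanScan(c(128L, 128L))),
    "membrane")
})

test_that("rendering with a fixed seed is bit-identical", {
  cell <- paperCell(origin = c(32, 32))
  occ <- data.frame(id = 1L, row = 0L, slotMin = -2L, slotMax = 2L)
  scan <- ScanParams(imageShape = c(96L, 96L), seed = 17L)
  t1 <- renderTopograph(occ, RepeatUnitTemplate(), fullLayers(), cell, scan)
  t2 <- renderTopograph(occ, RepeatUnitTemplate(), fullLayers(), cell, scan)
  expect_identical(heights(t1), heights(t2))
  expect_gt(stats::sd(heights(t1) - heights(renderTopograph(
    occ, RepeatUnitTemplate(), fullLayers(), cell, cleanScan(c(96L, 96L))))),
    0)  # noise actually applied
})

test_that("generateMovie composes growth and rendering with ground truth", {
  cfg <- demoConfig(nFrames = 1L, seed = 4L)
  one <- generateMovie(cfg)
  expect_equal(nFrames(one$stack), 1L)
  expect_equal(nrow(one$eventLog), 0L)

  cfg3 <- demoConfig(nFrames = 3L, seed = 4L)
  m1 <- generateMovie(cfg3)
  m2 <- generateMovie(cfg3)
  for (f in 1:3)
    expect_identical(heights(getFrame(m1$stack, f)),
                     heights(getFrame(m2$stack, f)))
  expect_equal(timestamps(m1$stack), c(0, 2, 4))

  # growth-only dynamics -> monotone occupied area
  cfgG <- demoConfig(nFrames = 6L, seed = 8L)
  cfgG$growth <- GrowthParams(kAssoc = 3, kDissoc = 0, kNucleate = 0.2)
  mg <- generateMovie(cfgG)
  area <- vapply(seq_len(6), function(f) {
    fr <- getFrame(mg$occupancy, f)
    sum(fr$slotMax - fr$slotMin + 1)
  }, numeric(1))
  expect_true(all(diff(area) >= 0))
  pxArea <- vapply(seq_len(6), function(f)
    sum(heights(getFrame(mg$stack, f)) > 9.5), numeric(1))
  expect_true(all(diff(pxArea) > -50))  # pixel count monotone up to noise
})

test_that("non-finite growth rates are rejected", {
  expect_error(GrowthParams(kAssoc = Inf), "finite")
  expect_error(GrowthParams(kDissoc = NaN), "finite")
})
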