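# Height profiles, protrusion detection and notched-box statistics.

test_that("extractProfile is exact on constant and affine height fields", {
  px <- 0.5
  flat <- Topograph(matrix(7, 64, 64), px)
  pr <- extractProfile(flat, c(2, 10), c(25, 10), width = 3)
  expect_true(all(pr$height == 7))
  expect_true(all(diff(pr$position) > 0))

  # ramp h = x: bilinear interpolation reproduces the plane exactly
  ramp <- Topograph(outer(rep(1, 64), (0:63) * px), px)
  pr2 <- extractProfile(ramp, c(3, 5), c(28, 20), width = 3)
  u <- (c(28, 20) - c(3, 5)) / sqrt(sum((c(28, 20) - c(3, 5))^2))
  expect_equal(pr2$height, 3 + pr2$position * u[1], tolerance = 1e-12)

  expect_error(extractProfile(flat, c(2, 10), c(200, 10)), "outside")
})

test_that("profile over membrane-bound protein plateaus at the layer sum", {
  cell <- paperCell(origin = c(20, 30))
  occ <- data.frame(id = 1L, row = 0L, slotMin = 0L, slotMax = 9L)
  topo <- renderTopograph(occ, RepeatUnitTemplate(), fullLayers(), cell,
                          cleanScan(c(128L, 128L)))
  pr <- extractProfile(topo, c(2, 30), c(62, 30))
  expect_equal(max(pr$height), 12)   # 7 nm membrane + 5 nm protein
  expect_equal(min(pr$height), 7)
})

test_that("detectProtrusions finds and cyclically labels sinusoid peaks", {
  p <- 6
  x <- seq(0, 6 * p - 0.25, by = 0.25)
  prof <- data.frame(position = x, height = sin(2 * pi * (x - p / 4) / p))
  det <- detectProtrusions(prof, minSeparation = 2, minProminence = 0.5)
  expect_equal(nrow(det), 6L)
  expect_equal(det$label, c("1", "2", "3", "1*", "2*", "3*"))
  expect_equal(diff(det$position), rep(p, 5), tolerance = 0.26)

  mono <- data.frame(position = x, height = x)
  expect_equal(nrow(detectProtrusions(mono)), 0L)

  # two peaks closer than the separation: the higher one is kept
  prof2 <- data.frame(position = seq(0, 10, 0.5),
                      height = 2 * exp(-(seq(0, 10, 0.5) - 4)^2) +
                        1.5 * exp(-(seq(0, 10, 0.5) - 5.3)^2 / 0.3))
  det2 <- detectProtrusions(prof2, minSeparation = 3, minProminence = 0.1)
  expect_equal(nrow(det2), 1L)
  expect_equal(det2$position, 4, tolerance = 0.6)
})

test_that("plateau-topped protrusions are detected once, at their centre", {
  h <- c(0, 0, 5, 5, 5, 0, 0, 5, 5, 0, 0)
  prof <- data.frame(position = seq_along(h) - 1, height = h)
  det <- detectProtrusions(prof, minSeparation = 2, minProminence = 1)
  expect_equal(nrow(det), 2L)
  expect_equal(det$position, c(3, 7.5), tolerance = 0.51)
})

test_that("height differences follow the labelled pairings", {
  mk <- function(hts) data.frame(position = 3.6 * (seq_along(hts) - 1),
                                 height = hts,
                                 label = c("1", "2", "3", "1*", "2*", "3*"),
                                 base = rep(1:3, 2), unit = rep(0:1, each = 3))
  hd <- heightDifferenceStats(list(mk(c(5, 5, 4.8, 5, 5, 4.8))))
  expect_equal(hd[["1-2"]]@median, 0)
  expect_equal(hd[["2-3"]]@median, 0.2)
  expect_equal(hd[["3-1*"]]@median, -0.2)

  flat <- heightDifferenceStats(list(mk(rep(6, 6))))
  expect_equal(flat[["1-2"]]@median, 0)
  expect_equal(flat[["2-3"]]@median, 0)
  expect_equal(flat[["3-1*"]]@median, 0)

  # series shorter than 4 peaks are skipped with a message
  short <- mk(c(5, 5, 4.8, 5, 5, 4.8))[1:3, ]
  expect_message(out <- heightDifferenceStats(list(short)), "fewer than 4")
  expect_null(out[["1-2"]])
})

test_that("generator EF drop produces the programmed sign pattern", {
  # noise/blur off: protrusion 3 (EF) is lowered by 0.15 nm in alternate
  # repeat units, so median(2-3) > 0 and median(3-1*) < 0
  cell <- Lattice2D(10.8, 6.6, 100, origin = c(14, 6))
  occ <- do.call(rbind, lapply(0:6, function(r)
    data.frame(id = r + 1L, row = r, slotMin = 0L, slotMax = 14L)))
  topo <- renderTopograph(occ, RepeatUnitTemplate(), fullLayers(), cell,
                          cleanScan(c(160L, 160L)))
  v <- latticeVectors(cell)
  # odd rows: the EF drop falls on a strict majority of repeat units
  # (row stagger 1), so the medians equal the programmed drop exactly
  series <- lapply(c(1, 3, 5), function(r) {
    p0 <- c(14, 6) + r * v["b", ] - 0.2 / 3 * v["a", ]
    p1 <- p0 + 15 / 3 * v["a", ]
    detectProtrusions(extractProfile(topo, p0, p1),
                      minSeparation = 2, minProminence = 0.3)
  })
  expect_true(all(vapply(series, nrow, integer(1)) == 15L))
  hd <- heightDifferenceStats(series)
  expect_equal(hd[["1-2"]]@median, 0, tolerance = 1e-9)
  expect_gt(hd[["2-3"]]@median, 0)
  expect_lt(hd[["3-1*"]]@median, 0)
  # enumeration per row (5 repeat units, odd row => EF dropped for even
  # unit index): 2-3 pairs carry the drop in 3 of 5 units -> median 0.15;
  # 3-1* pairs exist for 4 units, dropped in 2 -> median -0.15/2
  expect_equal(hd[["2-3"]]@median, 0.15, tolerance = 1e-9)
  expect_equal(hd[["3-1*"]]@median, -0.075, tolerance = 1e-9)
})

test_that("notchedBox follows the Tukey-hinge/McGill conventions", {
  bs <- notchedBox(c(1, 2, 3, 4, 5))
  expect_equal(bs@median, 3)
  expect_equal(bs@q1, 2)
  expect_equal(bs@q3, 4)
  expect_equal(bs@notch, 1.57 * 2 / sqrt(5))
  expect_equal(c(bs@min, bs@max, bs@n), c(1, 5, 5))

  cc <- notchedBox(rep(4.2, 4))
  expect_equal(cc@median, 4.2)
  expect_equal(cc@notch, 0)

  expect_error(notchedBox(numeric()), "at least one")
})

test_that("notchedBox is permutation/translation-equivariant and scales 1/sqrt(n)", {
  set.seed(31)
  x <- rnorm(25)
  b1 <- notchedBox(x)
  b2 <- notchedBox(sample(x))
  expect_identical(boxStats(b1), boxStats(b2))
  b3 <- notchedBox(x + 2.5)
  expect_equal(b3@median, b1@median + 2.5)
  expect_equal(b3@q1, b1@q1 + 2.5)
  expect_equal(b3@notch, b1@notch)
  # quadrupling the sample halves the notch
  b4 <- notchedBox(rep(x, 4))
  expect_equal(b4@notch, b1@notch / 2, tolerance = 1e-9)
})
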