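# PDB ingestion, Kabsch superposition, tiling, pseudo-AFM and contours.

test_that("readStructure parses atoms and applies the altloc policy", {
  f <- writeMiniPdb(c(
    pdbAtomLine(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 1.458, 0, 0),
    pdbAtomLine(3, "CA", "ALA", "A", 2, 2.0, 1.0, 0, occ = 0.4, alt = "B"),
    pdbAtomLine(4, "CA", "ALA", "A", 2, 2.1, 1.1, 0, occ = 0.6, alt = "A"),
    "END"))
  s <- readStructure(f)
  a <- atoms(s)
  expect_equal(nrow(a), 3L)
  expect_equal(a$x[a$resno == 2], 2.1)   # higher occupancy wins
  expect_equal(a$element, c("N", "C", "C"))

  # tie on occupancy: first record kept
  f2 <- writeMiniPdb(c(
    pdbAtomLine(1, "CA", "GLY", "A", 1, 5, 0, 0, occ = 0.5, alt = "A"),
    pdbAtomLine(2, "CA", "GLY", "A", 1, 6, 0, 0, occ = 0.5, alt = "B"),
    "END"))
  expect_equal(atoms(readStructure(f2))$x, 5)

  empty <- writeMiniPdb("END")
  expect_error(readStructure(empty), "no ATOM")
  mal <- writeMiniPdb(c(pdbAtomLine(1, "CA", "GLY", "A", 1, 0, 0, 0),
                        "ATOM      2  CA  GLY A   2      bad"))
  expect_error(readStructure(mal), "line 2")
})

test_that("kabschRmsd is zero under rigid motion and lists mismatches", {
  s <- toyStructure(8)
  expect_equal(kabschRmsd(s, s, selection = "CA")$rmsd, 0, tolerance = 1e-12)

  moved <- rotateStructure(s, c(0.3, -1.1, 0.6), shift = c(4, -2, 9))
  fit <- kabschRmsd(s, moved, selection = "CA")
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # distorted copy: proper positive RMSD, equal to the brute-force
  # quaternion-grid minimum (independent of the SVD route)
  set.seed(12)
  a <- atoms(moved)
  a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + rnorm(24, sd = 0.3)
  dist <- AtomicStructure(a)
  fit2 <- kabschRmsd(s, dist, selection = "CA")
  expect_equal(fit2$rmsd, bruteForceRmsd(s, dist), tolerance = 1e-3)

  # missing residues are reported
  short <- AtomicStructure(atoms(s)[1:5, ])
  expect_error(kabschRmsd(s, short, selection = "CA"), "unmatched")
})

test_that("verticalExtent measures backbone span with terminal exclusion", {
  rod <- AtomicStructure(data.frame(
    elety = "CA", resid = "GLY", resno = 1:6, chain = "A",
    x = 0, y = 0, z = seq(0, 50, 10), element = "C"))
  expect_equal(verticalExtent(rod, selection = "CA"), 5)
  expect_equal(verticalExtent(rod, excludeCTerm = 1, selection = "CA"), 4)
  expect_equal(verticalExtent(rod, excludeNTerm = 2, selection = "CA"), 3)
  expect_error(verticalExtent(rod, excludeNTerm = 6, selection = "CA"),
               "excluded")
  # principal-axis convention on a tilted rod
  tilted <- rotateStructure(rod, c(0, 0.8, 0))
  expect_equal(verticalExtent(tilted, axis = "principal",
                              selection = "CA"), 5, tolerance = 1e-9)
})

test_that("tileCrystal produces translated, relabelled copies", {
  s <- toyStructure(8)
  cell <- paperCell()
  expect_identical(tileCrystal(s, cell, 1, 1), s)

  t28 <- tileCrystal(s, cell, 4, 7)
  expect_equal(nrow(atoms(t28)), 8L * 28L)
  expect_equal(length(unique(atoms(t28)$chain)), 28L)

  # adjacent copies along a differ by exactly the a vector
  t2 <- tileCrystal(s, cell, 2, 1)
  a2 <- atoms(t2)
  v <- latticeVectors(cell) * 10
  c0 <- a2[a2$chain == "A.0", c("x", "y", "z")]
  c1 <- a2[a2$chain == "A.1", c("x", "y", "z")]
  expect_equal(c1$x - c0$x, rep(v["a", 1], 8), ignore_attr = TRUE)
  expect_equal(c1$y - c0$y, rep(v["a", 2], 8), ignore_attr = TRUE)
  expect_equal(c1$z, c0$z)
})

test_that("pseudoAFM matches the dilation definition and its invariants", {
  tip <- TipModel(0.5, 8, 0.25)
  flat <- Topograph(matrix(3, 16, 16), 0.25)
  expect_equal(heights(pseudoAFM(flat, tip)), heights(flat))

  # point tip (R -> 0, theta -> 0) is the identity
  set.seed(1)
  h <- matrix(runif(20 * 20, 0, 5), 20, 20)
  expect_equal(heights(pseudoAFM(Topograph(h, 0.25),
                                 TipModel(0, 0.01, 0.25))), h)

  # single spike: spherical-cap profile h - R + sqrt(R^2 - r^2)
  hs <- matrix(0, 41, 41); hs[21, 21] <- 4
  out <- heights(pseudoAFM(Topograph(hs, 0.1), TipModel(0.5, 8, 0.1)))
  r <- 0.1 * (0:4)
  expect_equal(out[21, 21:25], 4 - 0.5 + sqrt(0.5^2 - r^2),
               tolerance = 1e-12)

  # exhaustive max-search equivalence on a random rough surface
  set.seed(8)
  rough <- matrix(runif(24 * 24, 0, 3), 24, 24)
  expect_equal(heights(pseudoAFM(Topograph(rough, 0.25), tip)),
               bruteForceDilation(rough, 0.25, tip))

  # extensive and monotone
  out1 <- heights(pseudoAFM(Topograph(rough, 0.25), tip))
  expect_true(all(out1 >= rough))
  rough2 <- rough + matrix(runif(24 * 24, 0, 1), 24, 24)
  out2 <- heights(pseudoAFM(Topograph(rough2, 0.25), tip))
  expect_true(all(out2 >= out1))

  expect_error(pseudoAFM(Topograph(matrix(numeric(0), 0, 0), 0.25), tip),
               "empty|finite|dim")
})

test_that("rasterization and tiling give a periodic pseudo-AFM image", {
  # hard-sphere envelope of a single carbon atom: top = 2 * r_vdW
  one <- AtomicStructure(data.frame(elety = "C1", resid = "LIG", resno = 1,
                                    chain = "A", x = 0, y = 0, z = 0,
                                    element = "C"))
  env <- rasterizeStructure(one, step = 0.05)
  # apex may fall between raster nodes: allow half-step sampling error
  expect_equal(max(heights(env)), 2 * 0.17, tolerance = 0.02)

  # translation periodicity along a away from the raster boundary
  unit <- AtomicStructure(data.frame(
    elety = c("C1", "N1"), resid = "LIG", resno = 1, chain = "A",
    x = c(0, 2), y = c(0, 1), z = c(0, 1), element = c("C", "N")))
  cell <- Lattice2D(2.4, 1.8, 100)        # a = 8 steps of 0.3 nm
  tiled <- tileCrystal(unit, cell, 4, 3)
  img <- pseudoAFM(tiled, TipModel(0.3, 8, 0.3))
  h <- heights(img)
  shift <- 8  # a / step
  mid <- 10:(ncol(h) - 10 - shift)
  expect_equal(h[10:(nrow(h) - 10), mid + shift],
               h[10:(nrow(h) - 10), mid], tolerance = 1e-9)
})

test_that("depthContours yields closed-form and nested level sets", {
  px <- 0.05; n <- 201
  xs <- ((1:n) - 101) * px
  d2 <- outer(xs^2, xs^2, `+`)
  hemi <- Topograph(ifelse(d2 <= 9, sqrt(pmax(9 - d2, 0)), 0), px)
  cs <- depthContours(hemi, depths = c(0.5, 1, 2))
  # circle radii sqrt(R^2 - (R - d)^2) at R = 3
  for (k in 1:3) {
    d <- c(0.5, 1, 2)[k]
    poly <- cs@contours[[k]][[1]]
    rad <- sqrt((poly$x - 100 * px)^2 + (poly$y - 100 * px)^2)
    expect_equal(mean(rad), sqrt(9 - (3 - d)^2), tolerance = 0.02)
    expect_lt(diff(range(rad)), 0.05)
  }
  # nested levels -> nested contours for a unimodal surface
  r1 <- sqrt((cs@contours[[1]][[1]]$x - 5)^2 +
               (cs@contours[[1]][[1]]$y - 5)^2)
  r2 <- sqrt((cs@contours[[2]][[1]]$x - 5)^2 +
               (cs@contours[[2]][[1]]$y - 5)^2)
  expect_lt(max(r1), min(r2))

  # unreachable depth flagged as empty
  cs2 <- depthContours(hemi, depths = c(1, 5))
  expect_equal(length(cs2@contours[[2]]), 0L)
  expect_equal(attr(cs2, "unreachable"), 5)
  expect_error(depthContours(Topograph(matrix(1, 8, 8), 1)), "constant")
})
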