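## Ground-truthed synthetic HS-AFM movie generator.
##
## The generator emulates the assembly of a membrane-bound aegerolysin into
## striped 2D crystals: stripes of dimer slots on a monoclinic lattice grow
## and shrink at their ends by whole dimers (slot pitch a/3), new stripes
## nucleate on adjacent lattice rows (transversal growth), and each frame is
## rendered as a height map with mica / bilayer / protein layering, tip blur
## and pixel noise. Every stochastic event is logged so that downstream
## estimators can be scored against exact ground truth.

# Physical centre (nm) of dimer slot s on lattice row r.
slotCentre <- function(lattice, s, r) {
  v <- latticeVectors(lattice)
  cbind(lattice@origin[1] + (s + 0.5) / 3 * v["a", 1] + r * v["b", 1],
        lattice@origin[2] + (s + 0.5) / 3 * v["a", 2] + r * v["b", 2])
}

# Contiguous range of slots on row r whose centres keep >= margin nm of
# membrane around them. c(-Inf, Inf) when the mask is unbounded.
allowedSlotRange <- function(lattice, layers, r, margin = 2) {
  if (is.null(layers) || layers@membraneMask$shape == "full")
    return(c(-Inf, Inf))
  mask <- layers@membraneMask
  # generous slot window from the mask extent
  ext <- switch(mask$shape,
    disc = c(mask$centre - mask$radius, mask$centre + mask$radius),
    rect = c(mask$xmin, mask$ymin, mask$xmax, mask$ymax))
  span <- sqrt((ext[3] - ext[1])^2 + (ext[4] - ext[2])^2) +
    sqrt(sum((lattice@origin - ext[1:2])^2)) + abs(r) * lattice@bLen
  nmax <- ceiling(span / (lattice@aLen / 3)) + 3
  s <- seq(-nmax, nmax)
  ctr <- slotCentre(lattice, s, r)
  ok <- maskBoundaryDistance(mask, ctr[, 1], ctr[, 2]) >= margin
  if (!any(ok)) return(NULL)
  # largest contiguous allowed run (masks here are convex, so unique)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  i <- which(runs$values)[which.max(runs$lengths[runs$values])]
  c(s[ends[i] - runs$lengths[i] + 1], s[ends[i]])
}

#' Simulate dimer-wise stripe growth on a 2D lattice
#'
#' Kinetic Monte-Carlo growth of crystal stripes: per frame and stripe end,
#' Poisson-distributed numbers of dimer associations (mean `kAssoc`) and
#' dissociations (mean `kDissoc`, amplified by `edgeInstabilityFactor` for
#' stripes whose centroid lies within `edgeBand` nm of the membrane-mask
#' boundary) change the occupied slot range; longitudinal growth is fast,
#' transversal growth happens only through nucleation of new single-dimer
#' stripes on rows adjacent to an existing stripe (probability `kNucleate`
#' per frame). Stripes never merge: growth is clamped one empty slot short
#' of a same-row neighbour and to the membrane patch.
#'
#' Every applied event is logged with the frame it creates, the stripe id,
#' the end (`plus`/`minus`/`new`), the slot count and the length change in
#' nm (slots times a/3). Clamped draws are logged at their applied size, so
#' the log satisfies exact conservation: final length = initial length +
#' sum(assoc) - sum(dissoc) per stripe.
#'
#' @param lattice a [Lattice2D-class].
#' @param growth a [GrowthParams-class].
#' @param nFrames number of frames (>= 1); frame 1 is the initial state.
#' @param seed integer seed (NA: use the current RNG stream).
#' @param init data.frame(id, row, slotMin, slotMax) initial stripes;
#'   default one 5-slot stripe on row 0.
#' @param layers optional [LayerModel-class]; when given, growth is confined
#'   to the membrane patch and edge instability is active.
#' @param edgeBand distance (nm) from the mask boundary within which
#'   dissociation is amplified.
#' @param deterministic logical; draw `round(k)` events instead of Poisson
#'   (for closed-form checks).
#' @param activeEnds which stripe ends exchange dimers:
#'   "both", "plus" or "minus".
#' @param maskMargin margin (nm) kept between slot centres and the mask
#'   boundary.
#' @return An [OccupancyMovie-class] with the per-frame stripe table and the
#'   ground-truth event log.
#' @examples
#' cell <- Lattice2D(10.8, 6.6, 100)
#' mov <- simulateGrowth(cell, GrowthParams(kDissoc = 0, kNucleate = 0),
#'                       nFrames = 5, seed = 1)
#' eventLog(mov)
#' @export
simulateGrowth <- function(lattice, growth, nFrames, seed = NA_integer_,
                           init = NULL, layers = NULL, edgeBand = 5,
                           deterministic = FALSE,
                           activeEnds = c("both", "plus", "minus"),
                           maskMargin = 2) {
  stopifnot(is(lattice, "Lattice2D"), is(growth, "GrowthParams"),
            nFrames >= 1)
  activeEnds <- match.arg(activeEnds)
  if (is.null(init))
    init <- data.frame(id = 1L, row = 0L, slotMin = -2L, slotMax = 2L)
  stopifnot(all(init$slotMax >= init$slotMin))
  pitch <- lattice@aLen / 3

  withLocalSeed(seed, {
    state <- init
    state$id <- as.integer(state$id)
    nextId <- max(state$id) + 1L
    frames <- vector("list", nFrames)
    frames[[1]] <- state
    log <- list()
    nlog <- 0L
    addEvent <- function(frame, id, event, end, slots) {
      nlog <<- nlog + 1L
      log[[nlog]] <<- data.frame(frame = frame, stripe_id = id,
                                 event = event, end = end,
                                 slots = slots, length_nm = slots * pitch,
                                 stringsAsFactors = FALSE)
    }
    drawCount <- function(k) {
      if (deterministic) as.integer(round(k)) else stats::rpois(1L, k)
    }
    rangeCache <- new.env(parent = emptyenv())
    allowed <- function(r) {
      key <- as.character(r)
      if (is.null(rangeCache[[key]]))
        rangeCache[[key]] <- allowedSlotRange(lattice, layers, r, maskMargin)
      rangeCache[[key]]
    }

    if (nFrames > 1) for (f in 2:nFrames) {
      keep <- rep(TRUE, nrow(state))
      for (i in seq_len(nrow(state))) {
        st <- state[i, ]
        arange <- allowed(st$row)
        kD <- growth@kDissoc
        if (!is.null(layers) && growth@edgeInstabilityFactor > 1) {
          ctr <- slotCentre(lattice, (st$slotMin + st$slotMax) / 2, st$row)
          if (maskBoundaryDistance(layers@membraneMask,
                                   ctr[1], ctr[2]) <= edgeBand)
            kD <- kD * growth@edgeInstabilityFactor
        }
        ends <- switch(activeEnds, both = c("plus", "minus"),
                       plus = "plus", minus = "minus")
        for (end in ends) {
          # net end displacement this frame: associations minus
          # dissociations; only the net is observable between frames, so
          # only the net is logged (one event per end per frame)
          net <- drawCount(growth@kAssoc) - drawCount(kD)
          if (net > 0L) {
            # growth clamped to the membrane patch and one empty slot
            # short of same-row neighbours (stripes never merge)
            if (end == "plus") {
              lim <- if (is.null(arange)) st$slotMax else arange[2]
              others <- state$slotMin[keep & state$row == st$row &
                                        state$id != st$id &
                                        state$slotMin > st$slotMax]
              if (length(others)) lim <- min(lim, min(others) - 2)
              applied <- max(0L, as.integer(min(net, lim - st$slotMax)))
              st$slotMax <- st$slotMax + applied
            } else {
              lim <- if (is.null(arange)) st$slotMin else arange[1]
              others <- state$slotMax[keep & state$row == st$row &
                                        state$id != st$id &
                                        state$slotMax < st$slotMin]
              if (length(others)) lim <- max(lim, max(others) + 2)
              applied <- max(0L, as.integer(min(net, st$slotMin - lim)))
              st$slotMin <- st$slotMin - applied
            }
            if (applied > 0L) addEvent(f, st$id, "assoc", end, applied)
          } else if (net < 0L) {
            # shrinkage clamped by the current stripe length
            len <- st$slotMax - st$slotMin + 1L
            applied <- as.integer(min(-net, len))
            if (end == "plus") st$slotMax <- st$slotMax - applied
            else st$slotMin <- st$slotMin + applied
            if (applied > 0L) addEvent(f, st$id, "dissoc", end, applied)
            if (applied >= len) { keep[i] <- FALSE; break }
          }
        }
        state[i, ] <- st
      }
      state <- state[keep, , drop = FALSE]

      # transversal growth: nucleation next to an existing stripe
      if (nrow(state) > 0 && stats::runif(1) < growth@kNucleate) {
        pi_ <- sample.int(nrow(state), 1L)
        parent <- state[pi_, ]
        newRow <- parent$row + sample(c(-1L, 1L), 1L)
        slot <- if (parent$slotMin == parent$slotMax) parent$slotMin else
          sample(parent$slotMin:parent$slotMax, 1L)
        arange <- allowed(newRow)
        okMask <- !is.null(arange) &&
          (is.infinite(arange[1]) || (slot >= arange[1] && slot <= arange[2]))
        sameRow <- state[state$row == newRow, , drop = FALSE]
        okGap <- !any(slot >= sameRow$slotMin - 1L &
                        slot <= sameRow$slotMax + 1L)
        if (okMask && okGap) {
          state <- rbind(state, data.frame(id = nextId, row = newRow,
                                           slotMin = slot, slotMax = slot))
          addEvent(f, nextId, "nucleate", "new", 1L)
          nextId <- nextId + 1L
        }
      }
      rownames(state) <- NULL
      frames[[f]] <- state
    }

    eventLog <- if (nlog > 0L) do.call(rbind, log[seq_len(nlog)]) else
      data.frame(frame = integer(), stripe_id = integer(),
                 event = character(), end = character(), slots = integer(),
                 length_nm = numeric(), stringsAsFactors = FALSE)
    new("OccupancyMovie", frames = frames, lattice = lattice,
        eventLog = eventLog, frameInterval = growth@frameInterval)
  })
}

#' Render one occupancy frame as an AFM height map
#'
#' Forward model of an HS-AFM frame: mica at 0, the membrane patch at
#' `membraneThickness`, and one flat-topped elliptical protrusion of height
#' `protrusionHeight` above the membrane per occupied dimer slot (the EF
#' dimer lowered by `efAlternateDrop` in alternate repeat units, staggered
#' between rows). The ideal surface is then blurred with a Gaussian of
#' `tipBlurSigma` and corrupted by i.i.d. Gaussian pixel noise of
#' `noiseSigma`; both are skipped when zero. Rendering is deterministic for
#' a fixed `seed` in `scan`.
#'
#' Occupied slots whose centre lies outside the membrane patch are rejected:
#' the protein binds the membrane only, never bare mica.
#'
#' @param occupancy data.frame(id, row, slotMin, slotMax), e.g. one element
#'   of an [OccupancyMovie-class]; may have zero rows.
#' @param template a [RepeatUnitTemplate-class].
#' @param layers a [LayerModel-class].
#' @param lattice a [Lattice2D-class].
#' @param scan a [ScanParams-class].
#' @param timestamp frame time (s) stored in the result.
#' @return A [Topograph-class].
#' @examples
#' cell <- Lattice2D(10.8, 6.6, 100)
#' occ <- data.frame(id = 1, row = 0, slotMin = 0, slotMax = 5)
#' layers <- LayerModel(membraneMask = list(shape = "full"))
#' lat <- Lattice2D(10.8, 6.6, 100, origin = c(10, 30))
#' topo <- renderTopograph(occ, RepeatUnitTemplate(), layers, lat,
#'                         ScanParams(imageShape = c(128L, 128L),
#'                                    tipBlurSigma = 0, noiseSigma = 0))
#' @export
renderTopograph <- function(occupancy, template, layers, lattice, scan,
                            timestamp = NA_real_) {
  stopifnot(is(template, "RepeatUnitTemplate"), is(layers, "LayerModel"),
            is(lattice, "Lattice2D"), is(scan, "ScanParams"))
  nr <- scan@imageShape[1]; nc <- scan@imageShape[2]
  px <- scan@pixelSize
  mask <- maskRaster(layers@membraneMask, c(nr, nc), px)
  h <- matrix(layers@micaLevel, nr, nc)
  h[mask] <- layers@membraneThickness

  if (nrow(occupancy) > 0) {
    v <- latticeVectors(lattice)
    fp <- template@footprints
    top <- layers@membraneThickness + template@protrusionHeight
    for (i in seq_len(nrow(occupancy))) {
      st <- occupancy[i, ]
      slots <- st$slotMin:st$slotMax
      ctr <- slotCentre(lattice, slots, st$row)
      if (!all(pointInMask(layers@membraneMask, ctr[, 1], ctr[, 2])))
        stop("occupied lattice site outside the membrane patch ",
             "(stripe id ", st$id, "): the protein binds the membrane only")
      for (s in slots) {
        k <- (s %% 3L) + 1L              # dimer within the repeat unit
        u <- s %/% 3L                    # repeat unit index
        f <- fp[k, ]
        cx <- lattice@origin[1] + (u + f$aFrac) * v["a", 1] +
          (st$row + f$bFrac) * v["b", 1]
        cy <- lattice@origin[2] + (u + f$aFrac) * v["a", 2] +
          (st$row + f$bFrac) * v["b", 2]
        drop <- 0
        if (f$dimer == "EF" && template@efAlternateDrop > 0 &&
            ((u + st$row * template@rowStagger + template@efDropPhase)
             %% 2L) == 1L)
          drop <- template@efAlternateDrop
        lvl <- top - drop
        # fill the ellipse on the local pixel bounding box
        phi <- degToRad(lattice@orientation + f$angle)
        hs <- f$major / 2
        j0 <- max(1L, floor((cx - hs) / px) + 1L)
        j1 <- min(nc, ceiling((cx + hs) / px) + 1L)
        i0 <- max(1L, floor((cy - hs) / px) + 1L)
        i1 <- min(nr, ceiling((cy + hs) / px) + 1L)
        if (j0 > j1 || i0 > i1) next
        jj <- j0:j1; ii <- i0:i1
        dx <- outer(rep(1, length(ii)), (jj - 1) * px - cx)
        dy <- outer((ii - 1) * px - cy, rep(1, length(jj)))
        lx <- (dx * cos(phi) + dy * sin(phi)) / (f$major / 2)
        ly <- (-dx * sin(phi) + dy * cos(phi)) / (f$minor / 2)
        inside <- lx * lx + ly * ly <= 1
        blk <- h[ii, jj, drop = FALSE]
        blk[inside] <- pmax(blk[inside], lvl)
        h[ii, jj] <- blk
      }
    }
  }

  if (scan@tipBlurSigma > 0)
    h <- EBImage::gblur(h, sigma = scan@tipBlurSigma / px)
  if (scan@noiseSigma > 0)
    h <- withLocalSeed(scan@seed,
      h + matrix(stats::rnorm(nr * nc, sd = scan@noiseSigma), nr, nc))
  Topograph(h, px, timestamp)
}

#' Default configuration for a synthetic assembly movie
#'
#' A 128 x 128 nm field of view (256 x 256 px at 0.5 nm/px) holding a
#' 52 nm-radius membrane disc, three seed stripes near the patch centre, a
#' 2 s frame interval, association/dissociation means of 4 and 1.5 dimers
#' per stripe end per frame with four-fold edge amplification, 0.5 nm tip
#' blur and 0.1 nm pixel noise.
#'
#' @param nFrames number of frames.
#' @param seed integer seed used for both growth and noise.
#' @return A named list understood by [generateMovie()].
#' @export
demoConfig <- function(nFrames = 20L, seed = 1L) {
  list(
    lattice = Lattice2D(10.8, 6.6, 100, orientation = 0,
                        origin = c(64, 64)),
    template = RepeatUnitTemplate(),
    layers = LayerModel(membraneThickness = 7, proteinHeight = 5,
                        membraneMask = list(shape = "disc",
                                            centre = c(64, 64),
                                            radius = 52)),
    growth = GrowthParams(kAssoc = 4, kDissoc = 1.5, kNucleate = 0.05,
                          edgeInstabilityFactor = 4, frameInterval = 2),
    scan = ScanParams(pixelSize = 0.5, imageShape = c(256L, 256L),
                      tipBlurSigma = 0.5, noiseSigma = 0.1, seed = seed),
    init = data.frame(id = 1:3, row = c(-1L, 0L, 1L),
                      slotMin = c(-4L, -6L, -2L), slotMax = c(2L, 5L, 3L)),
    nFrames = as.integer(nFrames),
    edgeBand = 8,
    seed = as.integer(seed))
}

#' Generate a complete synthetic HS-AFM movie with ground truth
#'
#' Composes [simulateGrowth()] and [renderTopograph()]: simulates the
#' stripe-growth trajectory, renders every frame (per-frame independent
#' noise), and returns the image stack together with the ground-truth
#' occupancy movie and event log. The whole generation is driven by the
#' single seed in `config`, so a fixed configuration reproduces the stack
#' bit for bit.
#'
#' @param config list as produced by [demoConfig()]: fields `lattice`,
#'   `template`, `layers`, `growth`, `scan`, `init`, `nFrames`, `edgeBand`,
#'   `seed`.
#' @return list with elements `stack` ([TopographStack-class]), `occupancy`
#'   ([OccupancyMovie-class]) and `eventLog` (data.frame).
#' @examples
#' mov <- generateMovie(demoConfig(nFrames = 3L, seed = 7L))
#' mov$stack
#' @export
generateMovie <- function(config) {
  stopifnot(is.list(config), config$nFrames >= 1)
  seed <- if (is.null(config$seed)) NA_integer_ else as.integer(config$seed)
  withLocalSeed(seed, {
    occ <- simulateGrowth(config$lattice, config$growth, config$nFrames,
                          seed = NA_integer_, init = config$init,
                          layers = config$layers,
                          edgeBand = if (is.null(config$edgeBand)) 5 else
                            config$edgeBand)
    scan <- config$scan
    scan@seed <- NA_integer_   # noise drawn from the seeded stream
    dt <- config$growth@frameInterval
    frames <- lapply(seq_len(config$nFrames), function(f)
      renderTopograph(getFrame(occ, f), config$template, config$layers,
                      config$lattice, scan, timestamp = (f - 1) * dt))
    list(stack = TopographStack(frames, metadata = list(config = config)),
         occupancy = occ, eventLog = eventLog(occ))
  })
}
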