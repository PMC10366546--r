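#' @import methods
NULL

## ---------------------------------------------------------------------------
## Imaging containers
## ---------------------------------------------------------------------------

#' Topograph: a single AFM height map
#'
#' A `Topograph` holds one two-dimensional height map in nanometres on a
#' square pixel grid, together with the physical pixel size and an optional
#' acquisition timestamp. It is the universal image currency of the package:
#' every analysis stage consumes and/or produces `Topograph` objects.
#'
#' The coordinate convention is image-style: the origin is the centre of the
#' top-left pixel, x runs rightward along columns, y downward along rows, and
#' pixel indices are 0-based in physical coordinates (`x = (col - 1) *
#' pixelSize` for R's 1-based column `col`). Heights are in nm with the mica
#' support at 0.
#'
#' @slot heights numeric matrix of heights (nm), rows = y, columns = x.
#' @slot pixelSize pixel edge length in nm/px.
#' @slot timestamp acquisition time in seconds (NA if unknown).
#'
#' @exportClass Topograph
setClass("Topograph",
  representation(heights = "matrix", pixelSize = "numeric",
                 timestamp = "numeric"),
  prototype(pixelSize = 1, timestamp = NA_real_),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@heights))
      msg <- c(msg, "heights must be a numeric matrix")
    if (any(!is.finite(object@heights)))
      msg <- c(msg, "heights must be finite")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a Topograph
#'
#' @param heights numeric matrix of heights in nm.
#' @param pixelSize pixel size in nm/px.
#' @param timestamp frame time in seconds.
#' @return A [Topograph-class] object.
#' @examples
#' topo <- Topograph(matrix(7, 16, 16), pixelSize = 0.5)
#' pixelSize(topo)
#' @export
Topograph <- function(heights, pixelSize = 1, timestamp = NA_real_) {
  new("Topograph", heights = heights, pixelSize = as.numeric(pixelSize),
      timestamp = as.numeric(timestamp))
}

#' TopographStack: a time-ordered HS-AFM movie
#'
#' Frames share one pixel grid; timestamps are per frame in seconds.
#'
#' @slot frames list of numeric height matrices (nm), identical dimensions.
#' @slot pixelSize nm/px shared by all frames.
#' @slot timestamps numeric vector, seconds, one per frame.
#' @slot metadata free-form list (generator config, provenance, ...).
#'
#' @exportClass TopographStack
setClass("TopographStack",
  representation(frames = "list", pixelSize = "numeric",
                 timestamps = "numeric", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    msg <- NULL
    if (length(object@frames) == 0L)
      msg <- c(msg, "stack must contain at least one frame")
    dims <- unique(lapply(object@frames, dim))
    if (length(dims) > 1L)
      msg <- c(msg, "all frames must share the same dimensions")
    if (length(object@timestamps) != length(object@frames))
      msg <- c(msg, "one timestamp per frame required")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a TopographStack
#'
#' @param frames list of height matrices (nm) or of [Topograph-class] objects.
#' @param pixelSize nm/px (taken from the first Topograph if omitted).
#' @param timestamps seconds, one per frame; defaults to 0, 1, 2, ...
#' @param metadata optional list of provenance information.
#' @return A [TopographStack-class] object.
#' @export
TopographStack <- function(frames, pixelSize = NULL, timestamps = NULL,
                           metadata = list()) {
  if (length(frames) && is(frames[[1L]], "Topograph")) {
    if (is.null(pixelSize)) pixelSize <- frames[[1L]]@pixelSize
    if (is.null(timestamps))
      timestamps <- vapply(frames, slot, numeric(1), "timestamp")
    frames <- lapply(frames, slot, "heights")
  }
  if (is.null(pixelSize)) pixelSize <- 1
  if (is.null(timestamps) || all(is.na(timestamps)))
    timestamps <- seq_along(frames) - 1
  new("TopographStack", frames = frames, pixelSize = as.numeric(pixelSize),
      timestamps = as.numeric(timestamps), metadata = metadata)
}

## ---------------------------------------------------------------------------
## Lattice geometry and repeat-unit model
## ---------------------------------------------------------------------------

#' Lattice2D: a primitive 2D (monoclinic) unit cell
#'
#' Describes the two lattice vectors of a 2D crystal by their lengths `a`,
#' `b` (nm), the interaxial angle gamma (degrees), the in-plane orientation
#' of vector a relative to the image x-axis (degrees, y downward), and the
#' lattice origin (nm). Fitted cells follow the crystallographic convention
#' of this system: a >= b and gamma reported by its obtuse representative
#' when one exists.
#'
#' @slot aLen length of lattice vector a, nm.
#' @slot bLen length of lattice vector b, nm.
#' @slot gamma interaxial angle, degrees, in (0, 180).
#' @slot orientation angle of a in the image frame, degrees.
#' @slot origin numeric(2), lattice origin (x, y) in nm.
#'
#' @exportClass Lattice2D
setClass("Lattice2D",
  representation(aLen = "numeric", bLen = "numeric", gamma = "numeric",
                 orientation = "numeric", origin = "numeric"),
  prototype(orientation = 0, origin = c(0, 0)),
  validity = function(object) {
    msg <- NULL
    if (object@aLen <= 0 || object@bLen <= 0)
      msg <- c(msg, "lattice vector lengths must be positive")
    if (object@gamma <= 0 || object@gamma >= 180)
      msg <- c(msg, "gamma must lie strictly between 0 and 180 degrees")
    if (length(object@origin) != 2L)
      msg <- c(msg, "origin must be a length-2 numeric")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a Lattice2D
#'
#' @param aLen,bLen lattice vector lengths in nm.
#' @param gamma interaxial angle in degrees (0, 180).
#' @param orientation angle of vector a relative to the image x-axis, degrees.
#' @param origin lattice origin (x, y) in nm.
#' @return A [Lattice2D-class] object.
#' @examples
#' cell <- Lattice2D(10.8, 6.6, 100)
#' latticeVectors(cell)
#' @export
Lattice2D <- function(aLen, bLen, gamma = 90, orientation = 0,
                      origin = c(0, 0)) {
  new("Lattice2D", aLen = as.numeric(aLen), bLen = as.numeric(bLen),
      gamma = as.numeric(gamma), orientation = as.numeric(orientation),
      origin = as.numeric(origin))
}

#' RepeatUnitTemplate: footprints of the three dimers in one unit cell
#'
#' The hexameric repeat unit of the crystal holds three protein dimers per
#' unit cell, laid out along lattice vector a: two "head" dimers (AB, CD)
#' forming an almost circular tetramer and one "neck" dimer (EF) with a
#' distinctly narrower, differently oriented footprint. Each footprint is a
#' flat-topped elliptical protrusion above the membrane. In alternate repeat
#' units along a stripe the EF dimer sits lower by `efAlternateDrop`,
#' producing a long-range height modulation along the stripes.
#'
#' @slot footprints data.frame with one row per dimer: `dimer` (label),
#'   `aFrac`, `bFrac` (centre offsets in lattice fractional coordinates),
#'   `major`, `minor` (full ellipse axes, nm), `angle` (degrees of the major
#'   axis relative to lattice vector a).
#' @slot protrusionHeight protrusion top above the membrane surface, nm.
#' @slot efAlternateDrop lowering of the EF dimer in alternate repeat
#'   units, nm (>= 0).
#' @slot efDropPhase integer parity convention (0 or 1): which repeat units
#'   carry the lowered EF.
#' @slot rowStagger integer stagger (in repeat units) of the EF-drop phase
#'   between adjacent stripes.
#'
#' @exportClass RepeatUnitTemplate
setClass("RepeatUnitTemplate",
  representation(footprints = "data.frame", protrusionHeight = "numeric",
                 efAlternateDrop = "numeric", efDropPhase = "integer",
                 rowStagger = "integer"),
  validity = function(object) {
    msg <- NULL
    need <- c("dimer", "aFrac", "bFrac", "major", "minor", "angle")
    if (!all(need %in% names(object@footprints)))
      msg <- c(msg, paste("footprints needs columns:",
                          paste(need, collapse = ", ")))
    if (object@efAlternateDrop < 0)
      msg <- c(msg, "efAlternateDrop must be >= 0")
    if (object@protrusionHeight <= 0)
      msg <- c(msg, "protrusionHeight must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a RepeatUnitTemplate
#'
#' Defaults encode the observed repeat-unit morphology: head dimers AB and
#' CD with 5.1 x 3.0 nm footprints whose major axes lie across the stripe,
#' and a neck dimer EF with a narrower 5.1 x 2.4 nm footprint tilted by 20
#' degrees off the stripe normal, protruding 5 nm above the membrane; EF
#' drops by 0.15 nm in alternate repeat units and sits offset by 0.15 b
#' off the stripe centre line, as the neck does in high-resolution frames.
#' Footprint widths leave sub-nanometre grooves between neighbouring
#' dimers, so individual dimer protrusions are resolved in line profiles.
#'
#' @param footprints data.frame as described in [RepeatUnitTemplate-class];
#'   defaults to the AB/CD/EF layout above.
#' @param protrusionHeight nm above the membrane.
#' @param efAlternateDrop nm lowering of EF in alternate repeat units.
#' @param efDropPhase parity (0/1) selecting which units carry the drop.
#' @param rowStagger phase stagger between adjacent stripes, repeat units.
#' @return A [RepeatUnitTemplate-class] object.
#' @export
RepeatUnitTemplate <- function(footprints = NULL, protrusionHeight = 5,
                               efAlternateDrop = 0.15, efDropPhase = 0L,
                               rowStagger = 1L) {
  if (is.null(footprints)) {
    footprints <- data.frame(
      dimer = c("AB", "CD", "EF"),
      aFrac = c(1 / 6, 3 / 6, 5 / 6),
      bFrac = c(0, 0, 0.15),
      major = c(5.1, 5.1, 5.1),
      minor = c(3.0, 3.0, 2.4),
      angle = c(90, 90, 70),
      stringsAsFactors = FALSE)
  }
  new("RepeatUnitTemplate", footprints = footprints,
      protrusionHeight = as.numeric(protrusionHeight),
      efAlternateDrop = as.numeric(efAlternateDrop),
      efDropPhase = as.integer(efDropPhase),
      rowStagger = as.integer(rowStagger))
}

#' LayerModel: mica, membrane and protein layer heights
#'
#' Vertical layering of the synthetic scene: the mica support defines height
#' zero; a supported lipid bilayer patch sits `membraneThickness` above it
#' (7 nm for the rigid ceramide-phosphoethanolamine/cholesterol bilayer
#' emulated here) and the adsorbed protein layer adds about `proteinHeight`
#' (~5 nm monomer height). The lateral extent of the membrane patch is given
#' by `membraneMask`.
#'
#' @slot micaLevel reference level, nm (0 by convention).
#' @slot membraneThickness bilayer top above mica, nm.
#' @slot proteinHeight nominal protein layer thickness, nm.
#' @slot membraneMask list describing the patch geometry: either
#'   `list(shape = "full")` (membrane everywhere), `list(shape = "disc",
#'   centre = c(x, y), radius = r)` or `list(shape = "rect", xmin, xmax,
#'   ymin, ymax)`, all in nm.
#'
#' @exportClass LayerModel
setClass("LayerModel",
  representation(micaLevel = "numeric", membraneThickness = "numeric",
                 proteinHeight = "numeric", membraneMask = "list"),
  validity = function(object) {
    msg <- NULL
    if (object@membraneThickness <= 0)
      msg <- c(msg, "membraneThickness must be positive")
    if (object@proteinHeight <= 0)
      msg <- c(msg, "proteinHeight must be positive")
    if (!object@membraneMask$shape %in% c("full", "disc", "rect"))
      msg <- c(msg, "membraneMask$shape must be 'full', 'disc' or 'rect'")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a LayerModel
#'
#' @param membraneThickness bilayer top above mica, nm.
#' @param proteinHeight protein layer thickness, nm.
#' @param membraneMask patch geometry list, see [LayerModel-class].
#' @param micaLevel reference level, nm.
#' @return A [LayerModel-class] object.
#' @export
LayerModel <- function(membraneThickness = 7, proteinHeight = 5,
                       membraneMask = list(shape = "full"), micaLevel = 0) {
  new("LayerModel", micaLevel = as.numeric(micaLevel),
      membraneThickness = as.numeric(membraneThickness),
      proteinHeight = as.numeric(proteinHeight),
      membraneMask = membraneMask)
}

#' GrowthParams: kinetic rates of dimer-wise stripe growth
#'
#' Crystal stripes grow and shrink at their two ends by integer numbers of
#' dimer slots (slot pitch a/3 along the stripe). Association and
#' dissociation counts per stripe end per frame are Poisson with means
#' `kAssoc` and `kDissoc`; near the membrane edge `kDissoc` is amplified by
#' `edgeInstabilityFactor`, reproducing the transient, easily dissociating
#' stripes observed there. Transversal growth happens only by nucleation of
#' new stripes on rows adjacent to existing ones, with probability
#' `kNucleate` per frame.
#'
#' @slot kAssoc mean dimer association events per stripe end per frame.
#' @slot kDissoc mean dimer dissociation events per stripe end per frame.
#' @slot kNucleate probability of one new-stripe nucleation per frame.
#' @slot edgeInstabilityFactor multiplier (>= 1) on `kDissoc` near the
#'   membrane edge.
#' @slot frameInterval seconds between frames.
#'
#' @exportClass GrowthParams
setClass("GrowthParams",
  representation(kAssoc = "numeric", kDissoc = "numeric",
                 kNucleate = "numeric", edgeInstabilityFactor = "numeric",
                 frameInterval = "numeric"),
  validity = function(object) {
    msg <- NULL
    rates <- c(object@kAssoc, object@kDissoc, object@kNucleate)
    if (any(!is.finite(rates)) || any(rates < 0))
      msg <- c(msg, "rates must be finite and >= 0")
    if (!is.finite(object@edgeInstabilityFactor) ||
        object@edgeInstabilityFactor < 1)
      msg <- c(msg, "edgeInstabilityFactor must be >= 1")
    if (object@frameInterval <= 0)
      msg <- c(msg, "frameInterval must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Construct GrowthParams
#'
#' @param kAssoc,kDissoc mean association/dissociation events per stripe end
#'   per frame.
#' @param kNucleate new-stripe nucleation probability per frame.
#' @param edgeInstabilityFactor multiplier on `kDissoc` near the membrane
#'   edge (>= 1).
#' @param frameInterval seconds per frame.
#' @return A [GrowthParams-class] object.
#' @export
GrowthParams <- function(kAssoc = 4, kDissoc = 1.5, kNucleate = 0.05,
                         edgeInstabilityFactor = 4, frameInterval = 2) {
  new("GrowthParams", kAssoc = as.numeric(kAssoc),
      kDissoc = as.numeric(kDissoc), kNucleate = as.numeric(kNucleate),
      edgeInstabilityFactor = as.numeric(edgeInstabilityFactor),
      frameInterval = as.numeric(frameInterval))
}

#' ScanParams: instrument-response parameters of the synthetic scan
#'
#' @slot pixelSize nm/px.
#' @slot imageShape integer(2), rows x cols.
#' @slot tipBlurSigma Gaussian blur emulating finite tip sharpness, nm.
#' @slot noiseSigma additive zero-mean Gaussian pixel noise, nm.
#' @slot seed integer RNG seed for the noise (NA: use current RNG stream).
#'
#' @exportClass ScanParams
setClass("ScanParams",
  representation(pixelSize = "numeric", imageShape = "integer",
                 tipBlurSigma = "numeric", noiseSigma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be positive")
    if (length(object@imageShape) != 2L || any(object@imageShape < 4L))
      msg <- c(msg, "imageShape must be two integers >= 4")
    if (object@tipBlurSigma < 0 || object@noiseSigma < 0)
      msg <- c(msg, "sigmas must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct ScanParams
#'
#' Defaults (0.5 nm/px, 256 x 256, 0.5 nm blur, 0.1 nm noise) resolve the
#' ~6.5 nm stripe pitch with more than 10 pixels per period.
#'
#' @param pixelSize nm/px.
#' @param imageShape rows x cols.
#' @param tipBlurSigma nm.
#' @param noiseSigma nm.
#' @param seed integer seed, or NA to draw from the current RNG stream.
#' @return A [ScanParams-class] object.
#' @export
ScanParams <- function(pixelSize = 0.5, imageShape = c(256L, 256L),
                       tipBlurSigma = 0.5, noiseSigma = 0.1,
                       seed = NA_integer_) {
  new("ScanParams", pixelSize = as.numeric(pixelSize),
      imageShape = as.integer(imageShape),
      tipBlurSigma = as.numeric(tipBlurSigma),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' OccupancyMovie: ground-truth lattice occupancy of a simulated movie
#'
#' Per-frame decomposition of the crystal into stripes: each stripe lives on
#' one lattice row (integer multiple of vector b) and occupies a contiguous
#' range of dimer slots along a (slot pitch a/3, i.e. three dimers per unit
#' cell). The event log records every association, dissociation and
#' nucleation with its frame, stripe, slot count and length change.
#'
#' @slot frames list (one per frame) of data.frames with columns `id`,
#'   `row`, `slotMin`, `slotMax`.
#' @slot lattice the generating [Lattice2D-class].
#' @slot eventLog data.frame with columns `frame`, `stripe_id`, `event`
#'   (assoc/dissoc/nucleate), `end` (plus/minus/new), `slots`, `length_nm`.
#' @slot frameInterval seconds between frames.
#'
#' @exportClass OccupancyMovie
setClass("OccupancyMovie",
  representation(frames = "list", lattice = "Lattice2D",
                 eventLog = "data.frame", frameInterval = "numeric"),
  validity = function(object) {
    msg <- NULL
    ok <- vapply(object@frames, function(f)
      all(c("id", "row", "slotMin", "slotMax") %in% names(f)) &&
        all(f$slotMax >= f$slotMin), logical(1))
    if (!all(ok))
      msg <- c(msg, "each frame needs id/row/slotMin/slotMax with contiguous, non-empty slot ranges")
    if (is.null(msg)) TRUE else msg
  })

#' StabilityMaps: per-pixel mean and SD over a frame range
#'
#' @slot mean mean height map, a [Topograph-class].
#' @slot sd population standard deviation map, a [Topograph-class].
#' @slot frameRange integer(2), first and last frame used (1-based).
#' @slot duration time spanned by the range, seconds.
#'
#' @exportClass StabilityMaps
setClass("StabilityMaps",
  representation(mean = "Topograph", sd = "Topograph",
                 frameRange = "integer", duration = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@sd@heights < -1e-12))
      msg <- c(msg, "sd map must be non-negative")
    if (!identical(dim(object@mean@heights), dim(object@sd@heights)))
      msg <- c(msg, "mean and sd maps must share shape")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Structure-based tools
## ---------------------------------------------------------------------------

#' AtomicStructure: atoms of a PDB entry
#'
#' Thin container around an atom table in PDB conventions: coordinates in
#' Angstroms, one row per atom with element, atom name, residue name/number
#' and chain id. Chain ids are plain strings so that crystal tiling can
#' relabel copies without exhausting the one-letter PDB namespace.
#'
#' @slot atoms data.frame with columns `eleno`, `elety` (atom name),
#'   `resid`, `resno`, `chain`, `x`, `y`, `z` (Angstrom), `occ`, `element`.
#'
#' @exportClass AtomicStructure
setClass("AtomicStructure",
  representation(atoms = "data.frame"),
  validity = function(object) {
    msg <- NULL
    need <- c("elety", "resid", "resno", "chain", "x", "y", "z", "element")
    if (!all(need %in% names(object@atoms)))
      msg <- c(msg, paste("atoms needs columns:", paste(need, collapse = ", ")))
    else if (nrow(object@atoms) == 0L)
      msg <- c(msg, "structure contains no atoms")
    else if (any(!is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
      msg <- c(msg, "coordinates must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an AtomicStructure from an atom table
#'
#' @param atoms data.frame as described in [AtomicStructure-class].
#' @return An [AtomicStructure-class] object.
#' @export
AtomicStructure <- function(atoms) {
  atoms <- as.data.frame(atoms)
  if (!"eleno" %in% names(atoms)) atoms$eleno <- seq_len(nrow(atoms))
  if (!"occ" %in% names(atoms)) atoms$occ <- rep(1, nrow(atoms))
  new("AtomicStructure", atoms = atoms)
}

#' TipModel: sphere-capped conical AFM tip
#'
#' The tip profile is a spherical cap of apex radius `radius` continued
#' tangentially by a cone of half-angle `halfAngle`:
#' `tip(r) = R - sqrt(R^2 - r^2)` for `r <= R cos(theta)` and
#' `tip(r) = R - R sin(theta) + (r - R cos(theta)) / tan(theta)` beyond.
#' Pseudo-AFM images are the grayscale dilation of the sample surface by
#' this profile, evaluated on a raster of pitch `scanStep`.
#'
#' @slot radius apex radius R, nm.
#' @slot halfAngle cone half-angle theta, degrees, in (0, 90).
#' @slot scanStep raster pitch for structure rasterization, nm.
#'
#' @exportClass TipModel
setClass("TipModel",
  representation(radius = "numeric", halfAngle = "numeric",
                 scanStep = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@radius < 0) msg <- c(msg, "radius must be >= 0")
    if (object@halfAngle <= 0 || object@halfAngle >= 90)
      msg <- c(msg, "halfAngle must lie strictly between 0 and 90 degrees")
    if (object@scanStep <= 0) msg <- c(msg, "scanStep must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a TipModel
#'
#' Defaults follow the simulated-scanning convention used for the crystal
#' reconstructions: 0.5 nm apex radius, 8 degree cone half-angle, 0.25 nm
#' scan step.
#'
#' @param radius apex radius, nm.
#' @param halfAngle cone half-angle, degrees.
#' @param scanStep raster pitch, nm.
#' @return A [TipModel-class] object.
#' @export
TipModel <- function(radius = 0.5, halfAngle = 8, scanStep = 0.25) {
  new("TipModel", radius = as.numeric(radius),
      halfAngle = as.numeric(halfAngle), scanStep = as.numeric(scanStep))
}

#' BoxStats: notched box-plot summary of a sample
#'
#' Median, Tukey-hinge quartiles, the McGill notch half-width
#' `1.57 * (Q3 - Q1) / sqrt(n)` (an approximate 95% confidence interval for
#' the median), the extremes, and the sample size.
#'
#' @slot median sample median.
#' @slot q1,q3 lower/upper Tukey hinges.
#' @slot notch notch half-width.
#' @slot min,max sample extremes.
#' @slot n sample size.
#'
#' @exportClass BoxStats
setClass("BoxStats",
  representation(median = "numeric", q1 = "numeric", q3 = "numeric",
                 notch = "numeric", min = "numeric", max = "numeric",
                 n = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (!(object@q1 <= object@median && object@median <= object@q3))
      msg <- c(msg, "Q1 <= median <= Q3 violated")
    if (is.null(msg)) TRUE else msg
  })

#' ContourSet: iso-height polylines at depths below the surface top
#'
#' @slot depths depths below the surface top, nm, strictly increasing.
#' @slot levels absolute heights of the contours, nm (strictly decreasing).
#' @slot contours list (one element per depth) of lists of polyline
#'   data.frames with columns `x`, `y` in nm.
#'
#' @exportClass ContourSet
setClass("ContourSet",
  representation(depths = "numeric", levels = "numeric", contours = "list"),
  validity = function(object) {
    msg <- NULL
    if (is.unsorted(object@depths, strictly = TRUE))
      msg <- c(msg, "depths must be strictly increasing")
    if (length(object@levels) && any(diff(object@levels) >= 0))
      msg <- c(msg, "levels must be strictly decreasing")
    if (length(object@contours) != length(object@depths))
      msg <- c(msg, "one contour list per depth required")
    if (is.null(msg)) TRUE else msg
  })
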