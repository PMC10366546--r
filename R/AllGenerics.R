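## Accessor generics, methods and show() for the S4 layer.

#' @name accessors
#' @title Accessors for AFMCrystal classes
#' @description Slot access for the package's S4 containers goes through
#'   these accessor generics; user code should never reach into slots.
#' @param x,object an AFMCrystal object.
#' @param i frame index (1-based).
#' @return The accessed component (see the individual methods).
NULL

#' @rdname accessors
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))
#' @rdname accessors
#' @export
setMethod("heights", "Topograph", function(x) x@heights)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "Topograph", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "TopographStack", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))
#' @rdname accessors
#' @export
setMethod("timestamps", "TopographStack", function(x) x@timestamps)
#' @rdname accessors
#' @export
setMethod("timestamps", "Topograph", function(x) x@timestamp)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "TopographStack", function(x) length(x@frames))
#' @rdname accessors
#' @export
setMethod("nFrames", "OccupancyMovie", function(x) length(x@frames))

#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setMethod("getFrame", "TopographStack", function(x, i) {
  stopifnot(i >= 1L, i <= length(x@frames))
  Topograph(x@frames[[i]], x@pixelSize, x@timestamps[i])
})
#' @rdname accessors
#' @export
setMethod("getFrame", "OccupancyMovie", function(x, i) {
  stopifnot(i >= 1L, i <= length(x@frames))
  x@frames[[i]]
})

#' @rdname accessors
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))
#' @rdname accessors
#' @export
setMethod("eventLog", "OccupancyMovie", function(x) x@eventLog)

#' @rdname accessors
#' @export
setGeneric("cellParameters", function(x) standardGeneric("cellParameters"))
#' @rdname accessors
#' @export
setMethod("cellParameters", "Lattice2D", function(x)
  c(a = x@aLen, b = x@bLen, gamma = x@gamma, orientation = x@orientation))

#' Lattice vectors in the image frame
#'
#' Returns the two lattice vectors as rows of a 2 x 2 matrix (nm), using the
#' image convention (x rightward, y downward): vector a at `orientation`
#' degrees from the x-axis, vector b at `orientation + gamma`.
#'
#' @param x a [Lattice2D-class].
#' @return matrix with rows `a` and `b`, columns `x` and `y` (nm).
#' @export
setGeneric("latticeVectors", function(x) standardGeneric("latticeVectors"))
#' @rdname latticeVectors
#' @export
setMethod("latticeVectors", "Lattice2D", function(x) {
  th <- x@orientation * pi / 180
  g <- x@gamma * pi / 180
  rbind(a = x@aLen * c(cos(th), sin(th)),
        b = x@bLen * c(cos(th + g), sin(th + g)))
})

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "AtomicStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("meanMap", function(x) standardGeneric("meanMap"))
#' @rdname accessors
#' @export
setMethod("meanMap", "StabilityMaps", function(x) x@mean)

#' @rdname accessors
#' @export
setGeneric("sdMap", function(x) standardGeneric("sdMap"))
#' @rdname accessors
#' @export
setMethod("sdMap", "StabilityMaps", function(x) x@sd)

#' @rdname accessors
#' @export
setGeneric("boxStats", function(x) standardGeneric("boxStats"))
#' @rdname accessors
#' @export
setMethod("boxStats", "BoxStats", function(x)
  c(median = x@median, q1 = x@q1, q3 = x@q3, notch = x@notch,
    min = x@min, max = x@max, n = x@n))

## show() ----

setMethod("show", "Topograph", function(object) {
  d <- dim(object@heights)
  cat(sprintf("Topograph: %d x %d px (%.3g x %.3g nm), %.3g nm/px\n",
              d[1], d[2], d[1] * object@pixelSize, d[2] * object@pixelSize,
              object@pixelSize))
  cat(sprintf("  heights [nm]: min %.3g, median %.3g, max %.3g",
              min(object@heights), stats::median(object@heights),
              max(object@heights)))
  if (!is.na(object@timestamp))
    cat(sprintf("  | t = %.3g s", object@timestamp))
  cat("\n")
})

setMethod("show", "TopographStack", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("TopographStack: %d frames, %d x %d px, %.3g nm/px, t = %.3g..%.3g s\n",
              length(object@frames), d[1], d[2], object@pixelSize,
              min(object@timestamps), max(object@timestamps)))
})

setMethod("show", "Lattice2D", function(object) {
  cat(sprintf(
    "Lattice2D: a = %.3g nm, b = %.3g nm, gamma = %.4g deg, orientation = %.4g deg\n",
    object@aLen, object@bLen, object@gamma, object@orientation))
})

setMethod("show", "OccupancyMovie", function(object) {
  n <- length(object@frames)
  last <- object@frames[[n]]
  cat(sprintf("OccupancyMovie: %d frames, %d stripes in last frame, %d logged events\n",
              n, nrow(last), nrow(object@eventLog)))
})

setMethod("show", "StabilityMaps", function(object) {
  cat(sprintf("StabilityMaps over frames %d..%d (%.3g s): mean SD %.3g nm, max SD %.3g nm\n",
              object@frameRange[1], object@frameRange[2], object@duration,
              mean(object@sd@heights), max(object@sd@heights)))
})

setMethod("show", "AtomicStructure", function(object) {
  a <- object@atoms
  cat(sprintf("AtomicStructure: %d atoms, %d chains (%s), %d residues\n",
              nrow(a), length(unique(a$chain)),
              paste(utils::head(unique(a$chain), 8), collapse = ","),
              nrow(unique(a[, c("chain", "resno")]))))
})

setMethod("show", "BoxStats", function(object) {
  cat(sprintf(
    "BoxStats: median %.4g [notch +/- %.4g], hinges %.4g/%.4g, range %.4g..%.4g, n = %d\n",
    object@median, object@notch, object@q1, object@q3, object@min,
    object@max, object@n))
})

setMethod("show", "ContourSet", function(object) {
  cat(sprintf("ContourSet: depths %s nm below top (%d levels)\n",
              paste(object@depths, collapse = ", "), length(object@depths)))
})

#' Display a Topograph
#'
#' Renders the height map with [graphics::image()] in physical coordinates
#' (nm), y pointing downward as in raw AFM frames.
#'
#' @param x a [Topograph-class].
#' @param y unused.
#' @param ... passed to [graphics::image()].
#' @export
setMethod("plot", signature(x = "Topograph", y = "missing"),
  function(x, y, ...) {
    h <- x@heights
    xs <- (seq_len(ncol(h)) - 1) * x@pixelSize
    ys <- (seq_len(nrow(h)) - 1) * x@pixelSize
    graphics::image(x = xs, y = ys, z = t(h)[, rev(seq_len(nrow(h)))],
                    col = grDevices::hcl.colors(64, "YlOrBr", rev = TRUE),
                    asp = 1, xlab = "x [nm]", ylab = "y [nm]", ...)
  })
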