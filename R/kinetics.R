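## Stripe tracing across frames, association/dissociation measurement,
## cumulative surface coverage and event-size statistics.

# Estimated threshold separating protein tops from the membrane level:
# midpoint between the median of the non-mica heights (the membrane, as
# long as coverage is partial) and the image maximum. NULL when the frame
# carries no protein layer (relief above the membrane < 1 nm).
proteinLevel <- function(h, micaCut = 1) {
  hm <- h[h > micaCut]
  if (!length(hm)) return(NULL)
  membrane <- stats::median(hm)
  if (max(hm) - membrane < 1) return(NULL)
  (membrane + max(hm)) / 2
}

#' Trace crystal stripes in one frame
#'
#' Automated replacement for manually drawn stripe traces: with the lattice
#' known (fitted or ground truth), the height map is probed by bilinear
#' sampling at every dimer-slot centre of every lattice row crossing the
#' image; slots above the protein threshold are occupied, and runs of
#' consecutive occupied slots form stripe traces. Lengths are reported on
#' the slot grid (`slots x a/3`, the projection onto the lattice a-axis),
#' which quantizes away sub-slot boundary jitter. Traces shorter than
#' `minLength` are discarded.
#'
#' @param topo a [Topograph-class].
#' @param lattice a [Lattice2D-class] (orientation and origin define the
#'   slot grid).
#' @param minLength minimum trace length in nm.
#' @param level height threshold (nm) separating protein from membrane;
#'   default: estimated from the frame (midpoint between the membrane
#'   median and the maximum). Frames without protein return an empty list.
#' @return data.frame with one row per trace: `id`, `row`, `slotMin`,
#'   `slotMax`, `length_nm`, and the endpoints `x0`, `y0`, `x1`, `y1` (nm)
#'   of the traced polyline.
#' @export
traceStripes <- function(topo, lattice, minLength = 5, level = NULL) {
  stopifnot(is(topo, "Topograph"), is(lattice, "Lattice2D"))
  h <- topo@heights
  px <- topo@pixelSize
  if (is.null(level)) {
    level <- proteinLevel(h)
    if (is.null(level)) return(emptyTraces())
  }
  nr <- nrow(h); nc <- ncol(h)
  W <- (nc - 1) * px; H <- (nr - 1) * px
  v <- latticeVectors(lattice)
  pitch <- lattice@aLen / 3
  # rows whose stripe line can cross the image: bound |r| by the image
  # diagonal over the inter-row distance
  rowSpacing <- abs(lattice@bLen * sin(degToRad(lattice@gamma)))
  diag <- sqrt(W^2 + H^2) + sqrt(sum(lattice@origin^2))
  rmax <- ceiling(diag / rowSpacing) + 1
  smax <- ceiling(diag / pitch) + 1
  traces <- list()
  id <- 0L
  for (r in seq(-rmax, rmax)) {
    s <- seq(-smax, smax)
    ctr <- slotCentre(lattice, s, r)
    inside <- ctr[, 1] >= 0 & ctr[, 1] <= W & ctr[, 2] >= 0 & ctr[, 2] <= H
    if (!any(inside)) next
    s <- s[inside]
    ctr <- ctr[inside, , drop = FALSE]
    occ <- bilinearSample(h, px, ctr[, 1], ctr[, 2]) > level
    if (!any(occ)) next
    # runs of consecutive occupied slots (slot indices may have gaps where
    # the row leaves the image; those break runs)
    d <- c(TRUE, diff(s) != 1L | diff(occ) != 0)
    grp <- cumsum(d)
    for (g in unique(grp[occ])) {
      sg <- s[grp == g & occ]
      len <- length(sg) * pitch
      if (len < minLength) next
      id <- id + 1L
      ep <- slotCentre(lattice, range(sg), r)
      traces[[id]] <- data.frame(id = id, row = r, slotMin = min(sg),
                                 slotMax = max(sg), length_nm = len,
                                 x0 = ep[1, 1], y0 = ep[1, 2],
                                 x1 = ep[2, 1], y1 = ep[2, 2])
    }
  }
  if (!length(traces)) return(emptyTraces())
  out <- do.call(rbind, traces)
  rownames(out) <- NULL
  out
}

emptyTraces <- function() {
  data.frame(id = integer(), row = integer(), slotMin = integer(),
             slotMax = integer(), length_nm = numeric(), x0 = numeric(),
             y0 = numeric(), x1 = numeric(), y1 = numeric())
}

#' Measure association/dissociation between two traced frames
#'
#' Overlaps the stripe traces of two sequential frames (same lattice) and
#' measures, per lattice row, the stripe length gained (association) and
#' lost (dissociation) between them. Rows are aligned across frames within
#' `maxLateralOffset`; within a row the comparison is a slot-set
#' difference, so a stripe growing at one end yields one association event
#' of the added length, a gap opening inside a stripe yields one
#' dissociation event of the gap length, a new trace yields an association
#' of its full length and a vanished trace a dissociation of its full
#' length. Each event is attributed to the overlapping trace (largest
#' overlap first); the measured totals satisfy the conservation identity
#' total(t+1) - total(t) = sum(assoc) - sum(dissoc) exactly.
#'
#' @param tracesT,tracesT1 trace tables from [traceStripes()] for frames t
#'   and t+1.
#' @param lattice the shared [Lattice2D-class].
#' @param maxLateralOffset maximum lateral offset (nm) for two rows to be
#'   treated as the same stripe track; default half the inter-row spacing.
#' @param frameT,frameT1 frame indices stored in the output.
#' @return data.frame (kinetics record) with columns `frame_t`,
#'   `frame_t1`, `stripe_id` (the id of the trace containing the change:
#'   a frame t+1 id for associations, a frame t id for dissociations),
#'   `event` (assoc/dissoc), `slots`, `length_nm`.
#' @export
matchAndMeasure <- function(tracesT, tracesT1, lattice,
                            maxLateralOffset = NULL, frameT = NA_integer_,
                            frameT1 = NA_integer_) {
  stopifnot(is(lattice, "Lattice2D"))
  rowSpacing <- abs(lattice@bLen * sin(degToRad(lattice@gamma)))
  if (is.null(maxLateralOffset)) maxLateralOffset <- rowSpacing / 2
  pitch <- lattice@aLen / 3
  rowTol <- max(0L, floor(maxLateralOffset / rowSpacing))
  rec <- list(); nrec <- 0L
  add <- function(id, event, slots) {
    nrec <<- nrec + 1L
    rec[[nrec]] <<- data.frame(frame_t = frameT, frame_t1 = frameT1,
                               stripe_id = id, event = event,
                               slots = slots, length_nm = slots * pitch,
                               stringsAsFactors = FALSE)
  }
  rowsT <- unique(tracesT$row)
  rowsT1 <- unique(tracesT1$row)
  # align rows across the two frames within the lateral tolerance
  mapRow <- function(r, rows) {
    if (!length(rows)) return(NA_integer_)
    d <- abs(rows - r)
    if (min(d) <= rowTol) rows[which.min(d)] else NA_integer_
  }
  allRows <- sort(unique(c(rowsT, vapply(rowsT1, function(r) {
    m <- mapRow(r, rowsT); if (is.na(m)) r else m
  }, numeric(1)))))
  for (r in allRows) {
    tT <- tracesT[tracesT$row == r, , drop = FALSE]
    r1 <- mapRow(r, rowsT1)
    tT1 <- if (is.na(r1)) tracesT1[0, , drop = FALSE] else
      tracesT1[tracesT1$row == r1, , drop = FALSE]
    slotsOf <- function(tr) if (nrow(tr)) unlist(lapply(
      seq_len(nrow(tr)), function(i) tr$slotMin[i]:tr$slotMax[i])) else
        integer()
    sT <- slotsOf(tT); sT1 <- slotsOf(tT1)
    attrib <- function(seg, tr, trOther) {
      # attribute a changed segment to the trace with the largest overlap;
      # ties and empty overlaps resolved by smallest id (greedy, total
      # order on overlap then id)
      cand <- if (nrow(tr)) tr else trOther
      if (!nrow(cand)) return(NA_integer_)
      ov <- vapply(seq_len(nrow(cand)), function(i)
        length(intersect(seg, (cand$slotMin[i] - 1L):(cand$slotMax[i] + 1L))),
        integer(1))
      cand$id[order(-ov, cand$id)][1]
    }
    segments <- function(sl) {
      if (!length(sl)) return(list())
      sl <- sort(sl)
      grp <- cumsum(c(TRUE, diff(sl) != 1L))
      split(sl, grp)
    }
    for (seg in segments(setdiff(sT1, sT)))      # gained -> association
      add(attrib(seg, tT1, tT), "assoc", length(seg))
    for (seg in segments(setdiff(sT, sT1)))      # lost -> dissociation
      add(attrib(seg, tT, tT1), "dissoc", length(seg))
  }
  if (nrec == 0L)
    return(data.frame(frame_t = integer(), frame_t1 = integer(),
                      stripe_id = integer(), event = character(),
                      slots = integer(), length_nm = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rec[seq_len(nrec)])
  rownames(out) <- NULL
  out
}

#' Trace and measure a whole movie
#'
#' Runs [traceStripes()] on every frame and [matchAndMeasure()] on every
#' sequential frame pair. Frames may be skipped (e.g. bad image quality):
#' pass their indices in `omit`; records then carry the true frame gap and
#' are never interpolated.
#'
#' @param stack a [TopographStack-class].
#' @param lattice a [Lattice2D-class].
#' @param minLength,level passed to [traceStripes()].
#' @param omit integer frame indices to skip.
#' @return list with `traces` (per-frame list) and `records` (combined
#'   kinetics data.frame).
#' @export
measureMovieKinetics <- function(stack, lattice, minLength = 5,
                                 level = NULL, omit = integer()) {
  idx <- setdiff(seq_len(nFrames(stack)), omit)
  traces <- lapply(idx, function(i)
    traceStripes(getFrame(stack, i), lattice, minLength, level))
  names(traces) <- idx
  recs <- list()
  if (length(idx) > 1) for (k in seq_len(length(idx) - 1)) {
    recs[[k]] <- matchAndMeasure(traces[[k]], traces[[k + 1]], lattice,
                                 frameT = idx[k], frameT1 = idx[k + 1])
  }
  list(traces = traces, records = do.call(rbind, recs))
}

#' Cumulative crystal coverage from kinetics records
#'
#' Running sum, over ordered frame pairs, of total association minus total
#' dissociation length: the total size of the accumulating crystal relative
#' to the first analyzed frame. Increments may be negative when
#' dissociation outweighs association in an interval.
#'
#' @param records kinetics data.frame from [matchAndMeasure()] /
#'   [measureMovieKinetics()].
#' @param frameInterval seconds per frame (for the time axis); timestamps
#'   are `frame_t1 * frameInterval` when frame indices are available.
#' @return data.frame with columns `frame`, `time_s`, `increment_nm`,
#'   `coverage_nm`.
#' @export
cumulativeCoverage <- function(records, frameInterval = 1) {
  if (is.null(records) || nrow(records) == 0)
    return(data.frame(frame = integer(), time_s = numeric(),
                      increment_nm = numeric(), coverage_nm = numeric()))
  sgn <- ifelse(records$event == "dissoc", -1, 1)
  inc <- tapply(sgn * records$length_nm, records$frame_t1, sum)
  frames <- as.integer(names(inc))
  ord <- order(frames)
  inc <- as.numeric(inc[ord]); frames <- frames[ord]
  data.frame(frame = frames,
             time_s = frames * frameInterval,
             increment_nm = inc,
             coverage_nm = cumsum(inc))
}

#' Event-size statistics per kinetics class
#'
#' Pools event lengths per class (association, dissociation, and both
#' combined) and summarizes each with [notchedBox()].
#'
#' @param records kinetics data.frame.
#' @return list with elements `association`, `dissociation`, `both`
#'   ([BoxStats-class] or NULL for an empty class, with a flag attribute
#'   `"empty"` naming empty classes) and `values`.
#' @export
unitSizeStats <- function(records) {
  stopifnot(nrow(records) >= 1)
  a <- records$length_nm[records$event %in% c("assoc", "nucleate")]
  d <- records$length_nm[records$event == "dissoc"]
  mk <- function(x) if (length(x)) notchedBox(x) else NULL
  out <- list(association = mk(a), dissociation = mk(d), both = mk(c(a, d)),
              values = list(association = a, dissociation = d,
                            both = c(a, d)))
  attr(out, "empty") <- c("association", "dissociation")[
    c(length(a) == 0, length(d) == 0)]
  out
}

#' Least-squares fit of a four-parameter Gaussian
#'
#' Fits `y = amplitude * exp(-(x - centre)^2 / (2 width^2)) + offset` by
#' Levenberg-Marquardt least squares. Near-constant data are handled as
#' the degenerate zero-amplitude solution.
#'
#' @param x,y numeric vectors (>= 5 points).
#' @return list with `amplitude`, `centre`, `width`, `offset`,
#'   `residualNorm` and `converged`; on non-convergence `converged` is
#'   FALSE and the parameters are NA.
#' @export
gaussianFit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    return(list(amplitude = 0, centre = mean(x),
                width = diff(range(x)) / 4, offset = mean(y),
                residualNorm = 0, converged = TRUE))
  }
  off0 <- min(y)
  amp0 <- max(y) - min(y)
  mu0 <- x[which.max(y)]
  w0 <- max(diff(range(x)) / 6, 1e-6)
  fit <- try(minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * s^2)) + c0,
    start = list(A = amp0, mu = mu0, s = w0, c0 = off0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(amplitude = NA_real_, centre = NA_real_, width = NA_real_,
                offset = NA_real_, residualNorm = NA_real_,
                converged = FALSE))
  p <- stats::coef(fit)
  list(amplitude = unname(p["A"]), centre = unname(p["mu"]),
       width = abs(unname(p["s"])), offset = unname(p["c0"]),
       residualNorm = sqrt(sum(stats::resid(fit)^2)), converged = TRUE)
}
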