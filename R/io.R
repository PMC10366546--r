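## Stack I/O: multi-page 32-bit float TIFF plus a JSON sidecar.
##
## TIFF readers expect float samples in [0, 1], so heights (nm) are stored
## divided by a height scale recorded in the sidecar together with the
## pixel size, the timestamps and any metadata; the reader restores nm.

#' Write a topograph stack as multi-page float TIFF + JSON sidecar
#'
#' @param stack a [TopographStack-class].
#' @param file output TIFF path; the sidecar is written to
#'   `paste0(file, ".json")`.
#' @param heightScale nm mapped to sample value 1.0; default: the stack
#'   maximum (so samples span the unit interval).
#' @return `file`, invisibly.
#' @export
writeTopographStack <- function(stack, file, heightScale = NULL) {
  stopifnot(is(stack, "TopographStack"))
  hmin <- min(vapply(stack@frames, min, numeric(1)))
  hmax <- max(vapply(stack@frames, max, numeric(1)))
  if (hmin < 0) stop("negative heights cannot be stored; offset the stack")
  if (is.null(heightScale)) heightScale <- max(hmax, 1e-12)
  pages <- lapply(stack@frames, function(m) m / heightScale)
  tiff::writeTIFF(pages, file, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_nm = stack@pixelSize,
               height_scale_nm = heightScale,
               timestamps_s = stack@timestamps,
               n_frames = length(stack@frames))
  extra <- stack@metadata[setdiff(names(stack@metadata), "config")]
  if (length(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a topograph stack written by [writeTopographStack()]
#'
#' @param file TIFF path with its JSON sidecar alongside.
#' @return A [TopographStack-class] with heights in nm.
#' @export
readTopographStack <- function(file) {
  sidecar <- paste0(file, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(file, all = TRUE)
  frames <- lapply(pages, function(m) m * meta$height_scale_nm)
  TopographStack(frames, pixelSize = meta$pixel_size_nm,
                 timestamps = meta$timestamps_s,
                 metadata = list(source = file))
}

#' Write a ground-truth or kinetics event log as CSV
#'
#' @param log data.frame (event log from [simulateGrowth()] or kinetics
#'   records from [matchAndMeasure()]).
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
writeEventLog <- function(log, file) {
  utils::write.csv(log, file, row.names = FALSE)
  invisible(file)
}
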