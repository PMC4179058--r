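#' Thermal frame
#'
#' A single calibrated thermal image: a matrix of temperatures in degrees
#' Celsius plus acquisition metadata. Rows index the vertical image axis with
#' row 1 at the top; columns index the horizontal axis. All pixel coordinates
#' throughout the package are 1-based `(row, col)` pairs in this orientation.
#'
#' @param values Numeric matrix of temperatures (degrees C). All values must
#'   be finite.
#' @param frame_index Non-negative integer position of the frame in its
#'   sequence.
#' @param altitude Optional camera altitude in meters at acquisition time.
#' @param timestamp Optional acquisition time in seconds.
#'
#' @return An object of class `thermal_frame` with fields `values`, `height`,
#'   `width`, `frame_index`, `altitude`, `timestamp`.
#' @examples
#' fr <- thermal_frame(matrix(20, 4, 6), frame_index = 0)
#' fr$height
#' @export
thermal_frame <- function(values, frame_index = 0L, altitude = NULL,
                          timestamp = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix of temperatures")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("frame must have height >= 1 and width >= 1")
  }
  if (!all(is.finite(values))) {
    stop("all temperatures must be finite")
  }
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != 1L || is.na(frame_index) || frame_index < 0L) {
    stop("`frame_index` must be a single non-negative integer")
  }
  if (!is.null(altitude)) {
    altitude <- as.numeric(altitude)
    if (length(altitude) != 1L || !is.finite(altitude) || altitude <= 0) {
      stop("`altitude` must be a single positive number (meters)")
    }
  }
  structure(
    list(values = values, height = nrow(values), width = ncol(values),
         frame_index = frame_index, altitude = altitude,
         timestamp = timestamp),
    class = "thermal_frame"
  )
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf("<thermal_frame> %d x %d px, frame %d, %.1f-%.1f degC%s\n",
              x$height, x$width, x$frame_index,
              min(x$values), max(x$values),
              if (is.null(x$altitude)) ""
              else sprintf(", altitude %.1f m", x$altitude)))
  invisible(x)
}

#' Frame sequence
#'
#' An ordered collection of [thermal_frame] objects with strictly increasing
#' frame indices and a common raster size, the unit on which tracking
#' operates.
#'
#' @param frames List of [thermal_frame] objects.
#' @return An object of class `frame_sequence` (a list with field `frames`).
#' @export
frame_sequence <- function(frames) {
  if (!length(frames)) stop("a frame sequence must contain at least one frame")
  ok <- vapply(frames, inherits, logical(1), "thermal_frame")
  if (!all(ok)) stop("all elements must be thermal_frame objects")
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  if (any(diff(idx) <= 0L)) {
    stop("frame indices must be strictly increasing")
  }
  hs <- vapply(frames, `[[`, integer(1), "height")
  ws <- vapply(frames, `[[`, integer(1), "width")
  if (length(unique(hs)) != 1L || length(unique(ws)) != 1L) {
    stop("all frames in a sequence must share the same raster size")
  }
  structure(list(frames = frames), class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  alts <- altitudes(x)
  cat(sprintf("<frame_sequence> %d frames, %d x %d px%s\n",
              length(x$frames), x$frames[[1]]$height, x$frames[[1]]$width,
              if (all(is.na(alts))) ""
              else sprintf(", altitude %.1f-%.1f m",
                           min(alts, na.rm = TRUE), max(alts, na.rm = TRUE))))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Per-frame altitude profile of a sequence
#'
#' @param seq A [frame_sequence].
#' @return Numeric vector of altitudes in meters, `NA` where absent.
#' @export
altitudes <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  vapply(seq$frames, function(f) {
    if (is.null(f$altitude)) NA_real_ else f$altitude
  }, numeric(1))
}
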