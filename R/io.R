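# Raster storage: multi-page 16-bit unsigned TIFF holding quantized
# temperatures, plus a JSON sidecar {scale, offset, frame_index, altitude}.
# Temperature reconstruction is raw * scale + offset; quantization exists
# only at this file boundary.

sidecar_path <- function(path) {
  sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
}

#' Write a frame sequence to disk
#'
#' Stores temperatures as 16-bit unsigned integers in a multi-page TIFF with
#' a JSON metadata sidecar. The linear scale and offset are chosen to cover
#' the sequence's temperature range, so any temperature is reconstructed to
#' within half of one quantization step.
#'
#' @param seq A [frame_sequence].
#' @param path Output TIFF path (`.tif`); the sidecar is written next to it
#'   with extension `.json`.
#' @return Invisibly, the sidecar metadata list.
#' @export
write_frames <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  lo <- min(vapply(seq$frames, function(f) min(f$values), numeric(1)))
  hi <- max(vapply(seq$frames, function(f) max(f$values), numeric(1)))
  scale <- if (hi > lo) (hi - lo) / 65535 else 0.01
  offset <- lo
  pages <- lapply(seq$frames, function(f) {
    raw <- round((f$values - offset) / scale)
    raw / 65535  # writeTIFF stores round(x * 65535) at 16 bits
  })
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "none"),
    error = function(e) stop("cannot write TIFF at '", path, "': ",
                             conditionMessage(e))
  )
  meta <- list(
    scale = scale,
    offset = offset,
    frame_index = vapply(seq$frames, `[[`, integer(1), "frame_index"),
    altitude = altitudes(seq)
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(meta)
}

#' Read a frame sequence from disk
#'
#' Reads either a 16-bit TIFF written by [write_frames] (its JSON sidecar
#' must sit next to it) or, for small fixtures, a plain-text
#' whitespace-separated temperature grid (one frame, temperatures taken
#' verbatim, no sidecar).
#'
#' @param path Path to a `.tif`/`.tiff` file with sidecar, or to a
#'   plain-text grid file.
#' @return A [frame_sequence].
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    vals <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(vals) <- NULL
    return(frame_sequence(list(thermal_frame(vals, frame_index = 0L))))
  }
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("missing metadata sidecar: expected '", side, "' next to '",
         path, "'")
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (field in c("scale", "offset", "frame_index")) {
    if (is.null(meta[[field]])) {
      stop("sidecar '", side, "' lacks required field '", field, "'")
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  idx <- as.integer(meta$frame_index)
  if (length(idx) != length(pages)) {
    stop("sidecar lists ", length(idx), " frames but TIFF holds ",
         length(pages))
  }
  if (any(diff(idx) <= 0L)) stop("frame indices in sidecar are not strictly increasing")
  alt <- meta$altitude
  frames <- lapply(seq_along(pages), function(i) {
    vals <- pages[[i]] * meta$scale + meta$offset
    a <- if (is.null(alt) || length(alt) < i || is.na(alt[i])) NULL else alt[i]
    thermal_frame(vals, frame_index = idx[i], altitude = a)
  })
  frame_sequence(frames)
}
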