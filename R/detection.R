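#' Detection parameters
#'
#' Settings for per-frame hot-object detection. The threshold offset `c` is
#' added to the frame's median temperature; only pixels strictly warmer than
#' median + `c` are segmented, so detection adapts to scene-wide warming
#' (sun, season) and is unaffected by the hot objects themselves, which
#' barely move the median.
#'
#' @param c Temperature offset above the frame median, degrees C. Default 5.
#' @param min_area Minimum connected-component area in pixels to keep a blob.
#'   Default 2 (discards single-pixel noise).
#' @param connectivity Pixel connectivity for blob grouping, 4 or 8.
#'   Default 8: animals are compact and diagonal links should not split one
#'   object. (The 4-connected cross element is reserved for contour peeling.)
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(c = 5, min_area = 2L, connectivity = 8L) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0) {
    stop("`c` must be a single positive temperature offset")
  }
  min_area <- as.integer(min_area)
  if (is.na(min_area) || min_area < 1L) stop("`min_area` must be >= 1")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  structure(list(c = c, min_area = min_area, connectivity = connectivity),
            class = "detection_params")
}

#' Dynamic detection threshold for one frame
#'
#' Returns the frame's median temperature plus the offset `c`. The median is
#' used rather than the mean so that the hot objects being sought do not
#' drag the threshold up. For an even pixel count the median is the mean of
#' the two central order statistics.
#'
#' @param frame A [thermal_frame].
#' @param c Offset in degrees C (default 5).
#' @return Threshold temperature in degrees C.
#' @examples
#' dynamic_threshold(thermal_frame(matrix(20, 3, 3)), c = 5)  # 25
#' @export
dynamic_threshold <- function(frame, c = 5) {
  stopifnot(inherits(frame, "thermal_frame"))
  stats::median(frame$values) + c
}

#' Segment a frame at a threshold
#'
#' @param frame A [thermal_frame].
#' @param threshold Temperature in degrees C.
#' @return Logical matrix, `TRUE` exactly where temperature is strictly
#'   greater than `threshold`.
#' @export
segment_frame <- function(frame, threshold) {
  stopifnot(inherits(frame, "thermal_frame"))
  frame$values > threshold
}

# Label connected components of a logical mask by breadth-first search over
# the foreground pixels. Returns an integer matrix, 0 = background.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  fg <- which(mask)
  if (!length(fg)) return(labels)
  lab <- 0L
  queue <- integer(length(fg))
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    labels[start] <- lab
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      for (nb in seq_along(dr)) {
        rr <- r + dr[nb]; ccc <- cc + dc[nb]
        if (rr < 1L || rr > h || ccc < 1L || ccc > w) next
        q <- (ccc - 1L) * h + rr
        if (mask[q] && labels[q] == 0L) {
          labels[q] <- lab
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
  }
  labels
}

new_blob <- function(pixels, frame, frame_index) {
  # pixels: n x 2 integer matrix of (row, col)
  bbox <- c(min_row = min(pixels[, 1L]), min_col = min(pixels[, 2L]),
            max_row = max(pixels[, 1L]), max_col = max(pixels[, 2L]))
  structure(
    list(pixels = pixels,
         area = nrow(pixels),
         centroid = c(row = mean(pixels[, 1L]), col = mean(pixels[, 2L])),
         bounding_box = bbox,
         peak_temp = max(frame$values[pixels]),
         frame_index = frame_index),
    class = "blob"
  )
}

#' @export
print.blob <- function(x, ...) {
  cat(sprintf("<blob> frame %d, area %d px, centroid (%.1f, %.1f), peak %.2f degC\n",
              x$frame_index, x$area, x$centroid[1], x$centroid[2], x$peak_temp))
  invisible(x)
}

#' Extract hot blobs from a segmentation mask
#'
#' Groups above-threshold pixels into connected components, drops components
#' smaller than `min_area`, and returns one blob per surviving component,
#' sorted by the (min_row, min_col) corner of the bounding box.
#'
#' @param mask Logical segmentation mask from [segment_frame].
#' @param frame The [thermal_frame] the mask was computed from (same shape).
#' @param params A [detection_params] object.
#' @return List of `blob` objects with fields `pixels` (n x 2 matrix of
#'   1-based (row, col)), `area`, `centroid`, `bounding_box`, `peak_temp`,
#'   `frame_index`.
#' @export
extract_blobs <- function(mask, frame, params = detection_params()) {
  stopifnot(inherits(frame, "thermal_frame"),
            inherits(params, "detection_params"))
  if (!identical(dim(mask), dim(frame$values))) {
    stop("mask and frame must have the same shape")
  }
  labels <- label_components(mask, params$connectivity)
  n <- max(labels)
  if (n == 0L) return(list())
  blobs <- list()
  for (lab in seq_len(n)) {
    idx <- which(labels == lab, arr.ind = TRUE)
    if (nrow(idx) < params$min_area) next
    pix <- matrix(as.integer(idx), nrow(idx), 2L,
                  dimnames = list(NULL, c("row", "col")))
    blobs[[length(blobs) + 1L]] <- new_blob(pix, frame, frame$frame_index)
  }
  if (!length(blobs)) return(list())
  ord <- order(vapply(blobs, function(b) b$bounding_box[["min_row"]], numeric(1)),
               vapply(blobs, function(b) b$bounding_box[["min_col"]], numeric(1)))
  blobs[ord]
}

#' Detect hot objects in a frame
#'
#' Convenience wrapper chaining [dynamic_threshold], [segment_frame] and
#' [extract_blobs].
#'
#' @param frame A [thermal_frame].
#' @param params A [detection_params] object.
#' @return List of blobs (possibly empty).
#' @export
detect_objects <- function(frame, params = detection_params()) {
  th <- dynamic_threshold(frame, params$c)
  extract_blobs(segment_frame(frame, th), frame, params)
}

#' Serialize blobs to a JSON file
#'
#' Pixels are stored column-major run-length encoded per row for
#' compactness.
#'
#' @param blobs List of blobs.
#' @param path Output JSON path.
#' @return Invisibly, the serializable list.
#' @export
write_blobs <- function(blobs, path) {
  out <- lapply(blobs, function(b) {
    list(frame_index = b$frame_index,
         area = b$area,
         centroid = as.numeric(b$centroid),
         bbox = as.integer(b$bounding_box),
         peak_temp = b$peak_temp,
         pixels = apply(b$pixels, 1L, as.integer, simplify = FALSE))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
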