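# Thermal signatures by morphological contour peeling.
#
# The structuring element throughout is the 4-connected cross, so contours
# are 4-connected perimeters and the signature is invariant to integer
# translation and to rotation by multiples of 90 degrees.

shift_mask <- function(mask, dr, dc) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- mask[rs - dr, cs - dc]
  out
}

dilate_cross <- function(mask) {
  mask | shift_mask(mask, 1L, 0L) | shift_mask(mask, -1L, 0L) |
    shift_mask(mask, 0L, 1L) | shift_mask(mask, 0L, -1L)
}

erode_cross <- function(mask) {
  # pixels whose 4 axial neighbors (and themselves) are all foreground;
  # neighbors beyond the frame border count as background
  h <- nrow(mask); w <- ncol(mask)
  inner <- mask & shift_mask(mask, 1L, 0L) & shift_mask(mask, -1L, 0L) &
    shift_mask(mask, 0L, 1L) & shift_mask(mask, 0L, -1L)
  inner[c(1L, h), ] <- FALSE
  inner[, c(1L, w)] <- FALSE
  inner
}

#' Outer contour of an object mask
#'
#' The ring of background pixels axially adjacent to the object: the
#' dilation of the mask by the 4-connected cross, minus the mask. This is
#' the `i = -1` contour of a thermal signature, capturing the temperature
#' just outside the object's boundary.
#'
#' @param blob_mask Non-empty logical matrix.
#' @return Logical matrix of the ring. If the object touches the frame
#'   border the ring is clipped to the frame and the attribute `clipped`
#'   is set to `TRUE`.
#' @export
outer_contour <- function(blob_mask) {
  stopifnot(is.logical(blob_mask), any(blob_mask))
  ring <- dilate_cross(blob_mask) & !blob_mask
  h <- nrow(blob_mask); w <- ncol(blob_mask)
  clipped <- any(blob_mask[c(1L, h), ]) || any(blob_mask[, c(1L, w)])
  attr(ring, "clipped") <- clipped
  ring
}

#' Perimeter contour of an object mask
#'
#' Pixels of the object with at least one axial (4-connected) neighbor
#' outside it: the mask minus its erosion by the cross element. This is the
#' contour removed at each peeling iteration.
#'
#' @param blob_mask Non-empty logical matrix.
#' @return Logical matrix of the perimeter (subset of the mask).
#' @export
perimeter_contour <- function(blob_mask) {
  stopifnot(is.logical(blob_mask), any(blob_mask))
  blob_mask & !erode_cross(blob_mask)
}

blob_to_mask <- function(blob, height, width) {
  mask <- matrix(FALSE, height, width)
  mask[blob$pixels] <- TRUE
  mask
}

#' Extract the thermal signature of a detected object
#'
#' The signature `cm(i)`, `i = -1, 0, ..., M`, records the mean temperature
#' of successive contours: first the ring one pixel outside the object
#' (`i = -1`, obtained by a single cross dilation), then the object's
#' 4-connected perimeter, which is peeled off, and so on until the object is
#' exhausted after `M + 1` peels. Temperatures are always read from the
#' original frame; only the mask shrinks. An animal's insulating coat makes
#' its surface warmest just inside the boundary relative to the background,
#' so animal signatures rise steeply over the first interior contours,
#' unlike uniformly hot lamps or gently warm molehills.
#'
#' @param frame A [thermal_frame].
#' @param blob A blob from [extract_blobs], lying inside the frame.
#' @return An object of class `thermal_signature` with fields `samples`
#'   (numeric of length `M + 2`, first element the `i = -1` ring mean),
#'   `contour_sizes` (pixel count of each contour, same length), `M`, and
#'   `border_clipped` (`TRUE` if the outer ring was clipped by the frame
#'   edge). If the ring is entirely outside the frame the `i = -1` sample
#'   falls back to the first interior sample.
#' @export
extract_signature <- function(frame, blob) {
  stopifnot(inherits(frame, "thermal_frame"), inherits(blob, "blob"))
  mask <- blob_to_mask(blob, frame$height, frame$width)
  ring <- outer_contour(mask)
  clipped <- attr(ring, "clipped")
  n_ring <- sum(ring)
  samples <- numeric(0)
  sizes <- integer(0)
  cur <- mask
  while (any(cur)) {
    per <- perimeter_contour(cur)
    samples <- c(samples, mean(frame$values[per]))
    sizes <- c(sizes, sum(per))
    cur <- cur & !per
  }
  ring_mean <- if (n_ring > 0L) mean(frame$values[ring]) else samples[1L]
  structure(
    list(samples = c(ring_mean, samples),
         contour_sizes = c(n_ring, sizes),
         M = length(samples) - 1L,
         border_clipped = clipped),
    class = "thermal_signature"
  )
}

#' @export
print.thermal_signature <- function(x, ...) {
  cat(sprintf("<thermal_signature> M = %d, cm(-1..%d) = %s%s\n",
              x$M, x$M,
              paste(sprintf("%.2f", x$samples), collapse = ", "),
              if (x$border_clipped) " [border-clipped]" else ""))
  invisible(x)
}

#' Normalize a thermal signature
#'
#' Subtracts the `i = -1` outer-ring mean from every sample, making the
#' signature relative to the object's immediate background. The first
#' normalized sample is exactly 0, and adding any constant temperature to
#' the whole scene leaves the result unchanged -- absolute temperature
#' (sun-heating, season) carries no weight in the features.
#'
#' @param sig A `thermal_signature`, or a plain numeric sample vector of
#'   length >= 2.
#' @return Numeric vector of normalized samples.
#' @export
normalize_signature <- function(sig) {
  samples <- if (inherits(sig, "thermal_signature")) sig$samples else sig
  if (length(samples) < 2L) stop("signature must have at least 2 samples")
  samples - samples[1L]
}
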