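# Multi-frame tracking with guess-region gating and recursive Bayesian
# belief accumulation.

#' Tracker parameters
#'
#' @param radius Guess-region gate radius in pixels; a detection may only
#'   join a track if it lies within this distance of the track's predicted
#'   center. Default 190.
#' @param max_missed Number of consecutive frames a track may go without an
#'   accepted detection before termination. Default 3.
#' @param min_track_points Tracks need strictly more members than this to be
#'   identified at evaluation time. Default 5.
#' @param prior Initial animal belief of a new track. Default 0.5
#'   (maximum ignorance).
#' @param clamp Lower/upper clamp bounds applied to the kNN likelihood
#'   before each belief update. Default `c(0.05, 0.95)`.
#' @return An object of class `tracker_params`.
#' @export
tracker_params <- function(radius = 190, max_missed = 3L,
                           min_track_points = 5L, prior = 0.5,
                           clamp = c(0.05, 0.95)) {
  if (radius <= 0) stop("`radius` must be positive")
  max_missed <- as.integer(max_missed)
  if (max_missed < 0L) stop("`max_missed` must be >= 0")
  if (prior <= 0 || prior >= 1) stop("`prior` must lie strictly in (0, 1)")
  structure(list(radius = radius, max_missed = max_missed,
                 min_track_points = as.integer(min_track_points),
                 prior = prior, clamp = clamp),
            class = "tracker_params")
}

new_track <- function(id, frame, row, col, g_A, params) {
  bel <- update_belief(params$prior, clamp_likelihood(g_A, params$clamp))
  structure(
    list(id = id,
         members = data.frame(frame = frame, row = row, col = col, g_A = g_A,
                              belief = bel,
                              label = if (g_A > 0.5) "animal" else "non_animal",
                              stringsAsFactors = FALSE),
         missed = 0L, status = "active", final_label = NULL),
    class = "track"
  )
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track %s> %d members, frames %d-%d, belief %.3f, %s%s\n",
              as.character(x$id), nrow(x$members),
              min(x$members$frame), max(x$members$frame),
              x$members$belief[nrow(x$members)], x$status,
              if (is.null(x$final_label)) ""
              else paste0(", identified ", x$final_label)))
  invisible(x)
}

#' Predict the guess region of a track
#'
#' The guess-region center is the last member's position extended by the
#' movement between the two most recent members (linear extrapolation); a
#' track with a single member predicts its own position. The radius is the
#' fixed gate radius.
#'
#' @param track An active `track` with at least one member.
#' @param params A [tracker_params] object.
#' @return List with `center = c(row, col)` and `radius`.
#' @export
predict_guess_region <- function(track, params = tracker_params()) {
  stopifnot(inherits(track, "track"), nrow(track$members) >= 1L)
  m <- track$members
  n <- nrow(m)
  last <- c(m$row[n], m$col[n])
  center <- if (n >= 2L) last + (last - c(m$row[n - 1L], m$col[n - 1L])) else last
  list(center = c(row = center[1L], col = center[2L]), radius = params$radius)
}

#' Recursive Bayesian belief update
#'
#' One step of the track-level animal belief: with prior `bel_prev` (the
#' belief after the previous detection) and clamped kNN likelihood `g_A`
#' for the new detection, Bayes' rule with the two-class evidence
#' denominator gives
#' `bel_prev * g_A / (bel_prev * g_A + (1 - bel_prev) * (1 - g_A))`.
#' In log-odds the update simply adds `log(g_A / (1 - g_A))`, so the final
#' belief depends only on the multiset of likelihoods, not their order.
#'
#' @param bel_prev Previous belief, strictly in (0, 1).
#' @param g_A Clamped likelihood in `[0.05, 0.95]`.
#' @return Updated belief, strictly in (0, 1). A long run of one-sided
#'   likelihoods converges geometrically towards 0 or 1, so the result is
#'   additionally kept a machine-noise margin (1e-12) away from the
#'   endpoints to stop floating-point saturation from freezing the belief.
#' @examples
#' update_belief(0.5, 6 / 11)  # a symmetric prior just passes g_A through
#' @export
update_belief <- function(bel_prev, g_A) {
  stopifnot(bel_prev > 0, bel_prev < 1)
  b <- bel_prev * g_A / (bel_prev * g_A + (1 - bel_prev) * (1 - g_A))
  eps <- 1e-12
  min(max(b, eps), 1 - eps)
}

#' Associate one frame's detections with the active tracks
#'
#' Greedy gated nearest-neighbour assignment: among all (active track,
#' detection) pairs whose distance from the track's predicted guess-region
#' center is at most the gate radius, the globally nearest pair is matched
#' first, then the next nearest among the remaining, one detection per
#' track per frame. Each accepted detection triggers a belief update with
#' its clamped likelihood. Unmatched detections open new tracks at the
#' prior belief; tracks accepting nothing age by one missed frame and
#' terminate once the miss count exceeds `max_missed`. Missed frames do not
#' change belief (no observation, no update).
#'
#' @param tracks List of `track` objects (any status).
#' @param detections Data frame with columns `row`, `col`, `g_A` -- all
#'   detections of one frame.
#' @param frame Frame index of the detections (must exceed every track's
#'   last member frame).
#' @param params A [tracker_params] object.
#' @return Updated list of tracks (new tracks appended).
#' @export
associate_frame <- function(tracks, detections, frame,
                            params = tracker_params()) {
  frame <- as.integer(frame)
  active <- which(vapply(tracks, function(t) t$status == "active", logical(1)))
  for (ti in active) {
    lastf <- max(tracks[[ti]]$members$frame)
    if (frame <= lastf) stop("detections must be later than every track's last frame")
  }
  nd <- if (is.null(detections)) 0L else nrow(detections)
  matched_track <- integer(0)
  matched_det <- integer(0)
  if (length(active) && nd) {
    centers <- t(vapply(active, function(ti) {
      predict_guess_region(tracks[[ti]], params)$center
    }, numeric(2)))
    dist <- sqrt(outer(centers[, 1L], detections$row, "-")^2 +
                 outer(centers[, 2L], detections$col, "-")^2)
    dim(dist) <- c(length(active), nd)
    dist[dist > params$radius] <- Inf
    while (any(is.finite(dist))) {
      best <- arrayInd(which.min(dist), dim(dist))
      i <- best[1L]; j <- best[2L]
      matched_track <- c(matched_track, active[i])
      matched_det <- c(matched_det, j)
      dist[i, ] <- Inf
      dist[, j] <- Inf
    }
  }
  for (mi in seq_along(matched_track)) {
    ti <- matched_track[mi]; j <- matched_det[mi]
    tr <- tracks[[ti]]
    g <- detections$g_A[j]
    bel <- update_belief(tr$members$belief[nrow(tr$members)],
                         clamp_likelihood(g, params$clamp))
    tr$members <- rbind(tr$members,
                        data.frame(frame = frame, row = detections$row[j],
                                   col = detections$col[j], g_A = g,
                                   belief = bel,
                                   label = if (g > 0.5) "animal" else "non_animal",
                                   stringsAsFactors = FALSE))
    tr$missed <- 0L
    tracks[[ti]] <- tr
  }
  # age unmatched active tracks
  for (ti in setdiff(active, matched_track)) {
    tr <- tracks[[ti]]
    tr$missed <- tr$missed + 1L
    if (tr$missed > params$max_missed) tr$status <- "terminated"
    tracks[[ti]] <- tr
  }
  # new tracks for unmatched detections
  next_id <- length(tracks) + 1L
  for (j in setdiff(seq_len(nd), matched_det)) {
    tracks[[length(tracks) + 1L]] <-
      new_track(next_id, frame, detections$row[j], detections$col[j],
                detections$g_A[j], params)
    next_id <- next_id + 1L
  }
  tracks
}

#' Identify a track from its accumulated belief
#'
#' The final label is animal exactly when the last belief strictly exceeds
#' 0.5; every member's per-frame label is then overwritten with the final
#' label. Tracks with `min_track_points` or fewer members are flagged
#' `identified = FALSE` and excluded from track-level evaluation.
#'
#' @param track A `track` (terminated, or at end of sequence).
#' @param params A [tracker_params] object.
#' @return The track with `final_label`, `identified`, and relabeled
#'   members.
#' @export
identify_track <- function(track, params = tracker_params()) {
  stopifnot(inherits(track, "track"))
  bel <- track$members$belief[nrow(track$members)]
  track$final_label <- if (bel > 0.5) "animal" else "non_animal"
  track$members$label <- track$final_label
  track$identified <- nrow(track$members) > params$min_track_points
  track$status <- "terminated"
  track
}

#' Track a whole sequence of classified detections
#'
#' Feeds per-frame detection tables through [associate_frame] in frame
#' order, then identifies every track.
#'
#' @param detections_by_frame Named or ordered list of data frames (columns
#'   `row`, `col`, `g_A`), one per frame; an attached `frame` column or the
#'   list names give the frame indices, else positions 1..n are used.
#' @param params A [tracker_params] object.
#' @return List of identified `track` objects.
#' @export
track_sequence <- function(detections_by_frame, params = tracker_params()) {
  tracks <- list()
  frames <- names(detections_by_frame)
  for (i in seq_along(detections_by_frame)) {
    det <- detections_by_frame[[i]]
    fidx <- if (!is.null(det$frame) && nrow(det)) det$frame[1L]
            else if (!is.null(frames)) as.integer(frames[i]) else i
    tracks <- associate_frame(tracks, det, fidx, params)
  }
  lapply(tracks, identify_track, params = params)
}

#' Serialize tracks to a JSON file
#'
#' @param tracks List of tracks.
#' @param path Output JSON path.
#' @return Invisibly, the serializable list.
#' @export
write_tracks <- function(tracks, path) {
  out <- lapply(tracks, function(t) {
    list(id = t$id,
         members = lapply(seq_len(nrow(t$members)), function(i) {
           as.list(t$members[i, c("frame", "row", "col", "g_A", "belief")])
         }),
         final_label = t$final_label,
         identified = isTRUE(t$identified),
         status = t$status)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
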