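# Synthetic system-level benchmarks: the experiments that mirror, on
# generated scenes, the qualitative behaviour observed on field recordings
# (classifier separability, the benefit of track-level identification, and
# the altitude dependence of detection).

#' Detect and classify one frame
#'
#' Runs detection, signature extraction, DCT parameterization and kNN
#' classification on a single frame.
#'
#' @param frame A [thermal_frame].
#' @param training A `knn_training_set`.
#' @param params [detection_params].
#' @param n_coeff DCT coefficients per detection.
#' @param k kNN neighbours.
#' @return Data frame with one row per detection: `frame`, `row`, `col`,
#'   `area`, `g_A`, `label`.
#' @export
classify_frame <- function(frame, training, params = detection_params(),
                           n_coeff = 7L, k = 11L) {
  blobs <- detect_objects(frame, params)
  if (!length(blobs)) {
    return(data.frame(frame = integer(0), row = numeric(0), col = numeric(0),
                      area = integer(0), g_A = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(blobs, function(b) {
    fv <- dct_parameterize(normalize_signature(extract_signature(frame, b)),
                           n_coeff = n_coeff)
    r <- knn_classify(fv, training, k = k)
    data.frame(frame = frame$frame_index, row = b$centroid[["row"]],
               col = b$centroid[["col"]], area = b$area, g_A = r$g_A,
               label = r$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Leave-one-out balanced accuracy of a training set
#'
#' Classifies every training vector against all the others and reports the
#' balanced accuracy of the predictions -- the standard internal check of
#' class separability.
#'
#' @param training A `knn_training_set`.
#' @param k kNN neighbours.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
loo_balanced_accuracy <- function(training, k = 11L) {
  n <- nrow(training$x)
  pred <- character(n)
  for (i in seq_len(n)) {
    held <- structure(
      list(x = training$x[-i, , drop = FALSE],
           labels = training$labels[-i],
           counts = table(training$labels[-i]),
           n_coeff = training$n_coeff),
      class = "knn_training_set")
    pred[i] <- knn_classify(training$x[i, ], held, k = k)$label
  }
  truth <- training$labels
  cm <- confusion_matrix(tp = sum(pred == "animal" & truth == "animal"),
                         fp = sum(pred == "animal" & truth == "non_animal"),
                         fn = sum(pred == "non_animal" & truth == "animal"),
                         tn = sum(pred == "non_animal" & truth == "non_animal"))
  confusion_metrics(cm)$balanced_accuracy
}

# standard five-object benchmark scene: two animals, two molehills, one lamp
benchmark_objects <- function() {
  list(random_object("animal", c(60, 80)),
       random_object("animal", c(180, 240)),
       random_object("molehill", c(60, 240)),
       random_object("molehill", c(180, 80)),
       random_object("lamp", c(120, 160)))
}

#' Per-frame versus track-level classification on synthetic sequences
#'
#' Renders seeded multi-object sequences on a descending altitude profile,
#' classifies every detection per frame with the kNN likelihood, links
#' detections into tracks, identifies each track from its final belief, and
#' compares the balanced accuracy of the raw per-frame labels against the
#' track-overwritten labels. The descent matters: single-frame
#' classification of the early high-altitude detections is little better
#' than guessing, but the belief accumulated by the time the camera is low
#' relabels those same detections with the information-rich close frames --
#' the mechanism by which temporal pooling beats per-frame classification.
#' Detections are scored against the ground-truth object whose true center
#' lies within `match_radius` pixels; unmatched detections and members of
#' unidentified tracks (too few points) are excluded, as in track-level
#' evaluation of field recordings.
#'
#' @param training A `knn_training_set`. Should span the sequence's
#'   altitude range (see [generate_training_set]).
#' @param n_sequences Number of independent sequences.
#' @param n_frames Frames per sequence.
#' @param altitudes `c(start, end)` of the linear per-sequence altitude
#'   profile in meters. Default `c(18, 6)`: from degraded far-range
#'   imagery down to informative close range.
#' @param seed Integer seed.
#' @param k kNN neighbours.
#' @param match_radius Truth-matching radius in pixels.
#' @param offset_decay_length E-folding length (m) of the apparent-offset
#'   attenuation, as in [generate_training_set].
#' @param det_params [detection_params].
#' @param trk_params [tracker_params].
#' @return List: `per_frame_balanced_accuracy`,
#'   `tracked_balanced_accuracy`, `gain_points` (percentage points),
#'   `n_records`, and the per-detection `records` data frame.
#' @export
evaluate_tracking_gain <- function(training, n_sequences = 8L,
                                   n_frames = 30L, altitudes = c(18, 6),
                                   seed = 1L, k = 11L, match_radius = 10,
                                   offset_decay_length = 12,
                                   det_params = detection_params(),
                                   trk_params = tracker_params()) {
  records <- NULL
  for (s in seq_len(n_sequences)) {
    sseed <- seed * 1000L + s
    set.seed(sseed)
    objs <- benchmark_objects()
    sp <- scene_spec(objects = objs, seed = sseed,
                     offset_decay_length = offset_decay_length)
    gen <- generate_sequence(sp, n_frames,
                             seq(altitudes[1L], altitudes[2L],
                                 length.out = n_frames))
    dets <- vector("list", n_frames)
    rec <- NULL
    for (f in seq_len(n_frames)) {
      fr <- gen$sequence$frames[[f]]
      cls <- classify_frame(fr, training, det_params, training$n_coeff, k)
      dets[[f]] <- cls[, c("frame", "row", "col", "g_A")]
      if (!nrow(cls)) next
      for (b in seq_len(nrow(cls))) {
        dd <- vapply(gen$truth_tracks, function(tt) {
          i <- which(tt$frame == fr$frame_index)
          if (!length(i)) return(Inf)
          sqrt((tt$row[i] - cls$row[b])^2 + (tt$col[i] - cls$col[b])^2)
        }, numeric(1))
        if (min(dd) <= match_radius) {
          rec <- rbind(rec, data.frame(
            sequence = s, frame = fr$frame_index,
            row = cls$row[b], col = cls$col[b],
            truth = gen$truth_tracks[[which.min(dd)]]$label[1L],
            g_A = cls$g_A[b], stringsAsFactors = FALSE))
        }
      }
    }
    tracks <- track_sequence(dets, trk_params)
    if (is.null(rec)) next
    rec$track_label <- NA_character_
    for (tr in tracks) {
      if (!isTRUE(tr$identified)) next
      for (i in seq_len(nrow(tr$members))) {
        m <- tr$members[i, ]
        hit <- which(rec$frame == m$frame &
                     abs(rec$row - m$row) < 1e-9 & abs(rec$col - m$col) < 1e-9)
        rec$track_label[hit] <- tr$final_label
      }
    }
    records <- rbind(records, rec)
  }
  records <- records[!is.na(records$track_label), , drop = FALSE]
  balacc <- function(truth, pred) {
    confusion_metrics(confusion_matrix(
      tp = sum(pred == "animal" & truth == "animal"),
      fp = sum(pred == "animal" & truth == "non_animal"),
      fn = sum(pred == "non_animal" & truth == "animal"),
      tn = sum(pred == "non_animal" & truth == "non_animal")))$balanced_accuracy
  }
  per_frame <- ifelse(records$g_A > 0.5, "animal", "non_animal")
  pf <- balacc(records$truth, per_frame)
  tk <- balacc(records$truth, records$track_label)
  list(per_frame_balanced_accuracy = pf,
       tracked_balanced_accuracy = tk,
       gain_points = 100 * (tk - pf),
       n_records = nrow(records),
       records = records)
}

#' Detection performance over an altitude sweep
#'
#' Renders single-animal scenes at each altitude and reports the fraction
#' the detector finds. A detection counts only if some blob holds a pixel
#' within one pixel of the animal's true center -- a detected animal always
#' contains its own hottest core, whereas a stray noise blob that merely
#' lands nearby does not. With a finite radiative offset-decay length the
#' apparent animal temperature fades with altitude and the curve falls to
#' zero, reproducing the characteristic rapid degradation of detection at
#' height.
#'
#' @param altitudes Numeric vector of altitudes in meters.
#' @param n_scenes Scenes (independent animals) per altitude.
#' @param seed Integer seed.
#' @param offset_decay_length E-folding length (m) of the apparent-offset
#'   decay; default 12.
#' @param params [detection_params].
#' @return Data frame with columns `altitude`, `n_detected`, `n_actual`,
#'   `performance`.
#' @export
detection_sweep <- function(altitudes = seq(5, 26, by = 3), n_scenes = 16L,
                            seed = 1L, offset_decay_length = 12,
                            params = detection_params()) {
  out <- lapply(seq_along(altitudes), function(ai) {
    alt <- altitudes[ai]
    hits <- 0L
    for (s in seq_len(n_scenes)) {
      sseed <- seed * 10000L + ai * 100L + s
      set.seed(sseed)
      obj <- random_object("animal", c(48, 48) + stats::runif(2, -6, 6))
      sp <- scene_spec(shape = c(96L, 96L), objects = list(obj),
                       altitude = alt, ref_altitude = 5,
                       offset_decay_length = offset_decay_length,
                       seed = sseed)
      sc <- generate_scene(sp)
      blobs <- detect_objects(sc$frame, params)
      ctr <- round(sc$truth[[1L]]$center)
      hit <- any(vapply(blobs, function(b) {
        any(abs(b$pixels[, 1L] - ctr[1L]) <= 1L &
            abs(b$pixels[, 2L] - ctr[2L]) <= 1L)
      }, logical(1)))
      if (hit) hits <- hits + 1L
    }
    data.frame(altitude = alt, n_detected = hits, n_actual = n_scenes,
               performance = detection_performance(hits, n_scenes))
  })
  do.call(rbind, out)
}

#' Sample normalized synthetic animal signatures
#'
#' Renders randomized single-animal scenes (the same conditions as
#' [generate_training_set]) and returns the normalized thermal signature of
#' each detected animal -- the raw material for assessing how much of the
#' signature the truncated DCT retains.
#'
#' @param n Number of signatures.
#' @param seed Integer seed.
#' @param altitude_range `c(low, high)` meters; default `c(4, 16)`.
#' @param noise_sd Scene noise, degrees C.
#' @param offset_decay_length E-folding length (m) of the apparent-offset
#'   attenuation, as in [generate_training_set].
#' @param params [detection_params].
#' @return List of normalized sample vectors.
#' @export
sample_animal_signatures <- function(n, seed = 1L, altitude_range = c(4, 16),
                                     noise_sd = 1.5,
                                     offset_decay_length = 12,
                                     params = detection_params()) {
  set.seed(seed)
  sigs <- vector("list", n)
  i <- 0L
  while (i < n) {
    alt <- stats::runif(1, altitude_range[1L], altitude_range[2L])
    obj <- random_object("animal", c(48, 48) + stats::runif(2, -6, 6))
    sp <- scene_spec(shape = c(96L, 96L), background = stats::runif(1, 15, 23),
                     noise_sd = noise_sd, objects = list(obj),
                     altitude = alt, ref_altitude = 5,
                     offset_decay_length = offset_decay_length,
                     seed = sample.int(.Machine$integer.max %/% 2L, 1L))
    sc <- generate_scene(sp)
    blobs <- detect_objects(sc$frame, params)
    if (!length(blobs)) next
    dd <- vapply(blobs, function(b) {
      sqrt(sum((b$centroid - sc$truth[[1L]]$center)^2))
    }, numeric(1))
    i <- i + 1L
    sigs[[i]] <- normalize_signature(
      extract_signature(sc$frame, blobs[[which.min(dd)]]))
  }
  sigs
}
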