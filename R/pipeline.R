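# Stage runners wiring the modules into the end-to-end pipeline, plus the
# YAML configuration they share. Each runner reads and writes the documented
# on-disk formats so every intermediate artifact is inspectable; the CLI in
# inst/cli/thermaltrack.R is a thin argument parser over these functions.

#' Pipeline configuration
#'
#' A validated bag of stage parameters that round-trips through YAML
#' without loss.
#'
#' @param detection List: `c`, `min_area`, `connectivity`.
#' @param features List: `n_coeff`.
#' @param classifier List: `k`.
#' @param tracker List: `radius`, `max_missed`, `min_track_points`.
#' @param ranges List of altitude ranges as `c(low, high)`.
#' @param simulate List passed to the synthetic generator: `n_frames`,
#'   `altitude_start`, `altitude_end`, `n_animal`, `n_lamp`, `n_molehill`,
#'   `noise_sd`, `shape`.
#' @param seed Integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = list(c = 5, min_area = 2,
                                             connectivity = 8),
                            features = list(n_coeff = 7),
                            classifier = list(k = 11),
                            tracker = list(radius = 190, max_missed = 3,
                                           min_track_points = 5),
                            ranges = list(c(3, 10), c(10, 20)),
                            simulate = list(n_frames = 30, altitude_start = 5,
                                            altitude_end = 15, n_animal = 2,
                                            n_lamp = 2, n_molehill = 1,
                                            noise_sd = 1.5,
                                            shape = c(240, 320)),
                            seed = 1L) {
  cfg <- structure(list(detection = detection, features = features,
                        classifier = classifier, tracker = tracker,
                        ranges = ranges, simulate = simulate,
                        seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  do.call(detection_params, cfg$detection)
  do.call(tracker_params, cfg$tracker)
  if (cfg$features$n_coeff < 1) stop("config field features$n_coeff must be >= 1")
  if (cfg$classifier$k < 1) stop("config field classifier$k must be >= 1")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: '", path, "'")
  raw <- yaml::read_yaml(path)
  raw$ranges <- lapply(raw$ranges, as.numeric)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_params <- function(cfg) {
  list(det = do.call(detection_params, cfg$detection),
       trk = do.call(tracker_params, cfg$tracker))
}

#' Simulate a synthetic recording to disk
#'
#' Renders a seeded sequence (animals, lamps, molehills on a linear
#' altitude profile), writes the frames as TIFF + sidecar and the ground
#' truth as JSON.
#'
#' @param cfg A [pipeline_config].
#' @param output_dir Directory for `frames.tif`, `frames.json`,
#'   `ground_truth.json`.
#' @return Invisibly, the generated sequence and truth tracks.
#' @export
run_simulate <- function(cfg, output_dir) {
  sim <- cfg$simulate
  if (is.null(sim$n_frames) || sim$n_frames < 1) {
    stop("config field simulate$n_frames must be >= 1")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  shape <- as.integer(sim$shape)
  objects <- place_scene_objects(sim$n_animal, sim$n_lamp, sim$n_molehill,
                                 shape)
  spec <- scene_spec(shape = shape, noise_sd = sim$noise_sd,
                     objects = objects, ref_altitude = 5,
                     seed = cfg$seed)
  profile <- seq(sim$altitude_start, sim$altitude_end,
                 length.out = sim$n_frames)
  gen <- generate_sequence(spec, sim$n_frames, profile)
  write_frames(gen$sequence, file.path(output_dir, "frames.tif"))
  jsonlite::write_json(
    lapply(gen$truth_tracks, function(t) as.list(t)),
    file.path(output_dir, "ground_truth.json"),
    auto_unbox = FALSE, digits = NA)
  invisible(gen)
}

# deterministic-ish sparse placement on a grid, jittered by the caller's RNG
place_scene_objects <- function(n_animal, n_lamp, n_molehill, shape) {
  n <- n_animal + n_lamp + n_molehill
  classes <- c(rep("animal", n_animal), rep("lamp", n_lamp),
               rep("molehill", n_molehill))
  margin <- 40
  cols <- max(1L, ceiling(sqrt(n)))
  rows <- ceiling(n / cols)
  rseq <- seq(margin, shape[1L] - margin, length.out = rows)
  cseq <- seq(margin, shape[2L] - margin, length.out = cols)
  grid <- expand.grid(row = rseq, col = cseq)[seq_len(n), , drop = FALSE]
  lapply(seq_len(n), function(i) {
    random_object(classes[i],
                  center = c(grid$row[i], grid$col[i]) + stats::runif(2, -5, 5))
  })
}

#' Detect hot objects in a stored recording
#'
#' @param cfg A [pipeline_config].
#' @param input Path to a TIFF written by [write_frames] (or a plain-text
#'   grid fixture).
#' @param output Path for the blob JSON.
#' @return Invisibly, the per-frame blob lists.
#' @export
run_detect <- function(cfg, input, output) {
  p <- config_params(cfg)
  seq <- read_frames(input)
  blobs <- lapply(seq$frames, detect_objects, params = p$det)
  write_blobs(do.call(c, blobs), output)
  invisible(blobs)
}

#' Extract feature vectors for detected blobs
#'
#' Runs signature extraction and DCT parameterization for every blob of
#' every frame and writes the feature table CSV.
#'
#' @param cfg A [pipeline_config].
#' @param input Recording path as in [run_detect].
#' @param output Feature-table CSV path.
#' @param labels Optional character vector of labels, one per blob in
#'   detection order.
#' @return Invisibly, the feature table.
#' @export
run_features <- function(cfg, input, output, labels = NULL) {
  p <- config_params(cfg)
  seq <- read_frames(input)
  rows <- list()
  id <- 0L
  for (fr in seq$frames) {
    for (blob in detect_objects(fr, p$det)) {
      id <- id + 1L
      sig <- extract_signature(fr, blob)
      fv <- dct_parameterize(normalize_signature(sig),
                             n_coeff = cfg$features$n_coeff)
      lab <- if (is.null(labels)) NA_character_ else labels[id]
      rows[[id]] <- feature_table_row(id, blob, sig, fv, label = lab)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stop("no blobs detected; nothing to extract features from")
  write_feature_table(tab, output)
  invisible(tab)
}

#' Build and persist a training set
#'
#' Either validates a labeled feature table into a training set, or (with
#' `input = NULL`) generates a synthetic one.
#'
#' @param cfg A [pipeline_config].
#' @param input Labeled feature-table CSV, or `NULL` to synthesize.
#' @param output CSV path for the persisted training table.
#' @return Invisibly, the `knn_training_set`.
#' @export
run_train <- function(cfg, input = NULL, output) {
  ts <- if (is.null(input)) {
    generate_training_set(seed = cfg$seed,
                          n_coeff = cfg$features$n_coeff)
  } else {
    fit_training_set(read_feature_table(input))
  }
  tab <- attr(ts, "table")
  if (is.null(tab)) {
    tab <- data.frame(id = seq_len(nrow(ts$x)))
    for (j in seq_len(ts$n_coeff)) tab[[paste0("c", j - 1L)]] <- ts$x[, j]
    tab$label <- ts$labels
  }
  utils::write.csv(tab, output, row.names = FALSE, quote = FALSE)
  invisible(ts)
}

read_training_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  fit_training_set(tab)
}

#' Classify a feature table with a stored training set
#'
#' @param cfg A [pipeline_config].
#' @param input Feature-table CSV from [run_features].
#' @param training Training CSV from [run_train].
#' @param output Output CSV: the feature table plus `predicted` and `g_A`
#'   columns.
#' @return Invisibly, the classified table.
#' @export
run_classify <- function(cfg, input, training, output) {
  tab <- read_feature_table(input)
  ts <- read_training_csv(training)
  cc <- paste0("c", seq_len(ts$n_coeff) - 1L)
  miss <- setdiff(cc, names(tab))
  if (length(miss)) {
    stop("feature table lacks coefficient column(s): ",
         paste(miss, collapse = ", "))
  }
  pred <- predict(ts, tab[, cc, drop = FALSE], k = cfg$classifier$k)
  tab$predicted <- pred$label
  tab$g_A <- pred$g_A
  utils::write.csv(tab, output, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Track classified detections and identify tracks
#'
#' @param cfg A [pipeline_config].
#' @param input Classified CSV from [run_classify] (columns `frame_index`,
#'   `row`, `col`, `g_A`).
#' @param output Track JSON path.
#' @return Invisibly, the identified tracks.
#' @export
run_track <- function(cfg, input, output) {
  p <- config_params(cfg)
  tab <- utils::read.csv(input, stringsAsFactors = FALSE)
  need <- c("frame_index", "row", "col", "g_A")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("classified table lacks column(s): ", paste(miss, collapse = ", "))
  }
  by_frame <- split(tab, tab$frame_index)
  dets <- lapply(by_frame, function(d) {
    data.frame(frame = d$frame_index, row = d$row, col = d$col, g_A = d$g_A)
  })
  tracks <- track_sequence(dets, p$trk)
  write_tracks(tracks, output)
  invisible(tracks)
}

#' Evaluate a confusion matrix file
#'
#' Reads a CSV with columns `tp`, `fp`, `fn`, `tn` (one row per
#' evaluation), prints and returns the metric reports.
#'
#' @param cfg A [pipeline_config] (unused fields are ignored).
#' @param input CSV path.
#' @param output JSON path for the reports.
#' @return Invisibly, the list of `metrics_report`s.
#' @export
run_evaluate <- function(cfg, input, output) {
  tab <- utils::read.csv(input, stringsAsFactors = FALSE)
  need <- c("tp", "fp", "fn", "tn")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("confusion table lacks column(s): ", paste(miss, collapse = ", "))
  }
  reports <- lapply(seq_len(nrow(tab)), function(i) {
    confusion_metrics(confusion_matrix(tab$tp[i], tab$fp[i],
                                       tab$fn[i], tab$tn[i]))
  })
  names(reports) <- if (!is.null(tab$name)) tab$name else
    paste0("row", seq_len(nrow(tab)))
  jsonlite::write_json(
    lapply(reports, function(r) r[c("accuracy", "balanced_accuracy",
                                    "sensitivity", "specificity")]),
    output, auto_unbox = TRUE, digits = NA)
  for (nm in names(reports)) {
    cat(nm, "\n")
    print(reports[[nm]])
  }
  invisible(reports)
}
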