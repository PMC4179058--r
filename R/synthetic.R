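# Ground-truthed synthetic thermal scenes.
#
# Emulates top-view recordings over a cool field: a uniform background with
# per-pixel Gaussian sensor/clutter noise, plus sparse warm objects of three
# phenomenologies --
#   animal:   warm plateau falling to background across a thin boundary
#             shell (the insulating-coat edge gradient),
#   lamp:     uniformly very hot sharp-edged disk (halogen spotlight),
#   molehill: shallow wide Gaussian mound of disturbed warm soil.
# Object pixel footprints scale with (reference_altitude / altitude)^2; at
# high altitude the rendered profile narrows below a ~0.7 px floor so object
# temperature mixes with background, emulating the resolution floor of a
# finite ground sample distance.

#' Specify one synthetic scene object
#'
#' @param object_class `"animal"`, `"lamp"` or `"molehill"`.
#' @param center `c(row, col)` position at the reference altitude.
#' @param area Footprint area in pixels at the reference altitude (default
#'   305, a chicken-sized 0.05 m2 body seen from 5 m).
#' @param core_offset Core temperature above background, degrees C.
#'   Defaults: animal 12, lamp 25, molehill 8.
#' @param shell_width Edge-gradient shell width in pixels at the reference
#'   altitude (animal profile only). Default 2.
#' @param velocity `c(d_row, d_col)` pixels per frame.
#' @return An object of class `object_spec`.
#' @export
object_spec <- function(object_class = c("animal", "lamp", "molehill"),
                        center, area = 305,
                        core_offset = NULL, shell_width = 2,
                        velocity = c(0, 0)) {
  object_class <- match.arg(object_class)
  if (is.null(core_offset)) {
    core_offset <- switch(object_class, animal = 12, lamp = 25, molehill = 8)
  }
  if (area < 1) stop("`area` must be >= 1 pixel")
  if (core_offset <= 0) stop("`core_offset` must be positive")
  structure(list(object_class = object_class, center = as.numeric(center),
                 area = area, core_offset = core_offset,
                 shell_width = shell_width, velocity = as.numeric(velocity)),
            class = "object_spec")
}

#' Specify a synthetic scene
#'
#' @param shape `c(height, width)` in pixels. Default `c(240, 320)`, a
#'   typical uncooled thermal-core resolution.
#' @param background Background temperature, degrees C. Default 19, inside
#'   the 15-23 degree band of cool-season field conditions.
#' @param noise_sd Per-pixel Gaussian noise standard deviation, degrees C.
#'   Default 1.5, the small-scale surface-temperature clutter of a vegetated
#'   field (sun-warmed tussocks and soil) plus sensor noise.
#' @param objects List of [object_spec]s. Objects may not overlap: the
#'   emulated scenes are sparse.
#' @param altitude Camera altitude in meters. Default 5.
#' @param ref_altitude Altitude at which object areas are quoted. Default 5.
#' @param offset_decay_length E-folding length in meters for the optional
#'   radiative decay of apparent core offsets above the reference altitude;
#'   `Inf` (default) disables it.
#' @param seed Integer RNG seed; identical specs with identical seeds render
#'   bitwise-identical frames.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(240L, 320L), background = 19,
                       noise_sd = 1.5, objects = list(), altitude = 5,
                       ref_altitude = 5, offset_decay_length = Inf,
                       seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (altitude <= 0 || ref_altitude <= 0) stop("altitudes must be positive")
  structure(list(shape = as.integer(shape), background = background,
                 noise_sd = noise_sd, objects = objects,
                 altitude = altitude, ref_altitude = ref_altitude,
                 offset_decay_length = offset_decay_length,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Radial temperature-offset profile of one object at a given altitude.
# Returns a function of distance-from-center (px) and the object's support
# radius (px beyond which the contribution is ~0).
object_profile <- function(obj, scale, offset_decay) {
  r <- sqrt(obj$area * scale^2 / pi)
  off <- obj$core_offset * offset_decay
  floor_px <- 0.7  # sub-pixel mixing floor
  switch(obj$object_class,
    animal = {
      # steep edge ramp (85% of the offset over the shell) plus a gentle
      # dome toward the center, so the radial profile -- and hence the
      # noise-free signature -- is strictly monotone
      s <- max(obj$shell_width * scale, floor_px)
      rr <- max(r, floor_px)
      list(fun = function(d) {
        edge <- pmin(1, pmax(0, (r - d) / s + 1))
        dome <- pmax(0, 1 - d / rr)
        off * (0.85 * edge + 0.15 * dome)
      },
      support = r + s + 1)
    },
    lamp = {
      list(fun = function(d) off * pmin(1, pmax(0, r + 0.5 - d)),
           support = r + 1.5)
    },
    molehill = {
      sigma <- max(r / 1.2, floor_px)
      list(fun = function(d) off * exp(-d^2 / (2 * sigma^2)),
           support = 3.5 * sigma)
    })
}

render_objects <- function(values, spec, centers) {
  h <- spec$shape[1L]; w <- spec$shape[2L]
  scale <- spec$ref_altitude / spec$altitude
  decay <- if (is.finite(spec$offset_decay_length)) {
    exp(-max(spec$altitude - spec$ref_altitude, 0) / spec$offset_decay_length)
  } else 1
  truth <- list()
  supports <- numeric(length(spec$objects))
  for (oi in seq_along(spec$objects)) {
    obj <- spec$objects[[oi]]
    ctr <- centers[[oi]]
    prof <- object_profile(obj, scale, decay)
    supports[oi] <- prof$support
    r0 <- max(1L, floor(ctr[1L] - prof$support))
    r1 <- min(h, ceiling(ctr[1L] + prof$support))
    c0 <- max(1L, floor(ctr[2L] - prof$support))
    c1 <- min(w, ceiling(ctr[2L] + prof$support))
    if (r0 > r1 || c0 > c1) {
      truth[[oi]] <- NULL
      next
    }
    rr <- r0:r1; cc <- c0:c1
    d <- sqrt(outer((rr - ctr[1L])^2, (cc - ctr[2L])^2, "+"))
    contrib <- prof$fun(d)
    dim(contrib) <- dim(d)  # pmin/pmax may drop matrix dims
    values[rr, cc] <- values[rr, cc] + contrib
    hot <- which(contrib > 0.5, arr.ind = TRUE)
    truth[[oi]] <- list(
      object_class = obj$object_class,
      label = if (obj$object_class == "animal") "animal" else "non_animal",
      center = c(row = ctr[1L], col = ctr[2L]),
      area_px = nrow(hot),
      pixels = if (nrow(hot)) cbind(row = rr[hot[, 1L]], col = cc[hot[, 2L]])
               else matrix(integer(0), 0, 2))
  }
  # overlap guard: supports of any two objects must not intersect
  if (length(spec$objects) >= 2L) {
    for (i in seq_along(spec$objects)) {
      for (j in seq_len(i - 1L)) {
        dd <- sqrt(sum((centers[[i]] - centers[[j]])^2))
        if (dd < supports[i] + supports[j]) {
          stop("objects ", j, " and ", i, " overlap; synthetic scenes are sparse")
        }
      }
    }
  }
  list(values = values, truth = truth)
}

#' Render a synthetic thermal scene
#'
#' @param spec A [scene_spec].
#' @return List with `frame` (a [thermal_frame] carrying the spec's
#'   altitude) and `truth`, a list with one record per object:
#'   `object_class`, `label`, `center`, `area_px` and `pixels` (the pixels
#'   whose rendered temperature contribution exceeds 0.5 degrees C).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$shape[1L]; w <- spec$shape[2L]
  values <- matrix(spec$background + stats::rnorm(h * w, 0, spec$noise_sd), h, w)
  res <- render_objects(values, spec, lapply(spec$objects, `[[`, "center"))
  list(frame = thermal_frame(res$values, frame_index = 0L,
                             altitude = spec$altitude),
       truth = res$truth)
}

#' Render a synthetic frame sequence with moving objects
#'
#' Objects advance by their velocity each frame and rescale with the
#' per-frame altitude; ground-truth tracks record each object's position in
#' every frame where any part of it is rendered inside the raster (an
#' object leaving the frame yields a truncated track, which is legal).
#'
#' @param spec A [scene_spec]; its `altitude` field is ignored in favour of
#'   the profile.
#' @param n_frames Number of frames.
#' @param altitude_profile Numeric vector of length `n_frames`, meters.
#' @return List with `sequence` (a [frame_sequence]) and `truth_tracks`, a
#'   list per object of data frames `frame`, `row`, `col`, `label`,
#'   `area_px`.
#' @export
generate_sequence <- function(spec, n_frames, altitude_profile) {
  stopifnot(inherits(spec, "scene_spec"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("`n_frames` must be >= 1")
  if (length(altitude_profile) != n_frames) {
    stop("`altitude_profile` must have one altitude per frame")
  }
  set.seed(spec$seed)
  h <- spec$shape[1L]; w <- spec$shape[2L]
  frames <- vector("list", n_frames)
  tracks <- replicate(length(spec$objects),
                      data.frame(frame = integer(0), row = numeric(0),
                                 col = numeric(0), label = character(0),
                                 area_px = integer(0)),
                      simplify = FALSE)
  for (f in seq_len(n_frames)) {
    fspec <- spec
    fspec$altitude <- altitude_profile[f]
    centers <- lapply(spec$objects, function(o) {
      o$center + (f - 1L) * o$velocity
    })
    values <- matrix(spec$background + stats::rnorm(h * w, 0, spec$noise_sd),
                     h, w)
    res <- render_objects(values, fspec, centers)
    frames[[f]] <- thermal_frame(res$values, frame_index = f - 1L,
                                 altitude = altitude_profile[f])
    for (oi in seq_along(res$truth)) {
      tr <- res$truth[[oi]]
      if (is.null(tr) || tr$area_px == 0L) next
      tracks[[oi]] <- rbind(tracks[[oi]],
                            data.frame(frame = f - 1L, row = tr$center[["row"]],
                                       col = tr$center[["col"]],
                                       label = tr$label,
                                       area_px = tr$area_px,
                                       stringsAsFactors = FALSE))
    }
  }
  list(sequence = frame_sequence(frames), truth_tracks = tracks)
}

# Randomized per-class object parameters for training-set generation.
# Areas and offsets are drawn around the three phenomenologies' defaults.
# Animal and molehill offset ranges deliberately overlap: apparent surface
# temperature depends on sun, coat and distance, so amplitude alone must
# not separate the classes -- discrimination has to come from the signature
# shape (steep edge vs. shallow mound), as it does in the field.
random_object <- function(object_class, center) {
  switch(object_class,
    animal = object_spec("animal", center,
                         area = stats::runif(1, 250, 360),
                         core_offset = stats::runif(1, 8, 14),
                         shell_width = stats::runif(1, 1.5, 3)),
    lamp = object_spec("lamp", center,
                       area = stats::runif(1, 40, 90),
                       core_offset = stats::runif(1, 20, 30)),
    molehill = object_spec("molehill", center,
                           area = stats::runif(1, 150, 320),
                           core_offset = stats::runif(1, 6, 12)))
}

#' Generate a labeled synthetic training set
#'
#' Renders one randomized single-object scene per training vector (on a
#' small patch), runs the full detection + signature + DCT chain, and
#' labels the resulting feature vector with the object's class. The default
#' class counts match a field-data regime in which the non-animal class,
#' being more heterogeneous, needs more examples. Objects that the detector
#' misses at the drawn altitude are resampled, up to `max_retries` per
#' vector.
#'
#' @param n_animal Number of animal vectors. Default 140.
#' @param n_nonanimal Number of non-animal vectors (lamps and molehills in
#'   roughly equal shares). Default 359.
#' @param seed Integer RNG seed.
#' @param altitude_range `c(low, high)` meters; each scene draws its
#'   altitude uniformly from this range. Default `c(4, 16)`.
#' @param n_coeff DCT coefficients per vector. Default 7.
#' @param noise_sd Scene noise, degrees C. Default 1.5.
#' @param offset_decay_length E-folding length (m) of the apparent-offset
#'   attenuation above the reference altitude. Default 12: distant objects
#'   look cooler, so high-altitude training examples are dimmer, only the
#'   warmest distractors survive detection there, and the classes genuinely
#'   crowd together with height.
#' @param params [detection_params] used on the rendered scenes.
#' @param max_retries Resampling budget per vector (altitude and object are
#'   redrawn each retry). Default 20.
#' @return A `knn_training_set` (see [fit_training_set]); the feature table
#'   it was built from is attached as attribute `"table"`.
#' @export
generate_training_set <- function(n_animal = 140L, n_nonanimal = 359L,
                                  seed = 1L, altitude_range = c(4, 16),
                                  n_coeff = 7L, noise_sd = 1.5,
                                  offset_decay_length = 12,
                                  params = detection_params(),
                                  max_retries = 20L) {
  if (n_animal < 1L || n_nonanimal < 1L) stop("class counts must be >= 1")
  set.seed(seed)
  classes <- c(rep("animal", n_animal),
               rep(c("lamp", "molehill"), length.out = n_nonanimal))
  patch <- c(96L, 96L)
  rows <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cls <- classes[i]
    fv <- NULL
    for (try in seq_len(max_retries)) {
      alt <- stats::runif(1, altitude_range[1L], altitude_range[2L])
      obj <- random_object(cls, center = c(48, 48) + stats::runif(2, -6, 6))
      sp <- scene_spec(shape = patch, background = stats::runif(1, 15, 23),
                       noise_sd = noise_sd, objects = list(obj),
                       altitude = alt, ref_altitude = 5,
                       offset_decay_length = offset_decay_length,
                       seed = sample.int(.Machine$integer.max %/% 2L, 1L))
      sc <- generate_scene(sp)
      blobs <- detect_objects(sc$frame, params)
      if (!length(blobs)) next
      ctr <- sc$truth[[1L]]$center
      dd <- vapply(blobs, function(b) {
        sqrt(sum((b$centroid - ctr)^2))
      }, numeric(1))
      blob <- blobs[[which.min(dd)]]
      sig <- extract_signature(sc$frame, blob)
      fv <- dct_parameterize(normalize_signature(sig), n_coeff = n_coeff,
                             label = if (cls == "animal") "animal"
                                     else "non_animal")
      break
    }
    if (is.null(fv)) {
      stop("object of class '", cls, "' stayed undetected after ",
           max_retries, " retries")
    }
    rows[[i]] <- fv
  }
  ts <- fit_training_set(rows)
  tab <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- data.frame(id = i)
    for (j in seq_len(ts$n_coeff)) r[[paste0("c", j - 1L)]] <- ts$x[i, j]
    r$label <- ts$labels[i]
    r
  }))
  attr(ts, "table") <- tab
  ts
}
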