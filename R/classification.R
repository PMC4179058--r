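#' Build a kNN training set from a labeled feature table
#'
#' Validates a table of DCT feature vectors with class labels and returns a
#' classifier object usable with [knn_classify] and [predict.knn_training_set].
#' Duplicate rows are preserved: kNN operates on the multiset of training
#' points, and tie distances are broken deterministically by the insertion
#' order of the rows.
#'
#' @param features Either a data frame with coefficient columns `c0`, `c1`,
#'   ... and a `label` column, or a list of labeled `feature_vector` objects.
#' @return An object of class `knn_training_set` with fields `x` (numeric
#'   matrix, one row per training vector), `labels` (character), `counts`
#'   (named vector of class counts), `n_coeff`.
#' @examples
#' tab <- data.frame(c0 = c(0, 1), c1 = c(0, 1),
#'                   label = c("animal", "non_animal"))
#' fit_training_set(tab)
#' @export
fit_training_set <- function(features) {
  if (is.data.frame(features)) {
    if (!nrow(features)) stop("feature table is empty")
    cc <- grep("^c[0-9]+$", names(features), value = TRUE)
    if (!length(cc)) stop("feature table has no coefficient columns c0, c1, ...")
    cc <- cc[order(as.integer(sub("^c", "", cc)))]
    x <- as.matrix(features[, cc, drop = FALSE])
    labels <- as.character(features$label)
  } else if (is.list(features) && length(features) &&
             all(vapply(features, inherits, logical(1), "feature_vector"))) {
    nc <- vapply(features, function(f) length(f$coefficients), integer(1))
    if (length(unique(nc)) != 1L) {
      stop("all feature vectors must share the same number of coefficients")
    }
    x <- do.call(rbind, lapply(features, `[[`, "coefficients"))
    labels <- vapply(features, function(f) {
      if (is.null(f$label)) NA_character_ else f$label
    }, character(1))
  } else {
    stop("`features` must be a data frame or a list of feature_vector objects")
  }
  if (anyNA(labels)) stop("every training vector must carry a label")
  bad <- setdiff(unique(labels), c("animal", "non_animal"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (length(unique(labels)) < 2L) {
    stop("training set must contain both classes (animal and non_animal)")
  }
  if (!all(is.finite(x))) stop("feature coefficients must be finite")
  structure(
    list(x = unname(x), labels = labels,
         counts = c(animal = sum(labels == "animal"),
                    non_animal = sum(labels == "non_animal")),
         n_coeff = ncol(x)),
    class = "knn_training_set"
  )
}

#' @export
print.knn_training_set <- function(x, ...) {
  cat(sprintf("<knn_training_set> %d vectors (%d animal, %d non-animal), %d coefficients\n",
              nrow(x$x), x$counts[["animal"]], x$counts[["non_animal"]],
              x$n_coeff))
  invisible(x)
}

#' @export
summary.knn_training_set <- function(object, ...) {
  print(object)
  cat("coefficient ranges:\n")
  print(apply(object$x, 2L, range))
  invisible(object)
}

#' Classify a feature vector by k nearest neighbours
#'
#' Finds the `k` training vectors at smallest Euclidean distance from the
#' query (distance ties at the k-th rank broken by training insertion
#' order), counts the animal votes `k_A`, and returns the likelihood ratio
#' `g_A = k_A / k` along with the majority-vote label. With `k` odd no vote
#' tie is possible and the label is animal exactly when `g_A > 0.5`.
#'
#' @param fv A `feature_vector`, or a plain numeric coefficient vector.
#' @param training A `knn_training_set`.
#' @param k Number of neighbours; default 11.
#' @return An object of class `knn_result` with fields `label`, `g_A`,
#'   `k_A`, `k`, `neighbor_distances`, `neighbor_indices`.
#' @export
knn_classify <- function(fv, training, k = 11L) {
  stopifnot(inherits(training, "knn_training_set"))
  q <- if (inherits(fv, "feature_vector")) fv$coefficients else as.numeric(fv)
  if (length(q) != training$n_coeff) {
    stop("query has ", length(q), " coefficients but the training set has ",
         training$n_coeff)
  }
  k <- as.integer(k)
  n <- nrow(training$x)
  if (k > n) stop("k = ", k, " exceeds the training-set size ", n)
  d <- sqrt(colSums((t(training$x) - q)^2))
  ord <- order(d)  # stable: ties keep training insertion order
  nb <- ord[seq_len(k)]
  k_A <- sum(training$labels[nb] == "animal")
  structure(
    list(label = if (k_A > k / 2) "animal" else "non_animal",
         g_A = k_A / k, k_A = k_A, k = k,
         neighbor_distances = d[nb], neighbor_indices = nb),
    class = "knn_result"
  )
}

#' @export
print.knn_result <- function(x, ...) {
  cat(sprintf("<knn_result> %s (k_A = %d / k = %d, g_A = %.3f)\n",
              x$label, x$k_A, x$k, x$g_A))
  invisible(x)
}

#' @describeIn fit_training_set Predict labels for new feature vectors; with
#'   `newdata` a matrix or data frame of coefficients, returns a data frame
#'   of `label`, `g_A`, `k_A` per row.
#' @param object A `knn_training_set`.
#' @param newdata Matrix/data frame of query coefficients, or a single
#'   `feature_vector`.
#' @param k Number of neighbours.
#' @param ... Unused.
#' @export
predict.knn_training_set <- function(object, newdata, k = 11L, ...) {
  if (inherits(newdata, "feature_vector")) {
    return(knn_classify(newdata, object, k = k))
  }
  x <- as.matrix(newdata)
  res <- lapply(seq_len(nrow(x)), function(i) {
    knn_classify(x[i, ], object, k = k)
  })
  data.frame(label = vapply(res, `[[`, character(1), "label"),
             g_A = vapply(res, `[[`, numeric(1), "g_A"),
             k_A = vapply(res, `[[`, integer(1), "k_A"))
}

#' Clamp a likelihood ratio away from 0 and 1
#'
#' The recursive belief update would get stuck at 0 or 1 if the classifier
#' ever returned a ratio of exactly 0 or 1, so the likelihood fed to it is
#' clamped to `[0.05, 0.95]`.
#'
#' @param g Likelihood ratio in `[0, 1]`.
#' @param bounds Clamp bounds, default `c(0.05, 0.95)`.
#' @return Clamped value.
#' @export
clamp_likelihood <- function(g, bounds = c(0.05, 0.95)) {
  stopifnot(all(g >= 0 & g <= 1))
  pmin(bounds[2L], pmax(bounds[1L], g))
}

#' Read / write labeled feature tables
#'
#' Feature tables are CSV files with a mandatory header and columns
#' `id, frame_index, row, col, area, M, c0...c<n-1>, label`.
#'
#' @param path CSV path.
#' @return `read_feature_table`: a data frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "frame_index", "row", "col", "area", "M", "c0", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("feature table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  tab
}

#' @rdname read_feature_table
#' @param table Data frame in the feature-table layout.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a feature-table row from pipeline objects
#'
#' @param id Row identifier.
#' @param blob A blob.
#' @param sig Its `thermal_signature`.
#' @param fv Its `feature_vector`.
#' @param label Optional class label.
#' @return One-row data frame in the feature-table layout.
#' @export
feature_table_row <- function(id, blob, sig, fv, label = NA_character_) {
  row <- data.frame(id = id, frame_index = blob$frame_index,
                    row = blob$centroid[["row"]], col = blob$centroid[["col"]],
                    area = blob$area, M = sig$M)
  for (i in seq_along(fv$coefficients)) {
    row[[paste0("c", i - 1L)]] <- fv$coefficients[i]
  }
  row$label <- label
  row
}
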