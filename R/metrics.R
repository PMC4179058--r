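#' Confusion matrix for the animal / non-animal decision
#'
#' Animal is the positive class: `tp` animals predicted animal, `fn`
#' animals predicted non-animal, `fp` non-animals predicted animal, `tn`
#' non-animals predicted non-animal.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("confusion matrix is empty")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(prediction = c("animal", "non_animal"),
                              observation = c("animal", "non_animal")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity (true positive rate) is the fraction of animals recognized;
#' specificity (true negative rate) the fraction of non-animals recognized.
#' Balanced accuracy, their mean, is robust to the class imbalance that
#' altitude-dependent detection loss induces (animals drop out of the data
#' faster than lamps at altitude, so plain accuracy would be dominated by
#' the non-animal class).
#'
#' @param cm A [confusion_matrix].
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `balanced_accuracy`, `sensitivity`, `specificity`, and the source
#'   counts.
#' @examples
#' confusion_metrics(confusion_matrix(tp = 2056, fp = 332, fn = 330, tn = 1663))
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) stop("no positive (animal) observations: TP + FN = 0")
  if (cm$fp + cm$tn == 0) stop("no negative (non-animal) observations: FP + TN = 0")
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$fp + cm$tn)
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  structure(
    list(accuracy = (cm$tp + cm$tn) / total,
         balanced_accuracy = (sens + spec) / 2,
         sensitivity = sens, specificity = spec,
         counts = cm),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy            %.3f\n", x$accuracy))
  cat(sprintf("balanced accuracy   %.3f\n", x$balanced_accuracy))
  cat(sprintf("sensitivity (TPR)   %.3f\n", x$sensitivity))
  cat(sprintf("specificity (TNR)   %.3f\n", x$specificity))
  invisible(x)
}

#' Detection performance
#'
#' Ratio of objects found by the detector to the true object count
#' (manual labels in a field recording, generator ground truth here).
#'
#' @param n_detected Number of detected objects.
#' @param n_actual True number of objects; must be positive.
#' @return The ratio `n_detected / n_actual`.
#' @export
detection_performance <- function(n_detected, n_actual) {
  if (n_actual <= 0) stop("detection performance is undefined for n_actual = 0")
  n_detected / n_actual
}

#' Pixel footprint of an object at altitude
#'
#' For a fixed camera field of view, the ground sample distance grows
#' linearly with altitude, so the pixel area covered by an object of fixed
#' physical size falls with the square of altitude:
#' `round(pixels_ref * (alt_ref / alt)^2)`.
#'
#' @param pixels_ref Pixel count at the reference altitude.
#' @param alt_ref Reference altitude in meters.
#' @param alt Altitude of interest in meters.
#' @return Rounded pixel count.
#' @examples
#' pixel_footprint(305, 5, 20)  # 19 px
#' @export
pixel_footprint <- function(pixels_ref, alt_ref, alt) {
  if (any(c(alt_ref, alt) <= 0)) stop("altitudes must be positive")
  round(pixels_ref * (alt_ref / alt)^2)
}

#' Per-altitude-range evaluation
#'
#' Splits per-object classification records into half-open altitude
#' intervals `[low, high)` and reports the metrics of each. The defaults
#' are the short range 3-10 m and far range 10-20 m; with half-open
#' intervals an object at exactly 10 m belongs to the far range only.
#'
#' @param records Data frame with columns `altitude`, `truth`, `predicted`
#'   (labels `"animal"` / `"non_animal"`).
#' @param ranges List of `c(low, high)` pairs. Default
#'   `list(c(3, 10), c(10, 20))`.
#' @return Named list of `metrics_report`s, one per non-empty range (names
#'   `"low-high"`); ranges with no records, or with an empty class margin,
#'   are omitted with a warning.
#' @export
evaluate_range <- function(records, ranges = list(c(3, 10), c(10, 20))) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  out <- list()
  for (rg in ranges) {
    nm <- paste0(rg[1L], "-", rg[2L])
    sel <- records$altitude >= rg[1L] & records$altitude < rg[2L]
    sub <- records[sel, , drop = FALSE]
    if (!nrow(sub)) {
      warning("altitude range ", nm, " contains no records; omitted")
      next
    }
    cm <- confusion_matrix(
      tp = sum(sub$truth == "animal" & sub$predicted == "animal"),
      fp = sum(sub$truth == "non_animal" & sub$predicted == "animal"),
      fn = sum(sub$truth == "animal" & sub$predicted == "non_animal"),
      tn = sum(sub$truth == "non_animal" & sub$predicted == "non_animal"))
    rep <- tryCatch(confusion_metrics(cm), error = function(e) {
      warning("altitude range ", nm, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(rep)) out[[nm]] <- rep
  }
  out
}
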