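# Independent oracles and small fixture builders shared across tests.

# direct double-sum type-II cosine transform, in the package's
# length-compensated orthonormal convention; written independently of the
# implementation's matrix route
dct_oracle <- function(x) {
  n <- length(x)
  vapply(seq_len(n) - 1L, function(k) {
    s <- if (k == 0L) sqrt(1 / n) else sqrt(2 / n)
    acc <- 0
    for (i in seq_len(n) - 1L) {
      acc <- acc + x[i + 1L] * cos(pi * (2 * i + 1) * k / (2 * n))
    }
    s * acc / sqrt(n)
  }, numeric(1))
}

# sort-based median (mean of the two central order statistics when even)
median_oracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2L == 1L) v[(n + 1L) %/% 2L] else (v[n %/% 2L] + v[n %/% 2L + 1L]) / 2
}

# exhaustive kNN: all pairwise distances, full sort, stable ties
knn_oracle <- function(query, x, labels, k) {
  d <- apply(x, 1L, function(row) sqrt(sum((row - query)^2)))
  nb <- order(d)[seq_len(k)]
  k_A <- sum(labels[nb] == "animal")
  list(k_A = k_A, g_A = k_A / k,
       label = if (k_A > k / 2) "animal" else "non_animal")
}

# brute-force 2x2 assignment: enumerate every gated one-to-one matching
# (including partial ones), keep the maximum number of matches, break ties
# by total distance
assign_oracle_2x2 <- function(centers, dets, radius) {
  d <- sqrt(outer(centers[, 1], dets[, 1], "-")^2 +
            outer(centers[, 2], dets[, 2], "-")^2)
  cands <- list(rbind(c(1, 1)), rbind(c(1, 2)), rbind(c(2, 1)),
                rbind(c(2, 2)), rbind(c(1, 1), c(2, 2)),
                rbind(c(1, 2), c(2, 1)))
  cands <- Filter(function(p) all(d[p] <= radius), cands)
  if (!length(cands)) return(NULL)
  card <- vapply(cands, nrow, integer(1))
  cands <- cands[card == max(card)]
  cost <- vapply(cands, function(p) sum(d[p]), numeric(1))
  cands[[which.min(cost)]]
}

# frame with a uniform background and a hot rectangle
rect_frame <- function(h = 9, w = 9, rows = 4:6, cols = 4:6,
                       bg = 20, hot = 30, frame_index = 0L) {
  v <- matrix(bg, h, w)
  v[rows, cols] <- hot
  thermal_frame(v, frame_index = frame_index)
}

# blob covering exactly the given mask
mask_blob <- function(mask, frame) {
  pix <- which(mask, arr.ind = TRUE)
  pix <- matrix(as.integer(pix), nrow(pix), 2L,
                dimnames = list(NULL, c("row", "col")))
  thermaltrack:::new_blob(pix, frame, frame$frame_index)
}

balacc_of <- function(truth, pred) {
  confusion_metrics(confusion_matrix(
    tp = sum(pred == "animal" & truth == "animal"),
    fp = sum(pred == "animal" & truth == "non_animal"),
    fn = sum(pred == "non_animal" & truth == "animal"),
    tn = sum(pred == "non_animal" & truth == "non_animal")))$balanced_accuracy
}

# small cached training sets reused across tests: one from the low-altitude
# regime, one spanning the full altitude range of the emulated recordings
small_training_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_training_set(n_animal = 40L, n_nonanimal = 90L,
                                      seed = 424L, altitude_range = c(4, 7))
    }
    cache
  }
})

fullrange_training_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_training_set(n_animal = 70L, n_nonanimal = 170L,
                                      seed = 424L, altitude_range = c(4, 16))
    }
    cache
  }
})
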