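# DCT parameterization of normalized thermal signatures.
#
# Convention: orthonormal type-II DCT with an additional 1/sqrt(N) scaling,
#   c_k = s_k / sqrt(N) * sum_{n=0}^{N-1} x_n cos(pi (2n+1) k / (2N)),
#   s_0 = sqrt(1/N), s_k = sqrt(2/N) for k > 0,
# so that coefficient 0 equals the sequence mean for any length. Signatures
# of different lengths (objects seen at different scales / altitudes) thus
# map to commensurable coefficients: a constant signal of value v yields
# c_0 = v whether it has 3 samples or 300. Truncation to the leading
# n_coeff coefficients gives a fixed-length, smooth low-pass description.

dct_matrix <- function(n) {
  k <- seq_len(n) - 1L
  m <- outer(k, k, function(k, nn) cos(pi * (2 * nn + 1) * k / (2 * n)))
  s <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
  m * s  # rows are the orthonormal cosine basis vectors
}

#' DCT parameterization of a normalized signature
#'
#' Computes the length-compensated type-II cosine transform of the
#' normalized sample sequence and retains the first `n_coeff` coefficients,
#' zero-padding when the sequence is shorter than `n_coeff`.
#'
#' @param normalized Numeric sample sequence (from [normalize_signature]).
#' @param n_coeff Number of coefficients to retain. Default 7, which
#'   captures at least 95% of the signature energy for typical animal
#'   signatures.
#' @param label Optional class label, `"animal"` or `"non_animal"`.
#' @return An object of class `feature_vector` with fields `coefficients`
#'   (length `n_coeff` exactly), `source_length`, `label`.
#' @export
dct_parameterize <- function(normalized, n_coeff = 7L, label = NULL) {
  x <- as.numeric(normalized)
  n <- length(x)
  if (n < 1L) stop("sequence must have length >= 1")
  n_coeff <- as.integer(n_coeff)
  full <- as.numeric(dct_matrix(n) %*% x) / sqrt(n)
  coeffs <- rep(0, n_coeff)
  m <- min(n, n_coeff)
  coeffs[seq_len(m)] <- full[seq_len(m)]
  if (!is.null(label)) label <- match.arg(label, c("animal", "non_animal"))
  structure(list(coefficients = coeffs, source_length = n, label = label),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> [%s] (N = %d%s)\n",
              paste(sprintf("%.3f", x$coefficients), collapse = ", "),
              x$source_length,
              if (is.null(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

#' Reconstruct a signature from truncated DCT coefficients
#'
#' Inverse transform of the retained coefficients at the requested length,
#' giving the smooth approximation that the truncated transform encodes.
#' When no truncation occurred (`length` equals the source length and
#' `n_coeff >= length`) the round trip is lossless.
#'
#' @param fv A `feature_vector`.
#' @param length Length of the reconstructed sequence (default: the source
#'   signature length).
#' @return Numeric vector of reconstructed samples.
#' @export
reconstruct_signature <- function(fv, length = fv$source_length) {
  stopifnot(inherits(fv, "feature_vector"))
  n <- as.integer(length)
  if (n < 1L) stop("`length` must be >= 1")
  coef_full <- rep(0, n)
  m <- min(n, base::length(fv$coefficients))
  coef_full[seq_len(m)] <- fv$coefficients[seq_len(m)]
  as.numeric(crossprod(dct_matrix(n), coef_full * sqrt(n)))
}

#' Energy fraction captured by leading DCT coefficients
#'
#' Fraction of the sequence's total squared-coefficient mass carried by the
#' first `n_coeff` coefficients, under the orthonormal transform (so by
#' Parseval's identity it equals the retained fraction of signal energy).
#'
#' @param normalized Numeric sample sequence.
#' @param n_coeff Number of retained coefficients.
#' @return Fraction in `[0, 1]`; an all-zero sequence is defined to be
#'   fully explained (returns 1).
#' @export
energy_fraction <- function(normalized, n_coeff = 7L) {
  x <- as.numeric(normalized)
  n <- length(x)
  if (n < 1L) stop("sequence must have length >= 1")
  a <- as.numeric(dct_matrix(n) %*% x)
  total <- sum(a^2)
  if (total == 0) return(1)
  m <- min(n, as.integer(n_coeff))
  sum(a[seq_len(m)]^2) / total
}
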