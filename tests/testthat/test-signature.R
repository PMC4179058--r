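test_that("outer and perimeter contours match hand-enumerated shapes", {
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  ring <- outer_contour(m1)
  expect_equal(sum(ring), 4L)
  expect_true(all(ring[cbind(c(2, 4, 3, 3), c(3, 3, 2, 4))]))
  expect_false(attr(ring, "clipped"))
  expect_equal(sum(perimeter_contour(m1)), 1L)  # single pixel is its own rim

  sq <- matrix(FALSE, 7, 7); sq[3:5, 3:5] <- TRUE
  expect_equal(sum(outer_contour(sq)), 12L)     # 3 per side, no corners
  per <- perimeter_contour(sq)
  expect_equal(sum(per), 8L)                    # all but the center
  expect_false(per[4, 4])

  line <- matrix(FALSE, 3, 7); line[2, 2:6] <- TRUE
  expect_equal(sum(perimeter_contour(line)), 5L)  # 1-wide: nothing interior

  full <- matrix(TRUE, 3, 3)
  ringf <- outer_contour(full)
  expect_equal(sum(ringf), 0L)
  expect_true(attr(ringf, "clipped"))
})

test_that("contours agree with cross-kernel morphology from an independent library", {
  skip_if_not_installed("EBImage")
  kern <- EBImage::makeBrush(3, "diamond")
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(FALSE, 12, 12)
    m[4:9, 4:9] <- matrix(runif(36) < 0.6, 6, 6)
    if (!any(m)) m[6, 6] <- TRUE
    ref_ring <- (EBImage::dilate(m * 1, kern) == 1) & !m
    expect_identical(unname(ref_ring),
                     matrix(as.logical(outer_contour(m)), 12, 12))
    ref_per <- m & !(EBImage::erode(m * 1, kern) == 1)
    expect_identical(unname(ref_per), perimeter_contour(m))
  }
})

test_that("the 3x3 hot square yields the canonical signature", {
  fr <- rect_frame(h = 9, w = 9, rows = 4:6, cols = 4:6, bg = 20, hot = 30)
  blob <- detect_objects(fr, detection_params())[[1]]
  sig <- extract_signature(fr, blob)
  expect_equal(sig$samples, c(20, 30, 30))
  expect_equal(sig$contour_sizes, c(12L, 8L, 1L))
  expect_equal(sig$M, 1L)
  expect_false(sig$border_clipped)
})

test_that("contour peeling partitions the blob and terminates", {
  set.seed(32)
  for (rep in 1:6) {
    v <- matrix(20, 14, 14)
    rr <- sample(3:9, 1); cc <- sample(3:9, 1)
    v[rr:(rr + sample(1:4, 1)), cc:(cc + sample(1:4, 1))] <- 30
    v[sample(4:11, 2), sample(4:11, 2)] <- 30  # some extra warts
    fr <- thermal_frame(v)
    for (blob in detect_objects(fr, detection_params(min_area = 1))) {
      sig <- extract_signature(fr, blob)
      # interior contour sizes partition the blob area
      expect_equal(sum(sig$contour_sizes[-1]), blob$area)
      expect_lte(sig$M + 1L, blob$area)
      expect_equal(length(sig$samples), sig$M + 2L)
      expect_true(all(sig$contour_sizes[-1] >= 1L))
    }
  }
})

test_that("a radial gradient gives a strictly increasing interior signature", {
  n <- 21
  d <- sqrt(outer((1:n - 11)^2, (1:n - 11)^2, "+"))
  v <- 20 + pmax(0, 8 - d)  # cone peaking at the center
  dim(v) <- dim(d)
  fr <- thermal_frame(v)
  blob <- detect_objects(fr, detection_params(c = 2))[[1]]
  sig <- extract_signature(fr, blob)
  expect_gt(sig$M, 2L)
  expect_true(all(diff(sig$samples[-1]) > 0))
  # any uniform blob: interior samples all equal regardless of shape
  fru <- rect_frame(h = 11, w = 11, rows = 3:8, cols = 4:7)
  blobu <- detect_objects(fru)[[1]]
  sigu <- extract_signature(fru, blobu)
  expect_equal(length(unique(sigu$samples[-1])), 1L)
})

test_that("signatures are invariant to translation and right-angle rotation", {
  base <- matrix(20, 13, 13)
  base[4:7, 5:9] <- 30; base[5:6, 6:8] <- 33; base[4, 5] <- 26
  sig_of <- function(v) {
    fr <- thermal_frame(v)
    extract_signature(fr, detect_objects(fr, detection_params())[[1]])
  }
  ref <- sig_of(base)
  shifted <- matrix(20, 13, 13)
  shifted[2:13, 2:13] <- base[1:12, 1:12]
  expect_equal(sig_of(shifted)$samples, ref$samples)
  expect_equal(sig_of(shifted)$contour_sizes, ref$contour_sizes)
  for (rot in 1:3) {
    v <- base
    for (i in seq_len(rot)) v <- t(v)[ncol(v):1, ]  # 90-degree rotation
    expect_equal(sig_of(v)$samples, ref$samples)
    expect_equal(sig_of(v)$contour_sizes, ref$contour_sizes)
  }
})

test_that("border-touching blobs clip the outer ring and fall back sanely", {
  v <- matrix(20, 5, 5); v[1:2, 1:2] <- 30
  fr <- thermal_frame(v)
  blob <- detect_objects(fr, detection_params())[[1]]
  sig <- extract_signature(fr, blob)
  expect_true(sig$border_clipped)
  expect_equal(sig$samples[1], 20)  # ring mean from the available pixels
  # full-frame blob: no ring at all; i = -1 falls back to the first peel
  vf <- matrix(30, 3, 3)
  frf <- thermal_frame(vf)
  maskf <- matrix(TRUE, 3, 3)
  blobf <- mask_blob(maskf, frf)
  sigf <- extract_signature(frf, blobf)
  expect_equal(sigf$samples[1], sigf$samples[2])
})

test_that("normalization zeroes the ring sample and removes constant warming", {
  expect_equal(normalize_signature(c(20, 30, 30)), c(0, 10, 10))
  z <- c(0, 3, 5)
  expect_equal(normalize_signature(z), z)
  set.seed(33)
  for (rep in 1:10) {
    s <- rnorm(sample(2:12, 1), 20, 6)
    expect_equal(normalize_signature(s + 7), normalize_signature(s))
  }
  expect_error(normalize_signature(5), "at least 2")
})

test_that("the full feature pipeline ignores absolute scene temperature", {
  fr <- rect_frame(h = 11, w = 11, rows = 4:8, cols = 4:8, bg = 18, hot = 29)
  fr$values[6, 6] <- 33
  fv_of <- function(frame) {
    b <- detect_objects(frame, detection_params())[[1]]
    dct_parameterize(normalize_signature(extract_signature(frame, b)))
  }
  warm <- thermal_frame(fr$values + 6.25)
  expect_equal(fv_of(warm)$coefficients, fv_of(fr)$coefficients)
})
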