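test_that("dynamic threshold is the median plus the offset", {
  expect_equal(dynamic_threshold(thermal_frame(matrix(20, 3, 3)), c = 5), 25)
  # skewed 3x3 frame: hot pixels must not drag the threshold up
  v <- matrix(c(10, 10, 10, 10, 12, 30, 30, 10, 10), 3, 3)
  fr <- thermal_frame(v)
  expect_equal(median_oracle(as.vector(v)), 10)
  expect_equal(dynamic_threshold(fr, c = 5), 15)
  # random frames against the sort-based oracle, odd and even pixel counts
  set.seed(21)
  for (dims in list(c(3, 5), c(4, 4), c(7, 6))) {
    v <- matrix(rnorm(prod(dims), 20, 4), dims[1], dims[2])
    expect_equal(dynamic_threshold(thermal_frame(v), c = 5),
                 median_oracle(as.vector(v)) + 5)
  }
})

test_that("threshold is a spatial order statistic and shifts with constant warming", {
  set.seed(22)
  v <- matrix(rnorm(48, 20, 3), 6, 8)
  fr <- thermal_frame(v)
  perm <- matrix(sample(v), 6, 8)
  expect_equal(dynamic_threshold(thermal_frame(perm), 5),
               dynamic_threshold(fr, 5))
  th <- dynamic_threshold(fr, 5)
  warmed <- thermal_frame(v + 7.5)
  expect_equal(dynamic_threshold(warmed, 5), th + 7.5)
  expect_identical(segment_frame(warmed, th + 7.5), segment_frame(fr, th))
})

test_that("segmentation is a strict elementwise comparison", {
  fr <- rect_frame(bg = 20, hot = 30)
  expect_false(any(segment_frame(fr, 31)))
  single <- thermal_frame(matrix(c(rep(20, 8), 30), 3, 3))
  mask <- segment_frame(single, 25)
  expect_equal(sum(mask), 1L)
  expect_true(mask[3, 3])
  # boundary: a pixel exactly at the threshold is background
  expect_false(any(segment_frame(thermal_frame(matrix(25, 2, 2)), 25)))
  set.seed(23)
  v <- matrix(rnorm(60, 20, 5), 6, 10)
  expect_identical(segment_frame(thermal_frame(v), 22), v > 22)
})

test_that("blob extraction matches connected-component oracles", {
  # two 2-pixel components separated by a cold row
  v <- matrix(20, 5, 5)
  v[1, 2:3] <- 30
  v[4, c(2, 4)] <- 30  # gap: 4-disconnected, but (4,2)/(4,4) not adjacent
  v[4, 3] <- 30        # make one 3-pixel run
  fr <- thermal_frame(v)
  mask <- segment_frame(fr, 25)
  blobs <- extract_blobs(mask, fr, detection_params(min_area = 2))
  expect_length(blobs, 2L)
  expect_equal(vapply(blobs, `[[`, integer(1), "area"), c(2L, 3L))
  # sorted by bounding-box corner
  expect_lte(blobs[[1]]$bounding_box[["min_row"]],
             blobs[[2]]$bounding_box[["min_row"]])

  skip_if_not_installed("EBImage")
  # 4-connectivity labeling agrees with EBImage::bwlabel on random masks
  set.seed(24)
  for (rep in 1:5) {
    m <- matrix(runif(200) < 0.35, 10, 20)
    ours <- thermaltrack:::label_components(m, 4L)
    ref <- EBImage::bwlabel(m * 1)
    expect_equal(max(ours), max(ref))
    # identical partition: same co-membership for every foreground pair
    expect_equal(length(unique(ours[m])), length(unique(ref[ref > 0])))
    relabel <- tapply(ref[m], ours[m], function(v) length(unique(v)))
    expect_true(all(relabel == 1))
  }
})

test_that("connectivity 8 joins diagonals that connectivity 4 separates", {
  v <- matrix(20, 4, 4)
  v[1, 1] <- 30; v[2, 2] <- 30
  fr <- thermal_frame(v)
  mask <- segment_frame(fr, 25)
  p8 <- detection_params(min_area = 1, connectivity = 8)
  p4 <- detection_params(min_area = 1, connectivity = 4)
  expect_length(extract_blobs(mask, fr, p8), 1L)
  expect_length(extract_blobs(mask, fr, p4), 2L)
})

test_that("blob filtering and degenerate inputs behave as specified", {
  fr <- rect_frame()
  empty <- matrix(FALSE, 9, 9)
  expect_identical(extract_blobs(empty, fr, detection_params()), list())
  # area-1 component removed at min_area 2
  v <- matrix(20, 5, 5); v[3, 3] <- 30
  fr1 <- thermal_frame(v)
  expect_identical(detect_objects(fr1, detection_params(min_area = 2)), list())
  expect_length(detect_objects(fr1, detection_params(min_area = 1)), 1L)
  expect_error(extract_blobs(matrix(FALSE, 2, 2), fr, detection_params()),
               "same shape")
  expect_error(detection_params(c = 0), "positive")
  expect_error(detection_params(connectivity = 6), "4 or 8")
})

test_that("every blob pixel exceeds the threshold and none is missed", {
  set.seed(25)
  for (rep in 1:5) {
    v <- matrix(rnorm(300, 20, 4), 15, 20)
    fr <- thermal_frame(v)
    th <- dynamic_threshold(fr, 2)
    mask <- segment_frame(fr, th)
    params <- detection_params(c = 2, min_area = 2)
    blobs <- extract_blobs(mask, fr, params)
    covered <- matrix(FALSE, 15, 20)
    for (b in blobs) {
      expect_true(all(fr$values[b$pixels] > th))
      expect_gte(b$area, params$min_area)
      covered[b$pixels] <- TRUE
      expect_true(b$centroid[["row"]] >= b$bounding_box[["min_row"]] &&
                  b$centroid[["row"]] <= b$bounding_box[["max_row"]])
    }
    # any uncovered hot pixel must sit in a component smaller than min_area
    labels <- thermaltrack:::label_components(mask, 8L)
    for (p in which(mask & !covered)) {
      expect_lt(sum(labels == labels[p]), params$min_area)
    }
  }
})
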