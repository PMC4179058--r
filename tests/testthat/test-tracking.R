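det <- function(row, col, g = 0.6) data.frame(row = row, col = col, g_A = g)

test_that("guess regions extrapolate the last movement", {
  tr <- thermaltrack:::new_track(1L, 0L, 10, 10, 0.6, tracker_params())
  expect_equal(unname(predict_guess_region(tr)$center), c(10, 10))
  tracks <- associate_frame(list(tr), det(12, 14), 1L)
  gr <- predict_guess_region(tracks[[1]])
  expect_equal(unname(gr$center), c(14, 18))
  expect_equal(gr$radius, 190)
  # zero movement predicts in place
  tr2 <- thermaltrack:::new_track(2L, 0L, 10, 10, 0.6, tracker_params())
  tracks2 <- associate_frame(list(tr2), det(10, 10), 1L)
  expect_equal(unname(predict_guess_region(tracks2[[1]])$center), c(10, 10))
})

test_that("the belief update follows Bayes' rule with the two-class evidence", {
  expect_equal(update_belief(0.5, 0.5), 0.5)
  expect_equal(update_belief(0.5, 6 / 11), 6 / 11)
  expect_equal(update_belief(0.8, 0.95), 0.76 / 0.77)
  # single-step monotonicity
  for (bel in c(0.2, 0.5, 0.8)) {
    expect_gt(update_belief(bel, 0.7), bel)
    expect_lt(update_belief(bel, 0.3), bel)
    expect_equal(update_belief(bel, 0.5), bel)
  }
})

test_that("belief stays inside (0,1), converges, and is order-invariant", {
  set.seed(61)
  for (rep in 1:10) {
    gs <- clamp_likelihood(runif(sample(3:40, 1)))
    bel <- 0.5
    for (g in gs) {
      bel <- update_belief(bel, g)
      expect_gt(bel, 0); expect_lt(bel, 1)
    }
    bel_perm <- 0.5
    for (g in sample(gs)) bel_perm <- update_belief(bel_perm, g)
    expect_equal(bel_perm, bel, tolerance = 1e-9)
  }
  # constant evidence converges geometrically to the matching endpoint
  bel <- 0.5
  for (i in 1:60) bel <- update_belief(bel, 0.95)
  expect_gt(bel, 1 - 1e-11)
  bel <- 0.5
  for (i in 1:60) bel <- update_belief(bel, 0.05)
  expect_lt(bel, 1e-11)
})

test_that("the four-frame association walkthrough creates three tracks", {
  p <- tracker_params(radius = 50)
  tracks <- list()
  # frame 1: one detection -> first track
  tracks <- associate_frame(tracks, det(100, 100), 1L, p)
  expect_length(tracks, 1L)
  # frame 2: one inside the first track's region, one far away -> second track
  tracks <- associate_frame(tracks, rbind(det(105, 103), det(300, 400)), 2L, p)
  expect_length(tracks, 2L)
  expect_equal(nrow(tracks[[1]]$members), 2L)
  # frame 3: only the second track is extended; the first goes missing
  tracks <- associate_frame(tracks, det(302, 401), 3L, p)
  expect_equal(nrow(tracks[[2]]$members), 2L)
  expect_equal(tracks[[1]]$missed, 1L)
  # frame 4: two continuations plus a third new detection -> third track
  tracks <- associate_frame(
    tracks, rbind(det(108, 108), det(305, 403), det(50, 300)), 4L, p)
  expect_length(tracks, 3L)
  expect_equal(vapply(tracks, function(t) nrow(t$members), integer(1)),
               c(3L, 3L, 1L))
})

test_that("gating rejects far detections and ages the track", {
  p <- tracker_params(radius = 20, max_missed = 1)
  tracks <- associate_frame(list(), det(50, 50), 1L, p)
  tracks <- associate_frame(tracks, det(50, 71), 2L, p)  # distance 21 > 20
  expect_length(tracks, 2L)
  expect_equal(tracks[[1]]$missed, 1L)
  expect_equal(tracks[[1]]$status, "active")
  tracks <- associate_frame(tracks, data.frame(row = numeric(0),
                                               col = numeric(0),
                                               g_A = numeric(0)), 3L, p)
  expect_equal(tracks[[1]]$status, "terminated")  # missed 2 > max 1
  expect_equal(tracks[[2]]$missed, 1L)
})

test_that("two-track two-detection assignment matches the brute-force pairing", {
  # sparse-scene geometry (tracks separated by more than twice the gate, as
  # in the recordings the gate radius was chosen for): each detection falls
  # near one track, near none, or both contend for the same track -- in all
  # of these the exhaustive gated pairing is unique and greedy must find it
  set.seed(62)
  for (rep in 1:20) {
    p <- tracker_params(radius = 60)
    base1 <- c(runif(1, 0, 100), runif(1, 0, 100))
    base2 <- base1 + c(150, 150)  # > 2 * radius apart
    t1 <- thermaltrack:::new_track(1L, 0L, base1[1], base1[2], 0.6, p)
    t2 <- thermaltrack:::new_track(2L, 0L, base2[1], base2[2], 0.4, p)
    anchor <- list(base1, base2, base1 + 500)  # near t1, near t2, far away
    pos <- vapply(1:2, function(j) {
      unlist(anchor[[sample(3, 1)]]) + runif(2, -40, 40)
    }, numeric(2))
    dets <- data.frame(row = pos[1, ], col = pos[2, ], g_A = c(0.7, 0.3))
    centers <- rbind(predict_guess_region(t1, p)$center,
                     predict_guess_region(t2, p)$center)
    want <- assign_oracle_2x2(centers, cbind(dets$row, dets$col), p$radius)
    got <- associate_frame(list(t1, t2), dets, 1L, p)
    for (ti in 1:2) {
      m <- got[[ti]]$members
      if (!is.null(want) && ti %in% want[, 1]) {
        j <- want[want[, 1] == ti, 2]
        expect_equal(nrow(m), 2L)
        expect_equal(m$row[2], dets$row[j])
      } else {
        expect_equal(nrow(m), 1L)
      }
    }
  }
})

test_that("track counts are conserved frame by frame", {
  set.seed(63)
  p <- tracker_params(radius = 30, max_missed = 2)
  tracks <- list()
  for (f in 1:15) {
    n_new <- sample(0:3, 1)
    dets <- data.frame(row = runif(n_new, 0, 400), col = runif(n_new, 0, 400),
                       g_A = runif(n_new))
    before_ids <- length(tracks)
    active_before <- sum(vapply(tracks, function(t) t$status == "active",
                                logical(1)))
    tracks <- associate_frame(tracks, dets, f, p)
    matched <- sum(vapply(tracks[seq_len(before_ids)], function(t) {
      nrow(t$members) > 0 && t$members$frame[nrow(t$members)] == f
    }, logical(1)))
    expect_equal(length(tracks), before_ids + n_new - matched)
  }
})

test_that("identification relabels members from the final belief", {
  p <- tracker_params(min_track_points = 2)
  tr <- thermaltrack:::new_track(1L, 0L, 10, 10, 0.3, p)
  for (f in 1:5) {
    tr <- associate_frame(list(tr), det(10 + f, 10, g = 0.9), f, p)[[1]]
  }
  out <- identify_track(tr, p)
  expect_equal(out$final_label, "animal")
  expect_true(all(out$members$label == "animal"))
  expect_true(out$identified)
  # belief ending exactly at 0.5 is a non-animal call (strict exceed)
  tr2 <- thermaltrack:::new_track(2L, 0L, 5, 5, 0.5, p)
  out2 <- identify_track(tr2, p)
  expect_equal(out2$final_label, "non_animal")
  expect_false(out2$identified)  # only 1 member
})

test_that("a weak-then-strong evidence pattern flips the belief across 0.5", {
  # distant-approach scenario: early likelihoods below 0.5, later above
  gs <- c(0.3, 0.4, 0.45, 0.6, 0.8, 0.9, 0.9)
  bel <- numeric(length(gs)); b <- 0.5
  for (i in seq_along(gs)) {
    b <- update_belief(b, clamp_likelihood(gs[i])); bel[i] <- b
  }
  expect_lt(bel[3], 0.5)
  expect_gt(bel[length(gs)], 0.5)
  dets <- lapply(seq_along(gs), function(f) {
    data.frame(frame = f, row = 10 + f, col = 10, g_A = gs[f])
  })
  tracks <- track_sequence(dets, tracker_params(min_track_points = 5))
  expect_length(tracks, 1L)
  expect_equal(tracks[[1]]$final_label, "animal")
  expect_true(tracks[[1]]$identified)
})
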