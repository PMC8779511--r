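traj_from_centers <- function(centers, w = 50, h = 120) {
  data.frame(frame = seq_len(nrow(centers)) - 1L,
             x = centers[, 1] - w / 2, y = centers[, 2] - h / 2,
             w = w, h = h)
}

test_that("center spread matches the eigen-decomposition of known clusters", {
  same <- traj_from_centers(matrix(c(10, 10, 10, 20, 20, 20), 3, 2))
  expect_equal(center_spread(same), 0)
  line <- traj_from_centers(cbind(1:10, 2 * (1:10) + 3))
  expect_equal(center_spread(line), 0, tolerance = 1e-20)
  corners <- traj_from_centers(matrix(c(0, 2, 0, 2, 0, 0, 2, 2), 4, 2))
  expect_equal(center_spread(corners), 16 / 9)
  expect_error(center_spread(traj_from_centers(matrix(c(1, 1), 1, 2))),
               "two points")
})

test_that("eigenvalue product equals the covariance determinant (oracle identity)", {
  set.seed(51)
  for (rep in 1:100) {
    n <- sample(3:210, 1)
    pts <- cbind(rnorm(n, sd = runif(1, 0.1, 20)),
                 rnorm(n, sd = runif(1, 0.1, 20)))
    tr <- traj_from_centers(pts)
    expect_equal(center_spread(tr), det(cov(pts)), tolerance = 1e-9)
  }
})

test_that("scale spread tracks size changes and ignores position", {
  const <- data.frame(frame = 0:9, x = 1:10 * 5, y = (1:10)^2, w = 50,
                      h = 120)
  expect_equal(scale_spread(const), 0)       # pure translation
  expect_gt(center_spread(const), 0)         # features decouple
  alt <- data.frame(frame = 0:9, x = 0, y = 0,
                    w = rep(c(50, 60), 5), h = rep(c(120, 140), 5))
  pts <- cbind(alt$w / 2, alt$h / 2)
  expect_equal(scale_spread(alt), det(cov(pts)))
})

test_that("center spread is invariant under global translation", {
  set.seed(52)
  pts <- cbind(rnorm(50, sd = 4), rnorm(50, sd = 2))
  t1 <- traj_from_centers(pts)
  t2 <- traj_from_centers(pts + matrix(c(123, -45), 50, 2, byrow = TRUE))
  expect_equal(center_spread(t1), center_spread(t2), tolerance = 1e-9)
})

test_that("flow intensity obeys the hand-computed identities", {
  box <- list(x = 2, y = 2, w = 6, h = 6)
  zero <- flow_field(matrix(127, 12, 12), matrix(127, 12, 12))
  expect_equal(flow_intensity_frame(zero, box), 0)

  uni <- flow_field(matrix(147, 12, 12), matrix(107, 12, 12))
  expect_equal(flow_intensity_frame(uni, box), sqrt(800))

  # half the box at 137, half at 127, vertical still -> Ix = 5, Ixy = 5
  h <- matrix(127, 12, 12)
  h[3:5, 3:8] <- 137  # upper half of the 6x6 box (rows 2..4 0-based)
  half <- flow_field(h, matrix(127, 12, 12))
  expect_equal(flow_intensity_frame(half, box), 5)

  # doubling the deviation doubles the intensity exactly
  d1 <- flow_field(matrix(127 + 10, 12, 12), matrix(127 - 5, 12, 12))
  d2 <- flow_field(matrix(127 + 20, 12, 12), matrix(127 - 10, 12, 12))
  expect_equal(flow_intensity_frame(d2, box),
               2 * flow_intensity_frame(d1, box))

  # values outside the box are irrelevant
  hh <- matrix(runif(144, 0, 255), 12, 12)
  hh[3:8, 3:8] <- 147
  vv <- matrix(runif(144, 0, 255), 12, 12)
  vv[3:8, 3:8] <- 107
  expect_equal(flow_intensity_frame(flow_field(hh, vv), box), sqrt(800))

  expect_error(flow_intensity_frame(zero, list(x = 100, y = 100, w = 5,
                                               h = 5)), "intersect")
})

test_that("window intensity is the mean of per-frame intensities", {
  box <- data.frame(x = 0, y = 0, w = 10, h = 10)
  f0 <- flow_field(matrix(127, 10, 10), matrix(127, 10, 10))
  f10 <- flow_field(matrix(137, 10, 10), matrix(127, 10, 10))
  expect_equal(flow_intensity_window(list(f0, f0), rbind(box, box)), 0)
  expect_equal(flow_intensity_window(list(f0, f10), rbind(box, box)), 5)
  expect_error(flow_intensity_window(list(f0), rbind(box, box)),
               "equal length")
  # direct-sum oracle on a longer sinusoidal window
  set.seed(53)
  devs <- round(20 * sin(2 * pi * (0:59) / 30))
  flows <- lapply(devs, function(d)
    flow_field(matrix(127 + d, 10, 10), matrix(127, 10, 10)))
  boxes <- do.call(rbind, replicate(60, box, simplify = FALSE))
  expect_equal(flow_intensity_window(flows, boxes),
               sum(abs(devs)) / 60, tolerance = 1e-9)
})

test_that("feature extraction needs a full window and bundles all three", {
  cfg <- pipeline_config(activity_window_frames = 50)
  sc <- small_scene("still_stand", "Long", n_frames = 50, seed = 13,
                    frame_shape = c(160, 120), render_thermal = FALSE)
  track <- track_from_boxes(sc$detections)
  feats <- extract_features(track, sc$flows, cfg)
  expect_s3_class(feats, "activity_features")
  expect_gte(feats$center_spread, 0)
  expect_gte(feats$flow_intensity, 0)

  short_track <- track_from_boxes(sc$detections[sc$detections$frame < 49, ])
  err <- tryCatch(extract_features(short_track, sc$flows, cfg),
                  condition = identity)
  expect_s3_class(err, "thermotrack_window_not_full")
})

test_that("a stretching person scores higher on every feature than a still one", {
  cfg <- pipeline_config(activity_window_frames = 100)
  still <- small_scene("still_stand", "Long", n_frames = 100, seed = 14,
                       frame_shape = c(160, 120), render_thermal = FALSE)
  stretch <- small_scene("stretch_stand", "Long", n_frames = 100, seed = 14,
                         frame_shape = c(160, 120), render_thermal = FALSE)
  f_still <- extract_features(track_from_boxes(still$detections),
                              still$flows, cfg)
  f_str <- extract_features(track_from_boxes(stretch$detections),
                            stretch$flows, cfg)
  expect_gt(f_str$center_spread, f_still$center_spread)
  expect_gt(f_str$scale_spread, f_still$scale_spread)
  expect_gt(f_str$flow_intensity, f_still$flow_intensity)
})
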