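test_that("scenes are bit-identical across runs with the same seed", {
  script <- scene_script(persons = list(scene_person("gesture_stand",
                                                     "Short")),
                         frame_shape = c(120, 100), n_frames = 20, seed = 42,
                         noise = list(jitter_sd = 0.5, fp_rate = 0.1))
  s1 <- generate_scene(script)
  s2 <- generate_scene(script)
  expect_identical(s1$thermal, s2$thermal)
  expect_identical(s1$flows, s2$flows)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$keypoints, s2$keypoints)
  s3 <- generate_scene(scene_script(persons = script$persons,
                                    frame_shape = c(120, 100),
                                    n_frames = 20, seed = 43,
                                    noise = list(jitter_sd = 0.5,
                                                 fp_rate = 0.1)))
  expect_false(identical(s1$detections, s3$detections))
})

test_that("scripts validate temperature ordering and packing", {
  expect_error(scene_script(persons = list(scene_person(
    skin_temperature = 30, clothes_temperature = 33))),
    "skin > clothes > background")
  p1 <- scene_person(center = c(50, 60))
  p2 <- scene_person(center = c(52, 60))
  expect_error(scene_script(persons = list(p1, p2), frame_shape = c(120, 100)),
               "packing limit")
})

test_that("ground-truth insulation equals the formula on script temperatures", {
  sc <- small_scene("still_sit", "Long", n_frames = 5, seed = 3,
                    frame_shape = c(120, 100), render_thermal = FALSE,
                    render_flow = FALSE)
  gt <- sc$ground_truth$persons
  expect_equal(gt$true_icl,
               compute_icl(gt$skin_temperature, gt$clothes_temperature,
                           sc$ground_truth$background_temperature))
})

test_that("noiseless scenes are tracked perfectly", {
  sc <- generate_scene(scene_script(
    persons = list(scene_person("still_sit", "Long",
                                center = c(50, 75)),
                   scene_person("walk", "Short", center = c(150, 75))),
    frame_shape = c(200, 150), n_frames = 60, seed = 5),
    render_thermal = FALSE, render_flow = FALSE)
  st <- track_detections(sc$detections)
  cnt <- evaluate_tracking(sc$ground_truth$boxes, track_boxes(st))
  expect_equal(compute_mota(cnt), 100)
  expect_equal(cnt$idsw, 0L)
})

test_that("thermal rendering is quantized to the camera step", {
  sc <- small_scene("still_sit", "Long", n_frames = 3, seed = 6,
                    frame_shape = c(120, 100))
  q <- sc$script$quantization_step
  vals <- sc$thermal[[1]]
  expect_true(all(abs(vals / q - round(vals / q)) < 1e-9))
})

test_that("activity dataset is balanced, deterministic and level-separated", {
  ds <- generate_activity_dataset(6, seed = 17)
  expect_equal(nrow(ds), 18L)
  expect_equal(unname(table(ds$label)[c("low", "moderate", "high")]),
               rep(6L, 3), ignore_attr = TRUE)
  ds2 <- generate_activity_dataset(6, seed = 17)
  expect_identical(ds, ds2)
  med <- aggregate(cbind(center_spread, scale_spread, flow_intensity)
                   ~ label, ds, median)
  med <- med[match(c("low", "moderate", "high"), med$label), ]
  for (col in c("center_spread", "scale_spread", "flow_intensity")) {
    expect_lt(med[1, col], med[2, col])
    expect_lt(med[2, col], med[3, col])
  }
})

test_that("emitted artifacts round-trip through the readers", {
  sc <- small_scene("gesture_stand", "Short", n_frames = 8, seed = 19,
                    frame_shape = c(120, 100),
                    noise = list(jitter_sd = 0.4))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  back <- read_scene(dir)
  expect_equal(back$detections, sc$detections, tolerance = 1e-12)
  expect_equal(back$ground_truth$boxes[, c("frame", "id", "x", "y", "w",
                                           "h")],
               sc$ground_truth$boxes[, c("frame", "id", "x", "y", "w",
                                         "h")],
               ignore_attr = TRUE, tolerance = 1e-12)
  # flow PNGs are integer-exact
  expect_equal(back$flows[[3]]$horizontal, sc$flows[[3]]$horizontal,
               ignore_attr = TRUE)
  # float32 thermal storage is exact far below the quantization step
  expect_lt(max(abs(back$thermal[[1]] - sc$thermal[[1]])), 1e-4)
  # keypoints round-trip losslessly
  kb <- back$keypoints[[5]][[1]]
  ko <- sc$keypoints[[5]][[1]]
  expect_equal(kb$u, ko$u)
  expect_equal(kb$score, ko$score)
})
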