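test_that("region localization follows the sleeve-status rules", {
  kp <- full_kp(0.9)
  short <- locate_regions(kp, "Short", 0.6)
  expect_setequal(short$skin$part, c("nose", "left_lower_arm",
                                     "right_lower_arm"))
  # lower arm = midpoint of elbow and wrist
  la <- short$skin[short$skin$part == "left_lower_arm", ]
  expect_equal(la$u, (25 + 20) / 2)
  expect_equal(la$v, (45 + 65) / 2)
  expect_setequal(short$clothes$part, c("left_shoulder", "right_shoulder"))

  long <- locate_regions(kp, "Long", 0.6)
  expect_equal(long$skin$part, "nose")
  expect_setequal(long$clothes$part, c("left_shoulder", "right_shoulder",
                                       "left_elbow", "right_elbow"))

  ocl <- locate_regions(kp, "Occluded", 0.6)
  expect_equal(ocl$skin$part, "nose")
  expect_setequal(ocl$clothes$part, c("left_shoulder", "right_shoulder"))
})

test_that("sub-threshold keypoints are discarded before localization", {
  kp <- full_kp(0.9)
  kp$score[kp$name == "left_wrist"] <- 0.4
  reg <- locate_regions(kp, "Short", 0.6)
  expect_false("left_lower_arm" %in% reg$skin$part)
  expect_true("right_lower_arm" %in% reg$skin$part)
  kp$score[kp$name == "nose"] <- 0.1
  reg2 <- locate_regions(kp, "Short", 0.6)
  expect_false("nose" %in% reg2$skin$part)
  expect_error(locate_regions(kp, "Tucked", 0.6), "sleeve_status")
  kp$name[1] <- "left_ear"
  expect_error(locate_regions(kp, "Short", 0.6), "unsupported keypoint")
})

test_that("raising the threshold only ever shrinks the region sets", {
  set.seed(31)
  for (rep in 1:20) {
    kp <- full_kp(runif(7, 0.2, 1))
    status <- sample(c("Long", "Short", "Occluded"), 1)
    prev_n <- Inf
    for (thr in c(0.3, 0.5, 0.7, 0.9)) {
      reg <- locate_regions(kp, status, thr)
      n <- nrow(reg$skin) + nrow(reg$clothes)
      expect_lte(n, prev_n)
      prev_n <- n
    }
  }
})

test_that("short-sleeve skin contains long-sleeve skin; long clothes contains short", {
  set.seed(32)
  for (rep in 1:20) {
    kp <- full_kp(runif(7, 0.3, 1))
    s <- locate_regions(kp, "Short", 0.6)
    l <- locate_regions(kp, "Long", 0.6)
    expect_true(all(l$skin$part %in% s$skin$part))
    expect_true(all(s$clothes$part %in% l$clothes$part))
  }
})

test_that("sample accumulation counts points exactly on fully visible scenes", {
  sc <- small_scene("still_sit", "Long", n_frames = 100, seed = 7,
                    frame_shape = c(160, 120))
  st <- track_detections(sc$detections)
  tr <- confirmed_tracks(st)[[1]]
  samp <- accumulate_samples(tr, sc$keypoints, sc$thermal,
                             pipeline_config(), window = 0:99)
  expect_equal(samp$n_skin, 100L)        # 1 nose per frame
  expect_equal(samp$n_clothes, 400L)     # 2 shoulders + 2 elbows per frame
  expect_equal(samp$n_skin, nrow(samp$skin))
  expect_equal(samp$n_clothes, nrow(samp$clothes))
  expect_error(accumulate_samples(tr, sc$keypoints, sc$thermal,
                                  pipeline_config(), window = integer(0)),
               "at least one frame")
})

test_that("an always-occluded nose leaves the skin region empty downstream", {
  script <- scene_script(persons = list(scene_person(
    "still_sit", "Long", occluded_keypoints = "nose")),
    frame_shape = c(160, 120), n_frames = 30, seed = 8)
  sc <- generate_scene(script)
  st <- track_detections(sc$detections)
  tr <- confirmed_tracks(st)[[1]]
  samp <- accumulate_samples(tr, sc$keypoints, sc$thermal,
                             pipeline_config(), window = 0:29)
  expect_equal(samp$n_skin, 0L)
  err <- tryCatch(summarize_regions(samp, 22), condition = identity)
  expect_s3_class(err, "thermotrack_insufficient_samples")
  expect_match(conditionMessage(err), "skin")
})

test_that("summaries are means, order-invariant and bounded by the samples", {
  mk <- function(skin_t, clothes_t) {
    structure(list(
      skin = data.frame(frame = seq_along(skin_t), u = 1, v = 1,
                        temperature = skin_t),
      clothes = data.frame(frame = seq_along(clothes_t), u = 1, v = 1,
                           temperature = clothes_t),
      window_frames = 10L, n_skin = length(skin_t),
      n_clothes = length(clothes_t)), class = "region_samples")
  }
  s <- summarize_regions(mk(c(34.0, 35.0), 33.0), to = 25.0)
  expect_equal(s$ts, 34.5)
  expect_equal(s$tc, 33.0)
  expect_equal(s$to, 25.0)
  expect_equal(summarize_regions(mk(rep(34.5, 50), 33), 25)$ts, 34.5)
  set.seed(33)
  temps <- runif(20, 30, 36)
  s1 <- summarize_regions(mk(temps, 33), 25)
  s2 <- summarize_regions(mk(sample(temps), 33), 25)
  expect_equal(s1$ts, s2$ts)
  expect_gte(s1$ts, min(temps))
  expect_lte(s1$ts, max(temps))
})

test_that("background temperature excludes person boxes", {
  uni <- matrix(25.0, 10, 10)
  expect_equal(background_temperature(uni, list(list(x = 2, y = 2, w = 3,
                                                     h = 3))), 25.0)
  frame <- matrix(20.0, 10, 10)
  frame[3:7, 3:7] <- 35.0  # pixels (2..6, 2..6) 0-based
  expect_equal(background_temperature(frame, list(list(x = 2, y = 2, w = 5,
                                                       h = 5))), 20.0)
  expect_error(background_temperature(frame, list(list(x = 0, y = 0, w = 10,
                                                       h = 10))),
               "no background")
})

test_that("windowed background temperature recovers the scripted value", {
  sc <- small_scene("still_sit", "Long", n_frames = 40, seed = 9,
                    frame_shape = c(160, 120), background = 25.58)
  to <- background_temperature_window(sc$thermal, sc$ground_truth$boxes,
                                      0:39)
  expect_lt(abs(to - 25.58), 0.08)
})
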