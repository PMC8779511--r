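det_row <- function(frame, x, y, w, h, category = "LongSit", conf = 0.9) {
  data.frame(frame = frame, x = x, y = y, w = w, h = h,
             category = category, confidence = conf,
             stringsAsFactors = FALSE)
}

no_det <- det_row(0, 0, 0, 1, 1)[0, ]

test_that("a nearby detection is associated to the existing track", {
  st <- tracker_state(tracker_config())
  st <- track_step(st, det_row(0, 100, 100, 50, 120), 0)
  st <- track_step(st, det_row(1, 102, 101, 50, 120), 1)
  expect_length(st$tracks, 1L)
  expect_equal(st$tracks[[1]]$hit_streak, 2L)
  st <- track_step(st, det_row(2, 104, 102, 50, 120), 2)
  expect_equal(st$tracks[[1]]$state, "confirmed")
  expect_equal(st$tracks[[1]]$track_id, 1L)
})

test_that("a spurious single-frame detection never reaches confirmed output", {
  st <- tracker_state()
  st <- track_step(st, rbind(det_row(0, 100, 100, 50, 120),
                             det_row(0, 300, 20, 30, 60, "OclStand")), 0)
  for (f in 1:10)
    st <- track_step(st, det_row(f, 100 + f, 100, 50, 120), f)
  out <- track_boxes(st)
  expect_equal(unique(out$id), 1L)
  states <- vapply(st$tracks, `[[`, character(1), "state")
  expect_equal(states[2], "tentative")
  expect_false(2L %in% out$id)
})

test_that("tracks survive gaps up to max_age and die beyond it", {
  cfg <- tracker_config(max_age = 5)
  st <- tracker_state(cfg)
  f <- 0L
  for (i in 1:4) { st <- track_step(st, det_row(f, 50, 50, 40, 90), f); f <- f + 1L }
  expect_equal(st$tracks[[1]]$state, "confirmed")
  # gap of exactly max_age frames: id preserved on reappearance
  for (i in 1:5) { st <- track_step(st, no_det, f); f <- f + 1L }
  expect_equal(st$tracks[[1]]$state, "confirmed")
  st <- track_step(st, det_row(f, 50, 50, 40, 90), f); f <- f + 1L
  expect_equal(st$tracks[[1]]$age_since_update, 0L)
  expect_length(st$tracks, 1L)
  # gap of max_age + 1: deleted, reappearance starts a new id
  for (i in 1:6) { st <- track_step(st, no_det, f); f <- f + 1L }
  expect_equal(st$tracks[[1]]$state, "deleted")
  st <- track_step(st, det_row(f, 50, 50, 40, 90), f)
  expect_equal(st$tracks[[2]]$track_id, 2L)
})

test_that("frames must be fed consecutively", {
  st <- tracker_state()
  st <- track_step(st, det_row(0, 10, 10, 20, 40), 0)
  expect_error(track_step(st, det_row(5, 10, 10, 20, 40), 5),
               "non-consecutive")
  expect_error(track_step(st, no_det), "frame_index is required")
})

test_that("track ids increase strictly in creation order", {
  st <- tracker_state()
  dets0 <- rbind(det_row(0, 10, 10, 20, 40), det_row(0, 100, 10, 20, 40),
                 det_row(0, 200, 10, 20, 40))
  st <- track_step(st, dets0, 0)
  ids <- vapply(st$tracks, `[[`, integer(1), "track_id")
  expect_equal(ids, 1:3)
  st <- track_step(st, det_row(1, 300, 100, 20, 40), 1)
  expect_equal(st$tracks[[4]]$track_id, 4L)
})

test_that("the appearance hook contributes to the association cost", {
  # two equally-overlapping detections; appearance disambiguates
  hook <- function(det, track) if (det$x < 50) 0 else 10
  cfg <- tracker_config(appearance_hook = hook, appearance_weight = 1)
  st <- tracker_state(cfg)
  st <- track_step(st, det_row(0, 40, 50, 40, 90), 0)
  two <- rbind(det_row(1, 41, 50, 40, 90), det_row(1, 52, 50, 40, 90))
  st <- track_step(st, two, 1)
  # track 1 should take the low-appearance-distance detection (x = 41)
  tr1 <- st$tracks[[1]]
  expect_lt(abs(tr1$trajectory$x[2] - 41), 5)
})

test_that("category voting returns the mode and honours tie-break rules", {
  mk <- function(cats) {
    structure(list(category_history = data.frame(
      frame = seq_along(cats) - 1L, category = cats,
      stringsAsFactors = FALSE), last_vote = NA_character_),
      class = "track")
  }
  expect_equal(vote_category(mk(c(rep("LongSit", 180), rep("OclSit", 30))),
                             window = 210), "LongSit")
  expect_equal(vote_category(mk("ShortStand"), window = 63), "ShortStand")
  tied <- mk(c(rep("LongSit", 30), rep("ShortSit", 30)))
  expect_equal(vote_category(tied, window = 60, previous = "LongSit"),
               "LongSit")
  expect_equal(vote_category(tied, window = 60, previous = "ShortSit"),
               "ShortSit")
  # no previous vote: non-Occluded preferred, then alphabetical
  ocl_tie <- mk(c(rep("OclSit", 30), rep("ShortSit", 30)))
  expect_equal(vote_category(ocl_tie, window = 60), "ShortSit")
  expect_equal(vote_category(tied, window = 60), "LongSit")
  # voting only sees the window
  drift <- mk(c(rep("LongSit", 100), rep("ShortSit", 40)))
  expect_equal(vote_category(drift, window = 40), "ShortSit")
  empty <- structure(list(category_history = data.frame(
    frame = integer(0), category = character(0))), class = "track")
  expect_error(vote_category(empty), "empty category history")
})
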