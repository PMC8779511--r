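#' Tracker configuration
#'
#' Lifecycle and association settings for the tracking-by-detection stage.
#' A track is *tentative* until it has been associated with a detection in
#' `n_init` consecutive frames, after which it is *confirmed*; any track is
#' *deleted* once it has gone more than `max_age` frames without an
#' associated detection (the Maximum-Age rule).
#'
#' @param max_age Maximum number of frames a track may remain unassociated
#'   before deletion (Amax). Default 30 (about 1.4 s at 21 fps).
#' @param n_init Consecutive associations required for confirmation.
#' @param iou_threshold Minimum IoU for a detection/track pair to be
#'   associable.
#' @param appearance_hook Optional function `(detection, track) -> distance`
#'   (non-negative) added to the location cost; `NULL` disables appearance.
#' @param appearance_weight Weight of the appearance distance in the combined
#'   association cost `(1 - IoU) + appearance_weight * distance`.
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(max_age = 30, n_init = 3, iou_threshold = 0.3,
                           appearance_hook = NULL, appearance_weight = 1) {
  stopifnot(max_age >= 1, n_init >= 1,
            iou_threshold > 0, iou_threshold < 1,
            is.null(appearance_hook) || is.function(appearance_hook),
            appearance_weight >= 0)
  structure(list(max_age = as.integer(max_age), n_init = as.integer(n_init),
                 iou_threshold = as.numeric(iou_threshold),
                 appearance_hook = appearance_hook,
                 appearance_weight = as.numeric(appearance_weight)),
            class = "tracker_config")
}

#' Create an empty tracker state
#'
#' @param config A [tracker_config()].
#' @return A list of class `tracker_state` holding the live tracks, the next
#'   free track id and the index of the last processed frame.
#' @export
tracker_state <- function(config = tracker_config()) {
  stopifnot(inherits(config, "tracker_config"))
  structure(list(tracks = list(), next_id = 1L, frame = NA_integer_,
                 config = config),
            class = "tracker_state")
}

new_track <- function(id, det, frame, confirmed) {
  box <- bounding_box(det$x, det$y, det$w, det$h)
  structure(list(
    track_id = id,
    state = if (confirmed) "confirmed" else "tentative",
    kf = kf_init(box),
    age_since_update = 0L,
    hit_streak = 1L,
    last_vote = NA_character_,
    category_history = data.frame(frame = frame,
                                  category = as.character(det$category),
                                  stringsAsFactors = FALSE),
    trajectory = data.frame(frame = frame, x = box$x, y = box$y,
                            w = box$w, h = box$h, updated = TRUE,
                            confirmed = confirmed)
  ), class = "track")
}

traj_append <- function(track, frame, box, updated) {
  track$trajectory <- rbind(track$trajectory, data.frame(
    frame = frame, x = box$x, y = box$y, w = box$w, h = box$h,
    updated = updated, confirmed = track$state == "confirmed"))
  track
}

#' Advance the tracker by one frame
#'
#' Performs one step of tracking-by-detection: every live track's box is
#' propagated by its Kalman filter, detections are associated to predicted
#' boxes by minimum-cost assignment on `1 - IoU` (plus the appearance-hook
#' distance when configured), matched tracks are corrected and accumulate the
#' detection's category for voting, unmatched detections spawn tentative
#' tracks, and tracks unassociated for more than `max_age` frames are
#' deleted.
#'
#' Every frame must be fed exactly once and in order; pass a zero-row
#' detection data frame for frames without detections.
#'
#' @param state A [tracker_state()].
#' @param detections Data frame with columns `x`, `y`, `w`, `h`, `category`,
#'   `confidence` (and optionally `frame`), all sharing `frame_index`.
#' @param frame_index 0-based index of the frame being processed; defaults to
#'   the detections' `frame` column.
#' @return The updated `tracker_state`.
#' @export
track_step <- function(state, detections, frame_index = NULL) {
  stopifnot(inherits(state, "tracker_state"), is.data.frame(detections))
  cfg <- state$config
  if (is.null(frame_index)) {
    if (nrow(detections) == 0L)
      stop("frame_index is required when the detection list is empty",
           call. = FALSE)
    frame_index <- detections$frame[1]
  }
  frame_index <- as.integer(frame_index)
  if (nrow(detections) > 0 && "frame" %in% names(detections) &&
      !all(detections$frame == frame_index))
    stop("all detections must come from frame ", frame_index, call. = FALSE)
  if (!is.na(state$frame) && frame_index != state$frame + 1L)
    stop("non-consecutive frame: expected ", state$frame + 1L, ", got ",
         frame_index, "; feed every frame (possibly with zero detections)",
         call. = FALSE)

  live <- which(vapply(state$tracks, function(t) t$state != "deleted",
                       logical(1)))
  # predict
  for (i in live) state$tracks[[i]]$kf <- kf_predict(state$tracks[[i]]$kf)

  nd <- nrow(detections)
  nt <- length(live)
  match_det <- rep(NA_integer_, nt)
  if (nt > 0 && nd > 0) {
    cost <- matrix(Inf, nt, nd)
    for (ti in seq_len(nt)) {
      tr <- state$tracks[[live[ti]]]
      pbox <- kf_box(tr$kf)
      for (di in seq_len(nd)) {
        dbox <- detections[di, , drop = FALSE]
        iou <- box_iou(pbox, list(x = dbox$x, y = dbox$y,
                                  w = dbox$w, h = dbox$h))
        if (iou >= cfg$iou_threshold) {
          c0 <- 1 - iou
          if (!is.null(cfg$appearance_hook))
            c0 <- c0 + cfg$appearance_weight *
              cfg$appearance_hook(dbox, tr)
          cost[ti, di] <- c0
        }
      }
    }
    match_det <- solve_assignment(cost)
  }

  used_det <- rep(FALSE, nd)
  for (ti in seq_len(nt)) {
    idx <- live[ti]
    tr <- state$tracks[[idx]]
    di <- if (nt > 0) match_det[ti] else NA_integer_
    if (!is.na(di)) {
      used_det[di] <- TRUE
      det <- detections[di, , drop = FALSE]
      box <- bounding_box(det$x, det$y, det$w, det$h)
      tr$kf <- kf_update(tr$kf, box)
      tr$age_since_update <- 0L
      tr$hit_streak <- tr$hit_streak + 1L
      if (tr$state == "tentative" && tr$hit_streak >= cfg$n_init) {
        tr$state <- "confirmed"
        # confirmation is retroactive: the track existed from its first
        # detection, so earlier trajectory rows become part of the output
        tr$trajectory$confirmed <- TRUE
      }
      tr$category_history <- rbind(tr$category_history, data.frame(
        frame = frame_index, category = as.character(det$category),
        stringsAsFactors = FALSE))
      tr <- traj_append(tr, frame_index, kf_box(tr$kf), updated = TRUE)
    } else {
      tr$age_since_update <- tr$age_since_update + 1L
      tr$hit_streak <- 0L
      if (tr$age_since_update > cfg$max_age) {
        tr$state <- "deleted"
      } else if (tr$state == "confirmed") {
        # coasting: keep the predicted box so feature windows stay dense
        tr <- traj_append(tr, frame_index, kf_box(tr$kf), updated = FALSE)
      }
    }
    state$tracks[[idx]] <- tr
  }

  for (di in seq_len(nd)) {
    if (!used_det[di]) {
      det <- detections[di, , drop = FALSE]
      tr <- new_track(state$next_id, det, frame_index,
                      confirmed = cfg$n_init <= 1L)
      state$tracks[[length(state$tracks) + 1L]] <- tr
      state$next_id <- state$next_id + 1L
    }
  }

  state$frame <- frame_index
  state
}

#' Run the tracker over a whole detection table
#'
#' Convenience wrapper that feeds [track_step()] every frame in
#' `0:max(frame)` (empty frames included).
#'
#' @param detections Data frame of detections with a 0-based `frame` column.
#' @param config A [tracker_config()].
#' @param n_frames Number of frames to process; defaults to
#'   `max(detections$frame) + 1`.
#' @return The final `tracker_state`.
#' @export
track_detections <- function(detections, config = tracker_config(),
                             n_frames = NULL) {
  if (is.null(n_frames)) {
    if (nrow(detections) == 0L)
      stop("n_frames is required for an empty detection table", call. = FALSE)
    n_frames <- max(detections$frame) + 1L
  }
  state <- tracker_state(config)
  for (f in seq_len(n_frames) - 1L) {
    state <- track_step(state, detections[detections$frame == f, ,
                                          drop = FALSE], f)
  }
  state
}

#' Tracks that reached the confirmed state
#' @param state A `tracker_state`.
#' @return List of `track` objects currently or formerly confirmed (deleted
#'   tracks are included if they were confirmed at some point).
#' @export
confirmed_tracks <- function(state) {
  Filter(function(t) any(t$trajectory$confirmed), state$tracks)
}

#' Confirmed-track boxes in MOT layout
#'
#' Emits one row per frame and confirmed track where the track was actually
#' associated with a detection (coasted predictions are internal only).
#'
#' @param state A `tracker_state`.
#' @return Data frame `frame, id, x, y, w, h`.
#' @export
track_boxes <- function(state) {
  out <- lapply(confirmed_tracks(state), function(t) {
    rows <- t$trajectory[t$trajectory$updated & t$trajectory$confirmed, ,
                         drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    data.frame(frame = rows$frame, id = t$track_id,
               x = rows$x, y = rows$y, w = rows$w, h = rows$h)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), id = integer(0), x = numeric(0),
                      y = numeric(0), w = numeric(0), h = numeric(0))
  out[order(out$frame, out$id), , drop = FALSE]
}

#' Vote a track's category over a recent window
#'
#' Returns the modal category among the track's per-frame detector categories
#' within the last `window` frames. Ties are broken in favour of the
#' previously voted category, then of a non-Occluded candidate, then
#' alphabetically.
#'
#' @param track A `track` (or any list with a `category_history` data frame).
#' @param window Window length in frames, counted back from the most recent
#'   entry.
#' @param previous Previously voted category used for tie-breaking; defaults
#'   to the track's `last_vote`.
#' @return A single category string.
#' @export
vote_category <- function(track, window = 63, previous = NULL) {
  hist <- track$category_history
  if (is.null(hist) || nrow(hist) == 0L)
    stop("cannot vote on an empty category history", call. = FALSE)
  if (is.null(previous)) previous <- track$last_vote
  last <- max(hist$frame)
  recent <- hist$category[hist$frame > last - window]
  tab <- table(recent)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  if (!is.null(previous) && !is.na(previous) && previous %in% winners)
    return(previous)
  non_ocl <- winners[!startsWith(winners, "Ocl")]
  if (length(non_ocl) > 0) return(sort(non_ocl)[1])
  sort(winners)[1]
}
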