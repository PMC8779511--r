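# Three activity-intensity features over a tracking window:
# spread of box centers, spread of box half-extents, and optical-flow
# intensity pooled inside the box.

# Area of the ellipse fitted to a 2-D point cluster: the product of the two
# eigenvalues of the sample covariance matrix (identical to its determinant).
ellipse_spread <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("at least two points are required to measure spread", call. = FALSE)
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  prod(pmax(ev, 0))
}

traj_of <- function(track) {
  if (is.data.frame(track)) track else track$trajectory
}

#' Spread of bounding-box centers over a window
#'
#' The per-frame box centers `(cx, cy)` form a 2-D cluster; the feature is
#' the area of the ellipse fitted to it, computed as the product of the two
#' eigenvalues of the cluster's sample covariance matrix. Captures general
#' body movement.
#'
#' @param track A `track`, or a trajectory data frame with `x, y, w, h`.
#' @return Spread in pixels^2 (0 for a stationary box).
#' @export
center_spread <- function(track) {
  tr <- traj_of(track)
  ellipse_spread(cbind(tr$x + tr$w / 2, tr$y + tr$h / 2))
}

#' Spread of bounding-box scales over a window
#'
#' After translating every box to the origin, its upper-right corner
#' `(w/2, h/2)` encodes its scale; the feature is the eigenvalue-product
#' area of that cluster. Captures limb motion that changes the box size
#' without moving its center.
#'
#' @inheritParams center_spread
#' @return Spread in pixels^2 (0 for a constant box size).
#' @export
scale_spread <- function(track) {
  tr <- traj_of(track)
  ellipse_spread(cbind(tr$w / 2, tr$h / 2))
}

#' Construct a flow field
#'
#' Dense optical flow encoded as two 8-bit grayscale images, one per
#' direction, in which value 127 means zero motion and values farther from
#' 127 mean larger displacement.
#'
#' @param horizontal,vertical Matrices of grayscale values in `[0, 255]`,
#'   same shape as the thermal frame.
#' @param validate Check the grayscale range (disable for trusted
#'   internally generated fields).
#' @return A list of class `flow_field`.
#' @export
flow_field <- function(horizontal, vertical, validate = TRUE) {
  stopifnot(is.matrix(horizontal), is.matrix(vertical),
            all(dim(horizontal) == dim(vertical)))
  if (validate) {
    rng <- range(horizontal, vertical)
    if (rng[1] < 0 || rng[2] > 255)
      stop("flow grayscale values must lie in [0, 255]", call. = FALSE)
  }
  structure(list(horizontal = horizontal, vertical = vertical,
                 zero_level = 127), class = "flow_field")
}

box_pixels <- function(box, W, H) {
  u0 <- max(0L, ceiling(box$x)); u1 <- min(W - 1L, ceiling(box$x + box$w) - 1L)
  v0 <- max(0L, ceiling(box$y)); v1 <- min(H - 1L, ceiling(box$y + box$h) - 1L)
  if (u0 > u1 || v0 > v1) return(NULL)
  list(us = u0:u1, vs = v0:v1)
}

#' Per-frame optical-flow intensity inside a box
#'
#' `Ix` is the mean absolute deviation from grayscale 127 of the horizontal
#' flow over the box pixels and `Iy` likewise for the vertical flow; the
#' frame intensity is `sqrt(Ix^2 + Iy^2)`. Dividing by the pixel count
#' normalizes out the box size.
#'
#' @param flow A [flow_field()].
#' @param box A box (list or one-row data frame with `x, y, w, h`).
#' @return Flow intensity in grayscale units.
#' @export
flow_intensity_frame <- function(flow, box) {
  stopifnot(inherits(flow, "flow_field"))
  H <- nrow(flow$horizontal); W <- ncol(flow$horizontal)
  px <- box_pixels(as.list(box), W, H)
  if (is.null(px))
    stop("box does not intersect the flow field", call. = FALSE)
  ix <- mean(abs(flow$horizontal[px$vs + 1L, px$us + 1L] - 127))
  iy <- mean(abs(flow$vertical[px$vs + 1L, px$us + 1L] - 127))
  sqrt(ix^2 + iy^2)
}

#' Window-mean optical-flow intensity
#'
#' @param flows List of [flow_field()]s, one per frame of the window.
#' @param boxes Data frame of the corresponding per-frame boxes
#'   (`x, y, w, h`), one row per flow field.
#' @return Arithmetic mean of the per-frame intensities.
#' @export
flow_intensity_window <- function(flows, boxes) {
  stopifnot(is.data.frame(boxes))
  if (length(flows) != nrow(boxes))
    stop("flows and boxes must have equal length (got ", length(flows),
         " vs ", nrow(boxes), ")", call. = FALSE)
  if (length(flows) == 0L)
    stop("the window must contain at least one frame", call. = FALSE)
  mean(vapply(seq_along(flows), function(i)
    flow_intensity_frame(flows[[i]], boxes[i, , drop = FALSE]), numeric(1)))
}

stop_window_not_full <- function(have, need) {
  cond <- structure(
    class = c("thermotrack_window_not_full", "error", "condition"),
    list(message = sprintf(
      "window not full: %d frames available, %d required", have, need),
      call = NULL))
  stop(cond)
}

#' Extract the three activity-intensity features for a track
#'
#' Bundles [center_spread()], [scale_spread()] and
#' [flow_intensity_window()] over the most recent
#' `config$activity_window_frames` frames of the track.
#'
#' @param track A `track` with at least a full window of trajectory rows.
#' @param flows List of [flow_field()]s indexed by `frame + 1` over the whole
#'   recording (or exactly one per window frame).
#' @param config A [pipeline_config()].
#' @return A list of class `activity_features` with `center_spread`,
#'   `scale_spread`, `flow_intensity` and `window_frames`.
#' @export
extract_features <- function(track, flows, config = pipeline_config()) {
  itv <- config$activity_window_frames
  tr <- traj_of(track)
  if (nrow(tr) < itv) stop_window_not_full(nrow(tr), itv)
  win <- tr[seq(nrow(tr) - itv + 1L, nrow(tr)), , drop = FALSE]
  win_flows <- if (length(flows) == itv && is.null(names(flows))) {
    flows
  } else {
    lapply(win$frame, function(f) flows[[f + 1L]])
  }
  structure(list(
    center_spread = center_spread(win),
    scale_spread = scale_spread(win),
    flow_intensity = flow_intensity_window(win_flows,
                                           win[, c("x", "y", "w", "h")]),
    window_frames = itv), class = "activity_features")
}

#' Build a minimal track from a table of boxes
#'
#' Useful for computing features on externally supplied trajectories (e.g.
#' ground-truth or detector boxes) without running the tracker.
#'
#' @param boxes Data frame `frame, x, y, w, h` (optionally `category`).
#' @param track_id Identifier to attach.
#' @return A `track` object with a trajectory and category history.
#' @export
track_from_boxes <- function(boxes, track_id = 1L) {
  stopifnot(all(c("frame", "x", "y", "w", "h") %in% names(boxes)))
  boxes <- boxes[order(boxes$frame), , drop = FALSE]
  cat_hist <- if ("category" %in% names(boxes)) {
    data.frame(frame = boxes$frame, category = as.character(boxes$category),
               stringsAsFactors = FALSE)
  } else {
    data.frame(frame = integer(0), category = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(track_id = as.integer(track_id), state = "confirmed",
                 kf = NULL, age_since_update = 0L, hit_streak = nrow(boxes),
                 last_vote = NA_character_, category_history = cat_hist,
                 trajectory = data.frame(frame = boxes$frame, x = boxes$x,
                                         y = boxes$y, w = boxes$w,
                                         h = boxes$h, updated = TRUE,
                                         confirmed = TRUE)),
            class = "track")
}
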