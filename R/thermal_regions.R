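#' Localize skin and clothes sampling points from pose keypoints
#'
#' Implements the sleeve-aware region rule: the nose is always a skin (Rs)
#' point; for short sleeves the midpoint of elbow and wrist on each side
#' (the lower arm) is also skin; the shoulders are always clothes (Rc)
#' points; for long sleeves the elbows are also clothes. When the sleeve
#' status is occluded only the nose and shoulders are used. Keypoints whose
#' confidence score falls below the threshold are discarded first.
#'
#' @param keypoints Data frame with columns `name` (one of
#'   [supported_keypoints]), `u`, `v` (pixels) and `score` in `[0, 1]`; an
#'   optional logical `valid` column marks out-of-frame keypoints.
#' @param sleeve_status `"Long"`, `"Short"` or `"Occluded"`.
#' @param conf_threshold Keypoint confidence threshold in `(0, 1)`.
#' @return A list with data frames `skin` and `clothes`, each with columns
#'   `u`, `v`, `part`. Either may have zero rows.
#' @export
locate_regions <- function(keypoints, sleeve_status, conf_threshold = 0.6) {
  stopifnot(is.data.frame(keypoints),
            all(c("name", "u", "v", "score") %in% names(keypoints)))
  if (!sleeve_status %in% c("Long", "Short", "Occluded"))
    stop("sleeve_status must be Long, Short or Occluded", call. = FALSE)
  if (conf_threshold <= 0 || conf_threshold >= 1)
    stop("conf_threshold must lie in (0, 1)", call. = FALSE)
  bad <- setdiff(keypoints$name, supported_keypoints)
  if (length(bad) > 0)
    stop("unsupported keypoint name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  keep <- keypoints$score >= conf_threshold
  if ("valid" %in% names(keypoints)) keep <- keep & keypoints$valid
  kp <- keypoints[keep, , drop = FALSE]
  get <- function(nm) {
    row <- kp[kp$name == nm, , drop = FALSE]
    if (nrow(row) == 0L) NULL else row[1, , drop = FALSE]
  }
  pt <- function(u, v, part) data.frame(u = u, v = v, part = part,
                                        stringsAsFactors = FALSE)

  skin <- list()
  clothes <- list()

  nose <- get("nose")
  if (!is.null(nose)) skin <- c(skin, list(pt(nose$u, nose$v, "nose")))

  for (side in c("left", "right")) {
    sh <- get(paste0(side, "_shoulder"))
    el <- get(paste0(side, "_elbow"))
    wr <- get(paste0(side, "_wrist"))
    if (!is.null(sh))
      clothes <- c(clothes, list(pt(sh$u, sh$v, paste0(side, "_shoulder"))))
    if (sleeve_status == "Long" && !is.null(el))
      clothes <- c(clothes, list(pt(el$u, el$v, paste0(side, "_elbow"))))
    if (sleeve_status == "Short" && !is.null(el) && !is.null(wr))
      skin <- c(skin, list(pt((el$u + wr$u) / 2, (el$v + wr$v) / 2,
                              paste0(side, "_lower_arm"))))
  }

  empty <- data.frame(u = numeric(0), v = numeric(0), part = character(0),
                      stringsAsFactors = FALSE)
  list(skin = if (length(skin)) do.call(rbind, skin) else empty,
       clothes = if (length(clothes)) do.call(rbind, clothes) else empty)
}

# Temperature at a continuous pixel coordinate: nearest integer pixel,
# clamped to the frame, optionally averaged over an odd-sized patch.
sample_temperature <- function(values, u, v, patch_size = 1L) {
  H <- nrow(values); W <- ncol(values)
  ui <- min(max(round(u), 0), W - 1L)
  vi <- min(max(round(v), 0), H - 1L)
  half <- (patch_size - 1L) %/% 2L
  us <- max(0L, ui - half):min(W - 1L, ui + half)
  vs <- max(0L, vi - half):min(H - 1L, vi + half)
  mean(values[vs + 1L, us + 1L])
}

# Pick the skeleton whose keypoint hull overlaps a box the most.
match_skeleton <- function(box, skeletons) {
  if (length(skeletons) == 0L) return(NULL)
  overlap <- vapply(skeletons, function(sk) {
    sk <- sk[is.finite(sk$u) & is.finite(sk$v), , drop = FALSE]
    if (nrow(sk) == 0L) return(-Inf)
    hx0 <- min(sk$u); hx1 <- max(sk$u)
    hy0 <- min(sk$v); hy1 <- max(sk$v)
    # degenerate hulls still rank by contained area of a 1px-wide hull
    w <- max(hx1 - hx0, 1); h <- max(hy1 - hy0, 1)
    ix <- max(0, min(box$x + box$w, hx0 + w) - max(box$x, hx0))
    iy <- max(0, min(box$y + box$h, hy0 + h) - max(box$y, hy0))
    ix * iy
  }, numeric(1))
  if (all(overlap <= 0)) return(NULL)
  skeletons[[which.max(overlap)]]
}

#' Accumulate skin/clothes temperature samples over a window
#'
#' For every frame of the window in which the track has a box, the frame's
#' keypoint skeleton is assigned to the track (maximal overlap between the
#' skeleton's bounding hull and the track box), [locate_regions()] is applied
#' with the track's voted sleeve status, each returned point is rounded to
#' the nearest pixel, clamped to the frame, and its temperature read from the
#' thermal frame.
#'
#' @param track A `track` from the tracker (or [track_from_boxes()]).
#' @param keypoints_by_frame List indexed by `frame + 1`; each element is a
#'   list of skeleton data frames (columns `name, u, v, score`), or a single
#'   skeleton data frame.
#' @param thermal_frames List indexed by `frame + 1` of temperature matrices
#'   (degrees C).
#' @param config A [pipeline_config()].
#' @param window Integer vector of 0-based frame indices to accumulate over;
#'   defaults to the last `icl_window_frames` frames of the trajectory.
#' @param sleeve_status Override for the sleeve status; by default the modal
#'   category over the window (falling back to the whole history) is
#'   decomposed.
#' @return A list of class `region_samples` with data frames `skin` and
#'   `clothes` (`frame, u, v, temperature`), the window length and counts
#'   `n_skin`, `n_clothes`.
#' @export
accumulate_samples <- function(track, keypoints_by_frame, thermal_frames,
                               config = pipeline_config(), window = NULL,
                               sleeve_status = NULL) {
  traj <- track$trajectory
  if (is.null(window)) {
    last <- max(traj$frame)
    window <- max(min(traj$frame), last - config$icl_window_frames + 1L):last
  }
  if (length(window) == 0L)
    stop("accumulation window must contain at least one frame", call. = FALSE)

  if (is.null(sleeve_status)) {
    hist <- track$category_history
    in_win <- hist[hist$frame %in% window, , drop = FALSE]
    if (nrow(in_win) == 0L) in_win <- hist
    tab <- table(in_win$category)
    voted <- names(tab)[which.max(tab)]
    sleeve_status <- decompose_category(voted)$sleeve
  }

  skin <- list(); clothes <- list()
  for (f in window) {
    row <- traj[traj$frame == f, , drop = FALSE]
    if (nrow(row) == 0L) next
    if (f + 1L > length(thermal_frames) || is.null(thermal_frames[[f + 1L]]))
      next
    values <- thermal_frames[[f + 1L]]
    sks <- if (f + 1L <= length(keypoints_by_frame))
      keypoints_by_frame[[f + 1L]] else NULL
    if (is.data.frame(sks)) sks <- list(sks)
    sk <- match_skeleton(as.list(row[1, c("x", "y", "w", "h")]), sks)
    if (is.null(sk)) next
    reg <- locate_regions(sk, sleeve_status, config$keypoint_conf_threshold)
    take <- function(df) {
      if (nrow(df) == 0L) return(NULL)
      data.frame(frame = f, u = df$u, v = df$v,
                 temperature = vapply(seq_len(nrow(df)), function(i)
                   sample_temperature(values, df$u[i], df$v[i],
                                      config$patch_size), numeric(1)))
    }
    s <- take(reg$skin); if (!is.null(s)) skin <- c(skin, list(s))
    c_ <- take(reg$clothes); if (!is.null(c_)) clothes <- c(clothes, list(c_))
  }
  empty <- data.frame(frame = integer(0), u = numeric(0), v = numeric(0),
                      temperature = numeric(0))
  skin <- if (length(skin)) do.call(rbind, skin) else empty
  clothes <- if (length(clothes)) do.call(rbind, clothes) else empty
  structure(list(skin = skin, clothes = clothes,
                 window_frames = length(window),
                 n_skin = nrow(skin), n_clothes = nrow(clothes),
                 sleeve_status = sleeve_status),
            class = "region_samples")
}

#' Summarize accumulated region samples into mean temperatures
#'
#' @param samples A `region_samples` from [accumulate_samples()].
#' @param to Operative (background) temperature in degrees C, usually from
#'   [background_temperature_window()].
#' @return A list of class `thermal_summary` with `ts`, `tc`, `to` (degrees
#'   C) and the sample counts.
#' @export
summarize_regions <- function(samples, to) {
  stopifnot(inherits(samples, "region_samples"), is.numeric(to))
  if (samples$n_skin < 1L)
    stop_insufficient("skin")
  if (samples$n_clothes < 1L)
    stop_insufficient("clothes")
  structure(list(ts = mean(samples$skin$temperature),
                 tc = mean(samples$clothes$temperature),
                 to = to,
                 n_skin = samples$n_skin, n_clothes = samples$n_clothes),
            class = "thermal_summary")
}

stop_insufficient <- function(region) {
  cond <- structure(
    class = c("thermotrack_insufficient_samples", "error", "condition"),
    list(message = paste0("insufficient samples: the ", region,
                          " region is empty"),
         call = NULL, region = region))
  stop(cond)
}

#' Mean background temperature of one thermal frame
#'
#' The operative temperature proxy: the mean over all pixels lying outside
#' every person box.
#'
#' @param values Temperature matrix (degrees C).
#' @param person_boxes List of boxes (or a data frame with `x, y, w, h`
#'   columns) to exclude.
#' @return Mean background temperature, degrees C.
#' @export
background_temperature <- function(values, person_boxes = list()) {
  stopifnot(is.matrix(values), length(values) > 0)
  H <- nrow(values); W <- ncol(values)
  if (is.data.frame(person_boxes))
    person_boxes <- lapply(seq_len(nrow(person_boxes)), function(i)
      as.list(person_boxes[i, c("x", "y", "w", "h")]))
  mask <- matrix(FALSE, H, W)
  for (b in person_boxes) {
    us <- max(0L, ceiling(b$x)):min(W - 1L, ceiling(b$x + b$w) - 1L)
    vs <- max(0L, ceiling(b$y)):min(H - 1L, ceiling(b$y + b$h) - 1L)
    if (length(us) > 0 && length(vs) > 0 && us[1] <= us[length(us)] &&
        vs[1] <= vs[length(vs)])
      mask[vs + 1L, us + 1L] <- TRUE
  }
  bg <- values[!mask]
  if (length(bg) == 0L)
    stop("no background: person boxes cover the whole frame", call. = FALSE)
  mean(bg)
}

#' Mean background temperature over a window of frames
#'
#' Unweighted mean of the per-frame background means.
#'
#' @param thermal_frames List indexed by `frame + 1` of temperature matrices.
#' @param boxes_by_frame List indexed by `frame + 1` of box lists/data frames
#'   (e.g. the tracked boxes of that frame), or a single data frame with a
#'   `frame` column.
#' @param window Integer vector of 0-based frame indices.
#' @return Mean operative temperature, degrees C.
#' @export
background_temperature_window <- function(thermal_frames, boxes_by_frame,
                                          window) {
  stopifnot(length(window) > 0)
  per_frame <- vapply(window, function(f) {
    values <- thermal_frames[[f + 1L]]
    boxes <- if (is.data.frame(boxes_by_frame)) {
      boxes_by_frame[boxes_by_frame$frame == f, , drop = FALSE]
    } else if (f + 1L <= length(boxes_by_frame)) {
      boxes_by_frame[[f + 1L]]
    } else list()
    background_temperature(values, boxes)
  }, numeric(1))
  mean(per_frame)
}
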