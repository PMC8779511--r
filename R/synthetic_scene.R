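# Synthetic thermal office scenes: fully labelled frames, detections,
# keypoint skeletons and analytic optical-flow fields, with ground truth,
# so the whole pipeline can be exercised without camera hardware, a person
# detector, a pose network or a flow estimator.

scene_behaviors <- c("still_sit", "still_stand", "gesture_stand",
                     "stretch_stand", "walk")

#' Describe one synthetic person
#'
#' @param behavior One of `"still_sit"`, `"still_stand"`,
#'   `"gesture_stand"`, `"stretch_stand"`, `"walk"`.
#' @param sleeve `"Long"`, `"Short"` or `"Occluded"`.
#' @param skin_temperature,clothes_temperature Surface temperatures, degrees
#'   C. Defaults near measured office values (34.7 / 33.4).
#' @param center Optional `(cx, cy)` base position in pixels; auto-spaced
#'   when `NULL`.
#' @param width,height Optional base box size in pixels; posture-dependent
#'   defaults when `NULL`.
#' @param occluded_keypoints Character vector of keypoint names emitted with
#'   sub-threshold confidence scores (simulating occlusion).
#' @return A list describing the person.
#' @export
scene_person <- function(behavior = "still_sit", sleeve = "Long",
                         skin_temperature = 34.7, clothes_temperature = 33.4,
                         center = NULL, width = NULL, height = NULL,
                         occluded_keypoints = character(0)) {
  behavior <- match.arg(behavior, scene_behaviors)
  if (!sleeve %in% c("Long", "Short", "Occluded"))
    stop("sleeve must be Long, Short or Occluded", call. = FALSE)
  posture <- if (behavior == "still_sit") "Sit" else "Stand"
  prefix <- c(Long = "Long", Short = "Short", Occluded = "Ocl")[sleeve]
  list(behavior = behavior, sleeve = sleeve, posture = posture,
       category = paste0(prefix, posture),
       skin_temperature = skin_temperature,
       clothes_temperature = clothes_temperature,
       center = center, width = width, height = height,
       occluded_keypoints = occluded_keypoints)
}

#' Describe a synthetic scene
#'
#' Defaults emulate the study conditions: a 384 x 288 thermal sensor with
#' 0.08 degrees C quantization at 21 fps and a 22 degrees C office
#' background.
#'
#' @param persons List of [scene_person()] descriptions.
#' @param background_temperature Uniform background temperature, degrees C.
#' @param frame_shape `(width, height)` in pixels.
#' @param n_frames Number of frames to generate.
#' @param fps Frame rate, frames per second.
#' @param seed Integer seed; identical scripts and seeds generate
#'   bit-identical scenes.
#' @param noise List of corruption settings: `jitter_sd` (detection box
#'   jitter sigma, pixels), `fp_rate` / `fn_rate` (per-frame false
#'   positive/negative probabilities), `keypoint_jitter_sd` (pixels),
#'   `keypoint_score_mean` / `keypoint_score_sd` (confidence distribution),
#'   `sensor_noise_sd` (thermal noise sigma, degrees C).
#' @param quantization_step Thermal quantization, degrees C.
#' @return A validated list of class `scene_script`.
#' @export
scene_script <- function(persons = list(scene_person()),
                         background_temperature = 22,
                         frame_shape = c(384, 288), n_frames = 210,
                         fps = 21, seed = 1,
                         noise = list(), quantization_step = 0.08) {
  noise <- utils::modifyList(list(jitter_sd = 0, fp_rate = 0, fn_rate = 0,
                                  keypoint_jitter_sd = 0.3,
                                  keypoint_score_mean = 0.9,
                                  keypoint_score_sd = 0.04,
                                  sensor_noise_sd = 0.1), noise)
  stopifnot(n_frames >= 1, fps > 0, quantization_step > 0,
            noise$fp_rate >= 0, noise$fp_rate <= 1,
            noise$fn_rate >= 0, noise$fn_rate <= 1,
            noise$jitter_sd >= 0, length(frame_shape) == 2)
  W <- as.integer(frame_shape[1]); H <- as.integer(frame_shape[2])
  n <- length(persons)
  for (i in seq_len(n)) {
    p <- persons[[i]]
    if (is.null(p$width))
      p$width <- if (p$posture == "Sit") 64 else 56
    if (is.null(p$height))
      p$height <- if (p$posture == "Sit") round(H * 0.38) else round(H * 0.52)
    if (is.null(p$center))
      p$center <- c(W * i / (n + 1), H * 0.55)
    if (p$skin_temperature <= p$clothes_temperature ||
        p$clothes_temperature <= background_temperature)
      stop("default scenes require skin > clothes > background temperature",
           call. = FALSE)
    persons[[i]] <- p
  }
  # packing limit: base boxes must not overlap heavily
  if (n > 1) {
    base_box <- function(p) list(x = p$center[1] - p$width / 2,
                                 y = p$center[2] - p$height / 2,
                                 w = p$width, h = p$height)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (box_iou(base_box(persons[[i]]), base_box(persons[[j]])) > 0.3)
        stop("persons ", i, " and ", j,
             " overlap beyond the packing limit (IoU > 0.3)", call. = FALSE)
    }
  }
  structure(list(persons = persons,
                 background_temperature = background_temperature,
                 frame_shape = c(W, H), n_frames = as.integer(n_frames),
                 fps = fps, seed = as.integer(seed), noise = noise,
                 quantization_step = quantization_step),
            class = "scene_script")
}

# per-behavior kinematics and flow amplitude, drawn once per person
draw_motion_params <- function(behavior) {
  switch(behavior,
    still_sit = ,
    still_stand = list(amp = stats::runif(1, 0.05, 0.5), vel = 0,
                       scale_amp = stats::runif(1, 0, 0.004),
                       flow_amp = stats::runif(1, 0.2, 1.5)),
    gesture_stand = list(amp = stats::runif(1, 1.5, 3.5), vel = 0,
                         scale_amp = stats::runif(1, 0.010, 0.030),
                         flow_amp = stats::runif(1, 6, 16)),
    stretch_stand = list(amp = stats::runif(1, 5, 10), vel = 0,
                         scale_amp = stats::runif(1, 0.05, 0.12),
                         flow_amp = stats::runif(1, 25, 55)),
    walk = list(amp = stats::runif(1, 1, 2.5), vel = stats::runif(1, 1, 2.5) *
                  sample(c(-1, 1), 1),
                scale_amp = stats::runif(1, 0.02, 0.05),
                flow_amp = stats::runif(1, 15, 40)))
}

# deterministic per-frame box trajectory for one person
person_trajectory <- function(p, mp, n_frames, W, H) {
  t <- seq_len(n_frames) - 1
  period <- mp$period
  cx <- p$center[1] + mp$amp * sin(2 * pi * t / period + mp$phase)
  cy <- p$center[2] + 0.5 * mp$amp * sin(2 * pi * t / (period * 1.3) +
                                           mp$phase2)
  if (mp$vel != 0) {
    # walk: triangle-wave drift bouncing between frame margins
    margin <- p$width / 2 + 6
    span <- (W - 2 * margin)
    raw <- (p$center[1] - margin) + mp$vel * t
    cx <- margin + abs((raw %% (2 * span)) - span) +
      mp$amp * 0.2 * sin(2 * pi * t / period)
  }
  w <- p$width * (1 + mp$scale_amp * sin(2 * pi * t / (period * 0.8) +
                                           mp$phase3))
  h <- p$height * (1 + mp$scale_amp * sin(2 * pi * t / (period * 0.8) +
                                            mp$phase3 + 0.7))
  data.frame(frame = t, cx = cx, cy = cy, w = w, h = h,
             x = cx - w / 2, y = cy - h / 2)
}

# true keypoint layout for a box (continuous pixel coordinates)
person_keypoints <- function(x, y, w, h) {
  data.frame(
    name = c("nose", "left_shoulder", "right_shoulder", "left_elbow",
             "right_elbow", "left_wrist", "right_wrist"),
    u = c(x + 0.50 * w, x + 0.24 * w, x + 0.76 * w, x + 0.14 * w,
          x + 0.86 * w, x + 0.08 * w, x + 0.92 * w),
    v = c(y + 0.10 * h, y + 0.22 * h, y + 0.22 * h, y + 0.42 * h,
          y + 0.42 * h, y + 0.60 * h, y + 0.60 * h),
    stringsAsFactors = FALSE)
}

paint_disc <- function(values, cu, cv, r, temp) {
  H <- nrow(values); W <- ncol(values)
  us <- max(0L, floor(cu - r)):min(W - 1L, ceiling(cu + r))
  vs <- max(0L, floor(cv - r)):min(H - 1L, ceiling(cv + r))
  if (length(us) == 0L || length(vs) == 0L || us[1] > us[length(us)] ||
      vs[1] > vs[length(vs)]) return(values)
  mask <- outer((vs - cv)^2, (us - cu)^2, "+") <= r^2
  sub <- values[vs + 1L, us + 1L, drop = FALSE]
  sub[mask] <- temp
  values[vs + 1L, us + 1L] <- sub
  values
}

paint_ellipse <- function(values, cu, cv, ru, rv, temp) {
  H <- nrow(values); W <- ncol(values)
  us <- max(0L, floor(cu - ru)):min(W - 1L, ceiling(cu + ru))
  vs <- max(0L, floor(cv - rv)):min(H - 1L, ceiling(cv + rv))
  if (length(us) == 0L || length(vs) == 0L) return(values)
  mask <- outer(((vs - cv) / rv)^2, ((us - cu) / ru)^2, "+") <= 1
  sub <- values[vs + 1L, us + 1L, drop = FALSE]
  sub[mask] <- temp
  values[vs + 1L, us + 1L] <- sub
  values
}

render_person_thermal <- function(values, x, y, w, h, kp, sleeve,
                                  skin_t, clothes_t) {
  values <- paint_ellipse(values, x + w / 2, y + 0.52 * h, 0.34 * w,
                          0.32 * h, clothes_t)
  values <- paint_disc(values, x + 0.5 * w, y + 0.10 * h,
                       max(4, 0.09 * h), skin_t)
  for (side in c("left", "right")) {
    sh <- kp[kp$name == paste0(side, "_shoulder"), ]
    el <- kp[kp$name == paste0(side, "_elbow"), ]
    wr <- kp[kp$name == paste0(side, "_wrist"), ]
    values <- paint_disc(values, sh$u, sh$v, 3.2, clothes_t)
    arm_t <- if (sleeve == "Short") skin_t else clothes_t
    values <- paint_disc(values, el$u, el$v, 3.2, arm_t)
    values <- paint_disc(values, wr$u, wr$v, 3.2, arm_t)
    if (sleeve == "Short")
      values <- paint_disc(values, (el$u + wr$u) / 2, (el$v + wr$v) / 2,
                           3.2, skin_t)
  }
  values
}

#' Generate a labelled synthetic thermal office scene
#'
#' Renders each scripted person as a warm blob (clothes-temperature torso
#' ellipse, skin-temperature head and arm discs at the keypoint locations)
#' over a uniform background with Gaussian sensor noise, quantized to the
#' camera step. Motion scripts drive the box trajectories and analytic
#' optical-flow fields (displacement mapped to 127-offset grayscale).
#' Detections and keypoints are derived from ground truth and then corrupted
#' according to the script's noise settings. The same script and seed
#' produce bit-identical output.
#'
#' @param script A [scene_script()].
#' @param render_thermal,render_flow Skip expensive renders when a consumer
#'   only needs part of the scene (e.g. feature extraction needs no thermal
#'   frames).
#' @return A list with `thermal` (list of matrices, or `NULL`), `flows`
#'   (list of [flow_field()]s, or `NULL`), `detections` (data frame),
#'   `keypoints` (per-frame list of skeleton data frames) and
#'   `ground_truth` (`boxes`, `persons`, `background_temperature`).
#' @export
generate_scene <- function(script, render_thermal = TRUE,
                           render_flow = TRUE) {
  stopifnot(inherits(script, "scene_script"))
  set.seed(script$seed)
  W <- script$frame_shape[1]; H <- script$frame_shape[2]
  nf <- script$n_frames
  noise <- script$noise
  npers <- length(script$persons)

  # 1. motion parameters and trajectories (fixed draw order)
  trajs <- vector("list", npers)
  flow_series <- vector("list", npers)
  for (i in seq_len(npers)) {
    p <- script$persons[[i]]
    mp <- draw_motion_params(p$behavior)
    mp$period <- stats::runif(1, 50, 90)
    mp$phase <- stats::runif(1, 0, 2 * pi)
    mp$phase2 <- stats::runif(1, 0, 2 * pi)
    mp$phase3 <- stats::runif(1, 0, 2 * pi)
    mp$flow_period <- stats::runif(1, 30, 70)
    mp$flow_phase <- stats::runif(1, 0, 2 * pi)
    trajs[[i]] <- person_trajectory(p, mp, nf, W, H)
    t <- seq_len(nf) - 1
    flow_series[[i]] <- mp$flow_amp * sin(2 * pi * t / mp$flow_period +
                                            mp$flow_phase)
  }

  gt_boxes <- do.call(rbind, lapply(seq_len(npers), function(i) {
    tr <- trajs[[i]]
    data.frame(frame = tr$frame, id = i, x = tr$x, y = tr$y, w = tr$w,
               h = tr$h, category = script$persons[[i]]$category,
               stringsAsFactors = FALSE)
  }))

  # 2. detections (jitter + misses + spurious boxes)
  det <- list()
  for (f in seq_len(nf) - 1L) {
    for (i in seq_len(npers)) {
      if (stats::runif(1) < noise$fn_rate) next
      tr <- trajs[[i]][f + 1L, ]
      det[[length(det) + 1L]] <- data.frame(
        frame = f,
        x = tr$x + stats::rnorm(1, 0, noise$jitter_sd),
        y = tr$y + stats::rnorm(1, 0, noise$jitter_sd),
        w = max(4, tr$w + stats::rnorm(1, 0, noise$jitter_sd)),
        h = max(4, tr$h + stats::rnorm(1, 0, noise$jitter_sd)),
        category = script$persons[[i]]$category,
        confidence = stats::runif(1, 0.75, 0.99),
        stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < noise$fp_rate) {
      fw <- stats::runif(1, 0.08, 0.25) * W
      fh <- stats::runif(1, 0.25, 0.70) * H
      det[[length(det) + 1L]] <- data.frame(
        frame = f, x = stats::runif(1, 0, W - fw),
        y = stats::runif(1, 0, H - fh), w = fw, h = fh,
        category = sample(person_categories, 1),
        confidence = stats::runif(1, 0.3, 0.7), stringsAsFactors = FALSE)
    }
  }
  detections <- if (length(det)) do.call(rbind, det) else
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               w = numeric(0), h = numeric(0), category = character(0),
               confidence = numeric(0))

  # 3. keypoints (true layout + jitter + confidence scores)
  keypoints <- vector("list", nf)
  true_kp <- vector("list", npers)
  for (i in seq_len(npers)) true_kp[[i]] <- vector("list", nf)
  for (f in seq_len(nf) - 1L) {
    frame_kps <- vector("list", npers)
    for (i in seq_len(npers)) {
      tr <- trajs[[i]][f + 1L, ]
      kp <- person_keypoints(tr$x, tr$y, tr$w, tr$h)
      true_kp[[i]][[f + 1L]] <- kp
      kp$u <- kp$u + stats::rnorm(nrow(kp), 0, noise$keypoint_jitter_sd)
      kp$v <- kp$v + stats::rnorm(nrow(kp), 0, noise$keypoint_jitter_sd)
      score <- stats::rnorm(nrow(kp), noise$keypoint_score_mean,
                            noise$keypoint_score_sd)
      kp$score <- pmin(pmax(score, 0.01), 0.99)
      occl <- kp$name %in% script$persons[[i]]$occluded_keypoints
      kp$score[occl] <- stats::runif(sum(occl), 0.05, 0.3)
      frame_kps[[i]] <- kp
    }
    keypoints[[f + 1L]] <- frame_kps
  }

  # 4. flow fields (analytic: scripted limb motion + box displacement)
  flows <- NULL
  if (render_flow) {
    flows <- vector("list", nf)
    for (f in seq_len(nf) - 1L) {
      fh <- matrix(127, H, W)
      fv <- matrix(127, H, W)
      for (i in seq_len(npers)) {
        tr <- trajs[[i]]
        row <- tr[f + 1L, ]
        ddx <- if (f == 0L) 0 else row$cx - tr$cx[f]
        ddy <- if (f == 0L) 0 else row$cy - tr$cy[f]
        a <- flow_series[[i]][f + 1L]
        px <- box_pixels(list(x = row$x, y = row$y, w = row$w, h = row$h),
                         W, H)
        if (is.null(px)) next
        clip255 <- function(v) min(max(v, 0), 255)
        fh[px$vs + 1L, px$us + 1L] <- clip255(127 + round(a + 8 * ddx))
        fv[px$vs + 1L, px$us + 1L] <- clip255(127 + round(0.6 * a + 8 * ddy))
      }
      flows[[f + 1L]] <- flow_field(fh, fv, validate = FALSE)
    }
  }

  # 5. thermal frames (blobs + sensor noise, quantized)
  thermal <- NULL
  if (render_thermal) {
    thermal <- vector("list", nf)
    q <- script$quantization_step
    for (f in seq_len(nf) - 1L) {
      values <- matrix(script$background_temperature, H, W)
      for (i in seq_len(npers)) {
        p <- script$persons[[i]]
        tr <- trajs[[i]][f + 1L, ]
        values <- render_person_thermal(values, tr$x, tr$y, tr$w, tr$h,
                                        true_kp[[i]][[f + 1L]], p$sleeve,
                                        p$skin_temperature,
                                        p$clothes_temperature)
      }
      values <- values + matrix(stats::rnorm(H * W, 0,
                                             noise$sensor_noise_sd), H, W)
      thermal[[f + 1L]] <- round(values / q) * q
    }
  }

  level_of <- c(still_sit = NA_character_, still_stand = "low",
                gesture_stand = "moderate", stretch_stand = "high",
                walk = "high")
  persons_gt <- do.call(rbind, lapply(seq_len(npers), function(i) {
    p <- script$persons[[i]]
    data.frame(id = i, behavior = p$behavior, sleeve = p$sleeve,
               posture = p$posture, category = p$category,
               skin_temperature = p$skin_temperature,
               clothes_temperature = p$clothes_temperature,
               activity_level = level_of[[p$behavior]],
               true_icl = compute_icl(p$skin_temperature,
                                      p$clothes_temperature,
                                      script$background_temperature),
               stringsAsFactors = FALSE)
  }))

  list(thermal = thermal, flows = flows, detections = detections,
       keypoints = keypoints,
       ground_truth = list(
         boxes = gt_boxes, persons = persons_gt,
         background_temperature = script$background_temperature),
       script = script)
}

#' Generate a labelled activity-feature dataset
#'
#' Draws feature sets for the three standing activity levels by scripting
#' synthetic scenes (`still_stand` for low, `gesture_stand` for moderate,
#' `stretch_stand` alternating with `walk` for high) and running
#' [extract_features()] on each, exactly as the live pipeline would.
#'
#' @param n_per_level Number of feature sets per level.
#' @param seed Integer seed; the emitted dataset is seed-deterministic.
#' @param config A [pipeline_config()]; its `activity_window_frames` sets
#'   the scene length.
#' @param frame_shape Scene size in pixels; small frames keep generation
#'   fast, the features being size-relative.
#' @return Data frame with columns `center_spread`, `scale_spread`,
#'   `flow_intensity`, `label`.
#' @export
generate_activity_dataset <- function(n_per_level, seed = 0L,
                                      config = pipeline_config(),
                                      frame_shape = c(160, 120)) {
  stopifnot(n_per_level >= 1)
  set.seed(as.integer(seed))
  n_total <- 3L * n_per_level
  sub_seeds <- sample.int(2^31 - 2, n_total)
  behaviors <- c(rep("still_stand", n_per_level),
                 rep("gesture_stand", n_per_level),
                 rep(c("stretch_stand", "walk"),
                     length.out = n_per_level))
  labels <- rep(c("low", "moderate", "high"), each = n_per_level)
  rows <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    script <- scene_script(
      persons = list(scene_person(behavior = behaviors[k], sleeve = "Long",
                                  width = 36, height = 84,
                                  center = c(frame_shape[1] / 2,
                                             frame_shape[2] * 0.55))),
      frame_shape = frame_shape,
      n_frames = config$activity_window_frames,
      seed = sub_seeds[k],
      noise = list(jitter_sd = 0.3, sensor_noise_sd = 0.1))
    scene <- generate_scene(script, render_thermal = FALSE)
    track <- track_from_boxes(scene$detections)
    feats <- extract_features(track, scene$flows, config)
    rows[[k]] <- data.frame(center_spread = feats$center_spread,
                            scale_spread = feats$scale_spread,
                            flow_intensity = feats$flow_intensity,
                            label = labels[k], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
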