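#' Person categories: sleeve status crossed with key posture
#'
#' The detector taxonomy used throughout the pipeline. Each tracked person
#' carries one of six categories combining a sleeve status (`Long`, `Short`,
#' or `Occluded` when the arms cannot be seen) with a key posture (`Sit` or
#' `Stand`). File formats encode them as integer codes 1--6 in this order.
#'
#' @format A character vector of length six.
#' @export
person_categories <- c("LongSit", "ShortSit", "OclSit",
                       "LongStand", "ShortStand", "OclStand")

.sleeve_of <- c(LongSit = "Long", ShortSit = "Short", OclSit = "Occluded",
                LongStand = "Long", ShortStand = "Short", OclStand = "Occluded")
.posture_of <- c(LongSit = "Sit", ShortSit = "Sit", OclSit = "Sit",
                 LongStand = "Stand", ShortStand = "Stand", OclStand = "Stand")

#' Decompose a person category into sleeve status and posture
#'
#' @param category One of the six values in [person_categories].
#' @return A list with elements `sleeve` (`"Long"`, `"Short"` or
#'   `"Occluded"`) and `posture` (`"Sit"` or `"Stand"`).
#' @examples
#' decompose_category("LongSit")
#' decompose_category("OclStand")
#' @export
decompose_category <- function(category) {
  if (length(category) != 1L || !is.character(category) ||
      !category %in% person_categories) {
    stop("unknown person category: ",
         paste(format(category), collapse = ", "),
         " (expected one of ", paste(person_categories, collapse = ", "), ")",
         call. = FALSE)
  }
  list(sleeve = unname(.sleeve_of[category]),
       posture = unname(.posture_of[category]))
}

#' Construct an axis-aligned bounding box
#'
#' Boxes use a 0-based, top-left pixel origin and are half-open:
#' `[x, x + w) x [y, y + h)`. `x` grows rightwards, `y` downwards.
#'
#' @param x,y Top-left corner, pixels.
#' @param w,h Width and height, pixels; both must be strictly positive.
#' @return A list of class `bounding_box`.
#' @export
bounding_box <- function(x, y, w, h) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(w), is.numeric(h),
            length(x) == 1L, length(y) == 1L, length(w) == 1L, length(h) == 1L)
  if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0)
    stop("bounding box width and height must be strictly positive",
         call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)),
            class = "bounding_box")
}

#' Intersection-over-union of two boxes
#'
#' @param a,b Boxes as created by [bounding_box()] or any list/row with
#'   fields `x`, `y`, `w`, `h`.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  if (union <= 0) return(0)
  inter / union
}

#' Pipeline configuration
#'
#' Bundles every tunable constant of the pipeline. Defaults reproduce the
#' study conditions: a 21 fps thermal camera (10 s = 210 frames), a 0.6
#' keypoint confidence threshold, a heat-transfer coefficient of
#' 8.6 W/(m^2 K), a sitting metabolic rate of 72.5 W/m^2 and standing
#' activity-level boundaries of 75/125/174 W/m^2.
#'
#' @param fps Camera frame rate, frames per second.
#' @param keypoint_conf_threshold Minimum pose-keypoint confidence score in
#'   `(0, 1)`; keypoints below it are discarded before region localization.
#' @param icl_window_frames Accumulation window for skin/clothes temperature
#'   samples, frames. Default five minutes.
#' @param activity_window_frames Window for the three activity-intensity
#'   features, frames. Default 210 (10 s).
#' @param vote_window_frames Window for per-track category voting, frames.
#'   Default 63 (3 s).
#' @param h_coefficient Human heat-transfer coefficient h, W/(m^2 K).
#' @param m_sitting Metabolic rate assigned to sitting persons, W/m^2.
#' @param m_levels Named numeric vector `c(low=, moderate=, high=)` of
#'   standing metabolic-rate boundaries Ml < Mm < Mh, W/m^2.
#' @param quantization_step Thermal camera temperature resolution, degrees C.
#' @param patch_size Odd side length of the pixel patch averaged around each
#'   sampled keypoint; 1 samples the single nearest pixel.
#' @param icl_epsilon Minimum `|Tc - To|` (degrees C) below which the Icl
#'   formula is treated as ill-conditioned.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fps = 21,
                            keypoint_conf_threshold = 0.6,
                            icl_window_frames = 5 * 60 * fps,
                            activity_window_frames = 210,
                            vote_window_frames = 63,
                            h_coefficient = 8.6,
                            m_sitting = 72.5,
                            m_levels = c(low = 75, moderate = 125, high = 174),
                            quantization_step = 0.08,
                            patch_size = 1,
                            icl_epsilon = 0.1) {
  cfg <- list(fps = as.numeric(fps),
              keypoint_conf_threshold = as.numeric(keypoint_conf_threshold),
              icl_window_frames = as.integer(icl_window_frames),
              activity_window_frames = as.integer(activity_window_frames),
              vote_window_frames = as.integer(vote_window_frames),
              h_coefficient = as.numeric(h_coefficient),
              m_sitting = as.numeric(m_sitting),
              m_levels = m_levels,
              quantization_step = as.numeric(quantization_step),
              patch_size = as.integer(patch_size),
              icl_epsilon = as.numeric(icl_epsilon))
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$fps > 0)
  if (cfg$keypoint_conf_threshold <= 0 || cfg$keypoint_conf_threshold >= 1)
    stop("keypoint_conf_threshold must lie in (0, 1)", call. = FALSE)
  for (f in c("icl_window_frames", "activity_window_frames",
              "vote_window_frames"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop(f, " must be at least 1 frame", call. = FALSE)
  lv <- cfg$m_levels
  if (length(lv) != 3L || is.null(names(lv)) ||
      !identical(names(lv), c("low", "moderate", "high")))
    stop("m_levels must be a named vector c(low=, moderate=, high=)",
         call. = FALSE)
  if (!(lv[["low"]] < lv[["moderate"]] && lv[["moderate"]] < lv[["high"]]))
    stop("m_levels must satisfy low < moderate < high", call. = FALSE)
  if (cfg$quantization_step <= 0)
    stop("quantization_step must be positive", call. = FALSE)
  if (cfg$patch_size < 1L || cfg$patch_size %% 2L == 0L)
    stop("patch_size must be a positive odd integer", call. = FALSE)
  if (cfg$h_coefficient <= 0)
    stop("h_coefficient must be positive", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' The configuration file is a flat YAML document whose keys mirror the
#' argument names of [pipeline_config()] exactly; `m_levels` is a mapping
#' with keys `low`, `moderate`, `high`. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$m_levels)) raw$m_levels <- unlist(raw$m_levels)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config` to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out$m_levels <- as.list(out$m_levels)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, paste(format(v), collapse = " / ")))
  }
  invisible(x)
}

#' Supported pose keypoint names
#'
#' Only the keypoints that influence skin/clothes region localization are
#' used: the nose, both shoulders, both elbows and both wrists.
#' @export
supported_keypoints <- c("nose", "left_shoulder", "right_shoulder",
                         "left_elbow", "right_elbow",
                         "left_wrist", "right_wrist")
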