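# Interchange formats: MOTChallenge-style detection/track CSV, COCO-17
# keypoint JSON, multi-page float TIFF thermal stacks, 8-bit PNG flow pairs
# and JSON run manifests. File frame numbers are 1-based (MOT convention)
# and converted to the package's 0-based indices on read.

category_code <- function(category) {
  code <- match(as.character(category), person_categories)
  if (anyNA(code))
    stop("unknown person category: ",
         paste(unique(as.character(category)[is.na(code)]), collapse = ", "),
         call. = FALSE)
  code
}

category_from_code <- function(code) {
  if (any(is.na(code)) || any(code < 1) || any(code > 6) ||
      any(code != round(code))) {
    bad <- unique(code[is.na(code) | code < 1 | code > 6 |
                         code != round(code)])
    stop("invalid class code(s): class ", paste(bad, collapse = ", class "),
         " (expected 1-6)", call. = FALSE)
  }
  person_categories[code]
}

num17 <- function(x) formatC(x, digits = 17, format = "g")

parse_mot_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(matrix(numeric(0), 0, 9))
  parts <- strsplit(lines, ",", fixed = TRUE)
  nfields <- lengths(parts)
  if (any(nfields != 9L))
    stop("malformed row at line ", which(nfields != 9L)[1], " of ", path,
         ": expected 9 comma-separated fields, got ",
         nfields[which(nfields != 9L)[1]], call. = FALSE)
  vals <- suppressWarnings(vapply(parts, as.numeric, numeric(9)))
  bad <- which(colSums(is.na(vals)) > 0)
  if (length(bad) > 0)
    stop("malformed row at line ", bad[1], " of ", path,
         ": non-numeric field", call. = FALSE)
  t(vals)
}

#' Read / write detections in MOTChallenge CSV dialect
#'
#' Rows are `frame,id,x,y,w,h,conf,class,vis` with 1-based frame numbers in
#' the file (0-based in memory), `id = -1` for raw detections, and `class`
#' the integer category code 1-6 (the index into [person_categories]).
#'
#' @param path CSV file path.
#' @return `read_detections` returns a data frame `frame, x, y, w, h,
#'   category, confidence`; an empty file yields a zero-row frame.
#' @export
read_detections <- function(path) {
  m <- parse_mot_file(path)
  if (nrow(m) == 0L)
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0), category = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  data.frame(frame = as.integer(m[, 1]) - 1L, x = m[, 3], y = m[, 4],
             w = m[, 5], h = m[, 6],
             category = category_from_code(m[, 8]),
             confidence = m[, 7], stringsAsFactors = FALSE)
}

#' @rdname read_detections
#' @param detections Data frame as returned by [read_detections()].
#' @export
write_detections <- function(detections, path) {
  lines <- if (nrow(detections) == 0L) character(0) else
    paste(detections$frame + 1L, -1L,
          num17(detections$x), num17(detections$y),
          num17(detections$w), num17(detections$h),
          num17(detections$confidence),
          category_code(detections$category), 1, sep = ",")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write confirmed-track boxes in MOT CSV dialect
#'
#' Same dialect as [read_detections()] but with real track ids. When the
#' track table carries no categories the class field is written as code 1.
#'
#' @param path CSV file path.
#' @return `read_tracks` returns a data frame `frame, id, x, y, w, h,
#'   category, confidence`.
#' @export
read_tracks <- function(path) {
  m <- parse_mot_file(path)
  if (nrow(m) == 0L)
    return(data.frame(frame = integer(0), id = integer(0), x = numeric(0),
                      y = numeric(0), w = numeric(0), h = numeric(0),
                      category = character(0), confidence = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(frame = as.integer(m[, 1]) - 1L, id = as.integer(m[, 2]),
             x = m[, 3], y = m[, 4], w = m[, 5], h = m[, 6],
             category = category_from_code(m[, 8]), confidence = m[, 7],
             stringsAsFactors = FALSE)
}

#' @rdname read_tracks
#' @param tracks Data frame with `frame, id, x, y, w, h` and optionally
#'   `category`, `confidence`.
#' @export
write_tracks <- function(tracks, path) {
  cat_code <- if ("category" %in% names(tracks))
    category_code(tracks$category) else rep(1L, nrow(tracks))
  conf <- if ("confidence" %in% names(tracks)) tracks$confidence else
    rep(1, nrow(tracks))
  lines <- if (nrow(tracks) == 0L) character(0) else
    paste(tracks$frame + 1L, tracks$id, num17(tracks$x), num17(tracks$y),
          num17(tracks$w), num17(tracks$h), num17(conf), cat_code, 1,
          sep = ",")
  writeLines(lines, path)
  invisible(path)
}

# COCO-17 keypoint indices (0-based) for the seven supported names
.coco17_index <- c(nose = 0L, left_shoulder = 5L, right_shoulder = 6L,
                   left_elbow = 7L, right_elbow = 8L, left_wrist = 9L,
                   right_wrist = 10L)

#' Read / write keypoint skeletons as COCO-17 JSON
#'
#' The file holds `{"format": "coco17", "frames": [{"frame": <1-based>,
#' "people": [{"keypoints": [[u, v, score] x 17]}]}]}`. Only the seven
#' indices that matter for region localization (nose 0, shoulders 5/6,
#' elbows 7/8, wrists 9/10) are read; the writer zero-fills the rest.
#'
#' @param path JSON file path.
#' @param n_frames Length of the returned per-frame list (defaults to the
#'   largest frame number in the file).
#' @return `read_keypoints` returns a list indexed by `frame + 1`; each
#'   element is a list of skeleton data frames (`name, u, v, score`).
#' @export
read_keypoints <- function(path, n_frames = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$frames))
    stop("keypoint file has no 'frames' field: ", path, call. = FALSE)
  max_frame <- 0L
  for (fr in doc$frames) max_frame <- max(max_frame, as.integer(fr$frame))
  if (is.null(n_frames)) n_frames <- max_frame
  out <- rep(list(list()), n_frames)
  for (fr in doc$frames) {
    f <- as.integer(fr$frame) - 1L
    skeletons <- lapply(fr$people, function(person) {
      kp <- person$keypoints
      if (length(kp) != 17L)
        stop("expected 17 keypoints per person in ", path, call. = FALSE)
      idx <- .coco17_index
      data.frame(name = names(idx),
                 u = vapply(idx, function(i) as.numeric(kp[[i + 1L]][[1]]),
                            numeric(1)),
                 v = vapply(idx, function(i) as.numeric(kp[[i + 1L]][[2]]),
                            numeric(1)),
                 score = vapply(idx, function(i)
                   as.numeric(kp[[i + 1L]][[3]]), numeric(1)),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    out[[f + 1L]] <- skeletons
  }
  out
}

#' @rdname read_keypoints
#' @param keypoints_by_frame List indexed by `frame + 1` of skeleton data
#'   frames (or lists thereof).
#' @export
write_keypoints <- function(keypoints_by_frame, path) {
  frames <- list()
  for (f in seq_along(keypoints_by_frame)) {
    sks <- keypoints_by_frame[[f]]
    if (is.data.frame(sks)) sks <- list(sks)
    if (length(sks) == 0L) next
    people <- lapply(sks, function(sk) {
      kp <- rep(list(c(0, 0, 0)), 17L)
      for (i in seq_len(nrow(sk))) {
        idx <- .coco17_index[[sk$name[i]]]
        kp[[idx + 1L]] <- c(sk$u[i], sk$v[i], sk$score[i])
      }
      list(keypoints = kp)
    })
    frames[[length(frames) + 1L]] <- list(frame = f, people = people)
  }
  jsonlite::write_json(list(format = "coco17", frames = frames), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Stored TIFF sample = degrees C / `scale` so values stay in the [0, 1]
# range that baseline float-TIFF readers clamp to; exact to ~1e-5 degC.
.thermal_scale <- 100

#' Read / write a thermal frame stack as multi-page float TIFF
#'
#' Each page is one frame; 32-bit float samples store degrees C divided by
#' 100 (documented scale, so all indoor temperatures stay inside the unit
#' range common TIFF readers clamp to) and are rescaled on read.
#'
#' @param path TIFF file path.
#' @return `read_thermal_stack` returns a list of temperature matrices
#'   (degrees C), indexed by `frame + 1`.
#' @export
read_thermal_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(p) p * .thermal_scale)
}

#' @rdname read_thermal_stack
#' @param frames List of temperature matrices (degrees C).
#' @export
write_thermal_stack <- function(frames, path) {
  stopifnot(length(frames) > 0)
  pages <- lapply(frames, function(f) f / .thermal_scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Read / write optical-flow fields as 8-bit PNG pairs
#'
#' Frame `f` (0-based) is stored as `flow_x_<f>.png` and `flow_y_<f>.png`
#' (grayscale, 127 = zero motion).
#'
#' @param dir Directory holding the flow images.
#' @param n_frames Number of frames to read.
#' @return `read_flow_fields` returns a list of [flow_field()]s indexed by
#'   `frame + 1`.
#' @export
read_flow_fields <- function(dir, n_frames) {
  lapply(seq_len(n_frames) - 1L, function(f) {
    fx <- file.path(dir, sprintf("flow_x_%06d.png", f))
    fy <- file.path(dir, sprintf("flow_y_%06d.png", f))
    if (!file.exists(fx) || !file.exists(fy))
      stop("missing flow image(s) for frame ", f, " in ", dir, call. = FALSE)
    flow_field(round(png::readPNG(fx) * 255), round(png::readPNG(fy) * 255))
  })
}

#' @rdname read_flow_fields
#' @param flows List of [flow_field()]s indexed by `frame + 1`.
#' @export
write_flow_fields <- function(flows, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(flows) - 1L) {
    fl <- flows[[f + 1L]]
    png::writePNG(fl$horizontal / 255,
                  file.path(dir, sprintf("flow_x_%06d.png", f)))
    png::writePNG(fl$vertical / 255,
                  file.path(dir, sprintf("flow_y_%06d.png", f)))
  }
  invisible(dir)
}

#' Write a generated scene to a self-contained directory
#'
#' Emits `thermal.tiff`, `detections.csv`, `keypoints.json`, `flow/`,
#' `ground_truth_boxes.csv`, `ground_truth_persons.csv` and `scene.json`.
#'
#' @param scene Output of [generate_scene()].
#' @param dir Destination directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(scene$thermal))
    write_thermal_stack(scene$thermal, file.path(dir, "thermal.tiff"))
  if (!is.null(scene$flows))
    write_flow_fields(scene$flows, file.path(dir, "flow"))
  write_detections(scene$detections, file.path(dir, "detections.csv"))
  kp <- lapply(scene$keypoints, function(x) x)
  write_keypoints(kp, file.path(dir, "keypoints.json"))
  gt <- scene$ground_truth$boxes
  write_tracks(gt, file.path(dir, "ground_truth_boxes.csv"))
  utils::write.csv(scene$ground_truth$persons,
                   file.path(dir, "ground_truth_persons.csv"),
                   row.names = FALSE)
  meta <- list(n_frames = scene$script$n_frames,
               frame_shape = scene$script$frame_shape,
               fps = scene$script$fps, seed = scene$script$seed,
               background_temperature =
                 scene$ground_truth$background_temperature)
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir Scene directory.
#' @return A list with `thermal`, `flows`, `detections`, `keypoints`,
#'   `ground_truth` and `meta` (missing artifacts are `NULL`).
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  nf <- meta$n_frames
  thermal <- if (file.exists(file.path(dir, "thermal.tiff")))
    read_thermal_stack(file.path(dir, "thermal.tiff")) else NULL
  flows <- if (dir.exists(file.path(dir, "flow")))
    read_flow_fields(file.path(dir, "flow"), nf) else NULL
  gt_boxes <- read_tracks(file.path(dir, "ground_truth_boxes.csv"))
  gt_persons <- utils::read.csv(file.path(dir, "ground_truth_persons.csv"),
                                stringsAsFactors = FALSE)
  list(thermal = thermal, flows = flows,
       detections = read_detections(file.path(dir, "detections.csv")),
       keypoints = read_keypoints(file.path(dir, "keypoints.json"), nf),
       ground_truth = list(boxes = gt_boxes, persons = gt_persons,
                           background_temperature =
                             meta$background_temperature),
       meta = meta)
}

#' Build a run manifest
#'
#' Records the resolved configuration, input file digests, package version,
#' seeds and per-stage record counts; every CLI run writes one next to its
#' outputs so results can be traced to their exact inputs.
#'
#' @param config The resolved `pipeline_config`.
#' @param inputs Named character vector of input file paths (digested with
#'   MD5).
#' @param seed Seed(s) used by the run.
#' @param counts Named list of per-stage record counts.
#' @param notes Optional character vector of run notes (e.g. windows skipped
#'   because they were not full).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, inputs = character(0), seed = NA_integer_,
                         counts = list(), notes = character(0)) {
  digests <- if (length(inputs) > 0)
    vapply(inputs, function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
      character(1)) else character(0)
  structure(list(
    tool = "thermotrack",
    version = as.character(utils::packageVersion("thermotrack")),
    config = unclass(config),
    inputs = as.list(inputs), input_md5 = as.list(digests),
    seed = seed, counts = counts, notes = as.list(notes)),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Destination JSON file.
#' @export
write_manifest <- function(manifest, path) {
  out <- unclass(manifest)
  out$config$m_levels <- as.list(out$config$m_levels)
  out$config$appearance_hook <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
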