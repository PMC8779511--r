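#' CLEAR-MOT event counts
#'
#' @param gt Total number of ground-truth person boxes over all frames.
#' @param fn False negatives (missed ground-truth boxes).
#' @param fp False positives (hypothesis boxes matching no ground truth).
#' @param idsw Identity switches of matched ground-truth objects.
#' @return A list of class `mot_counts`.
#' @export
mot_counts <- function(gt, fn, fp, idsw) {
  stopifnot(gt >= 0, fn >= 0, fp >= 0, idsw >= 0)
  if (fn > gt) stop("fn cannot exceed gt", call. = FALSE)
  structure(list(gt = as.integer(gt), fn = as.integer(fn),
                 fp = as.integer(fp), idsw = as.integer(idsw)),
            class = "mot_counts")
}

#' Multiple Object Tracking Accuracy
#'
#' `MOTA = 100 * (1 - (FN + FP + IDSW) / GT)`, in percent.
#'
#' @param counts A [mot_counts()], or the `gt` count when the remaining
#'   counts are given separately.
#' @param fn,fp,idsw Event counts when `counts` is the scalar `gt`.
#' @return MOTA in percent (can be negative for very poor tracking).
#' @examples
#' compute_mota(mot_counts(gt = 44077, fn = 206, fp = 16, idsw = 0))
#' @export
compute_mota <- function(counts, fn = NULL, fp = NULL, idsw = NULL) {
  if (!inherits(counts, "mot_counts"))
    counts <- mot_counts(counts, fn, fp, idsw)
  if (counts$gt == 0L)
    stop("MOTA is undefined for zero ground-truth objects", call. = FALSE)
  100 * (1 - (counts$fn + counts$fp + counts$idsw) / counts$gt)
}

#' Frame-level accuracy from an error count
#'
#' Percentage of frames free of errors: `100 * (1 - n_errors / n_frames)`.
#' Used e.g. to summarize keypoint-localization checks where a frame with any
#' wrongly placed keypoint counts as one error frame.
#'
#' @param n_errors Number of error frames.
#' @param n_frames Total frames examined (> 0).
#' @return Accuracy in percent.
#' @examples
#' frame_accuracy(187, 4901)
#' @export
frame_accuracy <- function(n_errors, n_frames) {
  stopifnot(n_frames > 0, n_errors >= 0, n_errors <= n_frames)
  100 * (1 - n_errors / n_frames)
}

#' Evaluate tracking hypotheses against ground truth (CLEAR-MOT)
#'
#' Per frame, ground-truth and hypothesis boxes are matched by maximal IoU
#' (correspondences carried over from the previous frame are kept while their
#' IoU stays above the threshold, then remaining pairs are matched by
#' minimum-cost assignment). Unmatched ground truth counts as FN, unmatched
#' hypotheses as FP, and a matched ground-truth object whose hypothesis id
#' differs from its last matched id counts one identity switch.
#'
#' @param ground_truth Data frame `frame, id, x, y, w, h` of true boxes.
#' @param hypotheses Data frame `frame, id, x, y, w, h` of tracker output.
#' @param iou_match Minimum IoU for a valid correspondence (default 0.5).
#' @return A [mot_counts()].
#' @export
evaluate_tracking <- function(ground_truth, hypotheses, iou_match = 0.5) {
  need <- c("frame", "id", "x", "y", "w", "h")
  stopifnot(all(need %in% names(ground_truth)),
            all(need %in% names(hypotheses)))
  frames <- sort(unique(c(ground_truth$frame, hypotheses$frame)))
  fn <- 0L; fp <- 0L; idsw <- 0L; gt_total <- 0L
  last_match <- list()   # gt id (char) -> last hyp id ever matched
  prev_corr <- list()    # gt id (char) -> hyp id active in previous frame

  for (f in frames) {
    g <- ground_truth[ground_truth$frame == f, , drop = FALSE]
    h <- hypotheses[hypotheses$frame == f, , drop = FALSE]
    gt_total <- gt_total + nrow(g)
    ng <- nrow(g); nh <- nrow(h)
    g_used <- rep(FALSE, ng); h_used <- rep(FALSE, nh)
    corr <- list()

    # 1. keep still-valid correspondences from the previous frame
    for (gid in names(prev_corr)) {
      gi <- which(as.character(g$id) == gid)
      hi <- which(h$id == prev_corr[[gid]])
      if (length(gi) == 1L && length(hi) == 1L) {
        iou <- box_iou(as.list(g[gi, c("x", "y", "w", "h")]),
                       as.list(h[hi, c("x", "y", "w", "h")]))
        if (iou >= iou_match) {
          g_used[gi] <- TRUE; h_used[hi] <- TRUE
          corr[[gid]] <- h$id[hi]
        }
      }
    }

    # 2. assignment on the rest
    gi_free <- which(!g_used); hi_free <- which(!h_used)
    if (length(gi_free) > 0 && length(hi_free) > 0) {
      cost <- matrix(Inf, length(gi_free), length(hi_free))
      for (a in seq_along(gi_free)) for (b in seq_along(hi_free)) {
        iou <- box_iou(as.list(g[gi_free[a], c("x", "y", "w", "h")]),
                       as.list(h[hi_free[b], c("x", "y", "w", "h")]))
        if (iou >= iou_match) cost[a, b] <- 1 - iou
      }
      assign <- solve_assignment(cost)
      for (a in seq_along(gi_free)) {
        b <- assign[a]
        if (!is.na(b)) {
          gi <- gi_free[a]; hi <- hi_free[b]
          g_used[gi] <- TRUE; h_used[hi] <- TRUE
          corr[[as.character(g$id[gi])]] <- h$id[hi]
        }
      }
    }

    # 3. switches, misses, false positives
    for (gid in names(corr)) {
      hid <- corr[[gid]]
      if (!is.null(last_match[[gid]]) && last_match[[gid]] != hid)
        idsw <- idsw + 1L
      last_match[[gid]] <- hid
    }
    fn <- fn + sum(!g_used)
    fp <- fp + sum(!h_used)
    prev_corr <- corr
  }
  mot_counts(gt_total, fn, fp, idsw)
}
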