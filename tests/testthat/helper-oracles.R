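# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check: assignment is solved by
# exhaustive enumeration and MOT counting by brute-force per-frame matching.

# Enumerate every injective row->column map (rows may stay unmatched via
# forbidden/omitted pairs); return the maximum-cardinality, minimum-cost one.
brute_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  best <- list(match = rep(NA_integer_, n), card = -1L, cost = Inf)
  rec <- function(i, used, cur) {
    if (i > n) {
      idx <- which(!is.na(cur))
      card <- length(idx)
      cc <- if (card > 0) sum(cost[cbind(idx, cur[idx])]) else 0
      if (card > best$card || (card == best$card && cc < best$cost))
        best <<- list(match = cur, card = card, cost = cc)
      return(invisible())
    }
    rec(i + 1L, used, c(cur, NA_integer_))
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(cost[i, j]))
        rec(i + 1L, replace(used, j, TRUE), c(cur, j))
    }
  }
  rec(1L, rep(FALSE, m), integer(0))
  best
}

iou_ref <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  u <- a$w * a$h + b$w * b$h - inter
  if (u <= 0) 0 else inter / u
}

# Brute-force CLEAR-MOT counter: carry over still-valid correspondences,
# then exhaustively match the remainder (max cardinality, min total 1-IoU).
clear_mot_oracle <- function(gt, hyp, iou_match = 0.5) {
  frames <- sort(unique(c(gt$frame, hyp$frame)))
  fn <- fp <- idsw <- gtn <- 0L
  last <- list()
  prev <- list()
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    h <- hyp[hyp$frame == f, , drop = FALSE]
    gtn <- gtn + nrow(g)
    gu <- rep(FALSE, nrow(g))
    hu <- rep(FALSE, nrow(h))
    corr <- list()
    for (gid in names(prev)) {
      gi <- which(as.character(g$id) == gid)
      hi <- which(h$id == prev[[gid]])
      if (length(gi) == 1L && length(hi) == 1L &&
          iou_ref(as.list(g[gi, ]), as.list(h[hi, ])) >= iou_match) {
        gu[gi] <- TRUE
        hu[hi] <- TRUE
        corr[[gid]] <- h$id[hi]
      }
    }
    fg <- which(!gu)
    fh <- which(!hu)
    if (length(fg) > 0 && length(fh) > 0) {
      cost <- matrix(Inf, length(fg), length(fh))
      for (a in seq_along(fg)) {
        for (b in seq_along(fh)) {
          v <- iou_ref(as.list(g[fg[a], ]), as.list(h[fh[b], ]))
          if (v >= iou_match) cost[a, b] <- 1 - v
        }
      }
      res <- brute_assignment(cost)
      for (a in seq_along(fg)) {
        b <- res$match[a]
        if (!is.na(b)) {
          gu[fg[a]] <- TRUE
          hu[fh[b]] <- TRUE
          corr[[as.character(g$id[fg[a]])]] <- h$id[fh[b]]
        }
      }
    }
    for (gid in names(corr)) {
      if (!is.null(last[[gid]]) && last[[gid]] != corr[[gid]])
        idsw <- idsw + 1L
      last[[gid]] <- corr[[gid]]
    }
    fn <- fn + sum(!gu)
    fp <- fp + sum(!hu)
    prev <- corr
  }
  list(gt = gtn, fn = fn, fp = fp, idsw = idsw)
}

# Random small tracking scenario: a few random-walk ground-truth objects and
# a hypothesis stream derived from them by dropping boxes, adding clutter
# and relabelling ids, so every CLEAR event type occurs.
random_mot_scenario <- function(seed) {
  set.seed(seed)
  n_obj <- sample(1:3, 1)
  n_frames <- sample(4:8, 1)
  gt <- do.call(rbind, lapply(seq_len(n_obj), function(i) {
    x <- runif(1, 0, 150)
    y <- runif(1, 0, 100)
    steps_x <- cumsum(c(x, runif(n_frames - 1, -5, 5)))
    steps_y <- cumsum(c(y, runif(n_frames - 1, -5, 5)))
    data.frame(frame = seq_len(n_frames) - 1L, id = i, x = steps_x,
               y = steps_y, w = runif(1, 20, 40), h = runif(1, 30, 60))
  }))
  hyp <- gt
  hyp$x <- hyp$x + runif(nrow(hyp), -2, 2)
  hyp$y <- hyp$y + runif(nrow(hyp), -2, 2)
  hyp <- hyp[runif(nrow(hyp)) > 0.15, , drop = FALSE]  # misses
  relabel <- sample(1:2, 1) == 1
  if (relabel && n_obj >= 1) {
    swap_from <- sample(n_frames, 1) - 1L
    hyp$id[hyp$frame >= swap_from & hyp$id == 1] <- 99L
  }
  n_fp <- sample(0:2, 1)
  if (n_fp > 0) {
    hyp <- rbind(hyp, data.frame(
      frame = sample(seq_len(n_frames) - 1L, n_fp, replace = TRUE),
      id = 500 + seq_len(n_fp), x = runif(n_fp, 200, 300),
      y = runif(n_fp, 150, 250), w = runif(n_fp, 20, 40),
      h = runif(n_fp, 30, 60)))
  }
  list(gt = gt, hyp = hyp)
}
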