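# Detection evaluation: greedy IoU matching, precision/recall, all-point
# interpolated average precision, F1, FPS accounting.

#' Match detections against ground truth (one image, one class space)
#'
#' Detections are processed in order of descending score (ties broken by box
#' coordinates). A detection is a true positive iff the best-IoU unmatched
#' ground-truth box of the same class has IoU >= `iou_threshold`; every
#' ground truth is matched at most once.
#'
#' @param dets data frame with `class_id`, `score`, `x1, y1, x2, y2`.
#' @param gts data frame with `class_id`, `x1, y1, x2, y2`.
#' @param iou_threshold match threshold (default 0.5).
#' @return a `crl_match` object: per class `tp`, `fp`, `fn`, plus the
#'   score-ranked TP/FP `flags` and `scores`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  classes <- sort(unique(c(dets$class_id, gts$class_id)))
  out <- list()
  for (cl in classes) {
    d <- dets[dets$class_id == cl, , drop = FALSE]
    g <- gts[gts$class_id == cl, , drop = FALSE]
    if (nrow(d) > 0L)
      d <- d[order(-d$score, d$x1, d$y1, d$x2, d$y2), , drop = FALSE]
    matched <- rep(FALSE, nrow(g))
    flags <- logical(nrow(d))
    gb <- as.matrix(g[, c("x1", "y1", "x2", "y2"), drop = FALSE])
    for (i in seq_len(nrow(d))) {
      if (nrow(g) == 0L) break
      iou <- box_iou(as.numeric(d[i, c("x1", "y1", "x2", "y2")]), gb)
      iou[matched] <- -1
      j <- which.max(iou)
      if (length(j) == 1L && iou[j] >= iou_threshold) {
        flags[i] <- TRUE
        matched[j] <- TRUE
      }
    }
    out[[as.character(cl)]] <- list(
      tp = sum(flags), fp = sum(!flags), fn = sum(!matched),
      flags = flags, scores = d$score, n_gt = nrow(g))
  }
  structure(list(classes = out), class = "crl_match")
}

#' Precision and recall from a match result
#'
#' Micro-averaged over classes: `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, with the
#' convention 0/0 = 0.
#'
#' @param m a `crl_match` from [match_detections()], or a list with `tp`,
#'   `fp`, `fn`.
#' @return named numeric `c(P = ..., R = ...)`.
#' @export
precision_recall <- function(m) {
  if (inherits(m, "crl_match")) {
    tp <- sum(vapply(m$classes, `[[`, numeric(1), "tp"))
    fp <- sum(vapply(m$classes, `[[`, numeric(1), "fp"))
    fn <- sum(vapply(m$classes, `[[`, numeric(1), "fn"))
  } else {
    tp <- m$tp; fp <- m$fp; fn <- m$fn
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(P = p, R = r)
}

#' All-point interpolated average precision
#'
#' Area under the precision envelope over recall, computed from a
#' score-ranked sequence of TP/FP flags.
#'
#' @param flags logical vector, TRUE for a true positive, ranked by
#'   descending score.
#' @param n_gt number of ground-truth boxes.
#' @return AP in `[0, 1]`; 0 when there are no ground truths or no detections.
#' @export
average_precision <- function(flags, n_gt) {
  stopifnot(n_gt >= 0)
  if (n_gt == 0L || length(flags) == 0L) return(0)
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  rec <- tp / n_gt
  prec <- tp / (tp + fp)
  mrec <- c(0, rec)
  mpre <- c(1, prec)
  # precision envelope (monotone non-increasing from the right)
  for (i in rev(seq_len(length(mpre) - 1L)))
    mpre[i] <- max(mpre[i], mpre[i + 1L])
  sum(diff(mrec) * mpre[-1L])
}

#' Mean average precision over classes
#'
#' @param aps numeric vector of per-class AP values.
#' @return their unweighted mean (0 for an empty vector).
#' @export
map50 <- function(aps) {
  if (length(aps) == 0L) return(0)
  mean(aps)
}

#' F1 score
#'
#' Harmonic mean of precision and recall; 0 when `P + R == 0`.
#'
#' @param p,r precision and recall in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(p, r) {
  stopifnot(p >= 0, p <= 1, r >= 0, r <= 1)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Frames per second from stage timings
#'
#' `1000 / (preprocessing + inference + postprocessing)`, all in
#' milliseconds, batch size 1.
#'
#' @param pre_ms,infer_ms,post_ms per-image stage times in milliseconds.
#' @return frames per second.
#' @export
measure_fps <- function(pre_ms, infer_ms, post_ms) {
  if (any(c(pre_ms, infer_ms, post_ms) <= 0))
    stop("measure_fps: all stage times must be positive")
  1000 / (pre_ms + infer_ms + post_ms)
}

# Dataset-level evaluation: accumulate ranked flags per class across images.
#' Evaluate detections over a dataset
#'
#' @param det_list list of per-image detection data frames.
#' @param gt_list list of per-image ground-truth data frames.
#' @param num_classes number of classes.
#' @param iou_threshold IoU match threshold (0.5 for mAP at 0.5).
#' @return list with per-class `P`, `R`, `AP`, `F1` and the class-mean
#'   `mAP50`, `P`, `R`, `F1`.
#' @export
evaluate_detections <- function(det_list, gt_list, num_classes,
                                iou_threshold = 0.5) {
  acc <- lapply(seq_len(num_classes), function(i)
    list(flags = logical(), scores = numeric(), n_gt = 0L))
  for (i in seq_along(det_list)) {
    m <- match_detections(det_list[[i]], gt_list[[i]], iou_threshold)
    for (cl_name in names(m$classes)) {
      cl <- as.integer(cl_name) + 1L
      e <- m$classes[[cl_name]]
      acc[[cl]]$flags <- c(acc[[cl]]$flags, e$flags)
      acc[[cl]]$scores <- c(acc[[cl]]$scores, e$scores)
      acc[[cl]]$n_gt <- acc[[cl]]$n_gt + e$n_gt
    }
  }
  per_class <- lapply(acc, function(a) {
    o <- order(-a$scores)
    flags <- a$flags[o]
    tp <- sum(flags); fp <- sum(!flags); fn <- a$n_gt - tp
    pr <- precision_recall(list(tp = tp, fp = fp, fn = fn))
    list(P = pr[["P"]], R = pr[["R"]],
         AP = average_precision(flags, a$n_gt),
         F1 = f1_score(pr[["P"]], pr[["R"]]))
  })
  list(per_class = per_class,
       P = mean(vapply(per_class, `[[`, numeric(1), "P")),
       R = mean(vapply(per_class, `[[`, numeric(1), "R")),
       F1 = mean(vapply(per_class, `[[`, numeric(1), "F1")),
       mAP50 = map50(vapply(per_class, `[[`, numeric(1), "AP")))
}
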