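# Training objective: task-aligned assignment, binary cross-entropy
# classification, complete-IoU box loss and distribution-focal loss, with
# analytic gradients with respect to the raw head outputs.

TAL_TOPK <- 10L
TAL_ALPHA <- 0.5
TAL_BETA <- 6.0
LOSS_W_CLS <- 0.5
LOSS_W_BOX <- 7.5
LOSS_W_DFL <- 1.5

# anchor table for a set of feature levels: centre (pixels) and stride,
# cell order h-fastest within each level
anchor_table <- function(level_dims, strides) {
  out <- list()
  for (l in seq_along(level_dims)) {
    h <- level_dims[[l]][1L]; w <- level_dims[[l]][2L]; s <- strides[l]
    rows <- rep(seq_len(h) - 1L, times = w)
    cols <- rep(seq_len(w) - 1L, each = h)
    out[[l]] <- data.frame(cx = (cols + 0.5) * s, cy = (rows + 0.5) * s,
                           stride = s, level = l)
  }
  do.call(rbind, out)
}

# flatten one image of a (B, C, h, w) level array to (h*w) x C, h-fastest
flat_chw <- function(arr, n) {
  d <- dim(arr)
  a <- arr[n, , , ]
  dim(a) <- c(d[2L], d[3L] * d[4L])
  t(a)
}

# inverse of flat_chw for gradients: (h*w) x C -> (C, h, w)
unflat_chw <- function(mat, h, w) {
  array(t(mat), dim = c(ncol(mat), h, w))
}

# complete IoU and its gradient wrt the predicted box corners
ciou_grad <- function(a, b) {
  ax1 <- a[1]; ay1 <- a[2]; ax2 <- a[3]; ay2 <- a[4]
  bx1 <- b[1]; by1 <- b[2]; bx2 <- b[3]; by2 <- b[4]
  aw <- ax2 - ax1; ah <- ay2 - ay1
  bw <- bx2 - bx1; bh <- by2 - by1
  iw <- min(ax2, bx2) - max(ax1, bx1)
  ih <- min(ay2, by2) - max(ay1, by1)
  I <- max(iw, 0) * max(ih, 0)
  Aa <- aw * ah; Ab <- bw * bh
  U <- Aa + Ab - I
  iou <- if (U > 0) I / U else 0

  dI <- c(0, 0, 0, 0)
  if (iw > 0 && ih > 0) {
    dI[1] <- -ih * (ax1 > bx1)
    dI[3] <-  ih * (ax2 < bx2)
    dI[2] <- -iw * (ay1 > by1)
    dI[4] <-  iw * (ay2 < by2)
  }
  dAa <- c(-ah, -aw, ah, aw)
  dU <- dAa - dI
  diou_corners <- if (U > 0) (dI * U - I * dU) / U^2 else c(0, 0, 0, 0)

  # centre-distance penalty rho^2 / c^2
  acx <- (ax1 + ax2) / 2; acy <- (ay1 + ay2) / 2
  bcx <- (bx1 + bx2) / 2; bcy <- (by1 + by2) / 2
  rho2 <- (acx - bcx)^2 + (acy - bcy)^2
  cw <- max(ax2, bx2) - min(ax1, bx1)
  chh <- max(ay2, by2) - min(ay1, by1)
  c2 <- cw^2 + chh^2 + 1e-9
  drho2 <- c(acx - bcx, acy - bcy, acx - bcx, acy - bcy)
  dcw <- c(-(ax1 < bx1), 0, (ax2 > bx2), 0)
  dch <- c(0, -(ay1 < by1), 0, (ay2 > by2))
  dc2 <- 2 * cw * dcw + 2 * chh * dch
  dpen <- (drho2 * c2 - rho2 * dc2) / c2^2

  # aspect-ratio penalty alpha * v, alpha treated as constant
  atan_d <- atan(bw / max(bh, 1e-9)) - atan(aw / max(ah, 1e-9))
  v <- 4 / pi^2 * atan_d^2
  alpha <- if ((1 - iou + v) > 0) v / (1 - iou + v) else 0
  denom <- aw^2 + ah^2 + 1e-9
  datan_daw <- -ah / denom
  datan_dah <- aw / denom
  dv_daw <- 4 / pi^2 * 2 * atan_d * (-datan_daw)
  dv_dah <- 4 / pi^2 * 2 * atan_d * (-datan_dah)
  dv <- c(-dv_daw, -dv_dah, dv_daw, dv_dah)

  ciou <- iou - rho2 / c2 - alpha * v
  grad <- diou_corners - dpen - alpha * dv
  list(ciou = ciou, grad = grad)
}

# task-aligned assignment for one image
tal_assign <- function(scores, boxes, anchors, gt) {
  ng <- nrow(gt)
  na <- nrow(anchors)
  assigned_gt <- integer(na)          # 0 = background
  align <- numeric(na)
  iou_a <- numeric(na)
  if (ng == 0L) return(list(gt = assigned_gt, align = align, iou = iou_a))
  metric <- matrix(0, na, ng)
  ioum <- matrix(0, na, ng)
  for (j in seq_len(ng)) {
    inside <- anchors$cx > gt$x1[j] & anchors$cx < gt$x2[j] &
      anchors$cy > gt$y1[j] & anchors$cy < gt$y2[j]
    idx <- which(inside)
    if (length(idx) == 0L) next
    iou <- box_iou(as.numeric(gt[j, c("x1", "y1", "x2", "y2")]),
                   boxes[idx, , drop = FALSE])
    sc <- scores[idx, gt$class_id[j] + 1L]
    met <- (sc^TAL_ALPHA) * (pmax(iou, 0)^TAL_BETA)
    ioum[idx, j] <- iou
    keep <- idx[order(-met)][seq_len(min(TAL_TOPK, length(idx)))]
    metric[keep, j] <- met[match(keep, idx)]
  }
  cand <- which(rowSums(metric > 0) > 0L)
  for (i in cand) {
    j <- which.max(ioum[i, ] * (metric[i, ] > 0))
    assigned_gt[i] <- j
  }
  # normalized alignment: per gt, metric / max(metric) * max(iou)
  for (j in seq_len(ng)) {
    sel <- which(assigned_gt == j)
    if (length(sel) == 0L) next
    mm <- metric[sel, j]
    mx <- max(mm)
    mi <- max(ioum[sel, j])
    align[sel] <- if (mx > 0) mm / mx * mi else 0
    iou_a[sel] <- ioum[sel, j]
  }
  list(gt = assigned_gt, align = align, iou = iou_a)
}

#' Detection loss with gradients
#'
#' Computes the composite objective (binary cross-entropy classification,
#' complete-IoU box regression, distribution-focal loss; weights 0.5 / 7.5 /
#' 1.5) under task-aligned assignment (topk = 10, alpha = 0.5, beta = 6), and
#' its gradient with respect to the raw per-level head outputs.
#'
#' @param levels per-level raw predictions from [forward_model()].
#' @param targets list (length = batch) of ground-truth data frames with
#'   `class_id` (0-based) and pixel boxes `x1, y1, x2, y2`.
#' @param reg_max number of distance bins.
#' @param strides per-level strides.
#' @param fixed_assign reuse a previously computed assignment (the `assign`
#'   element of an earlier result) instead of re-assigning; assignment targets
#'   are treated as constants by the gradient, so this allows numerical
#'   gradient checks.
#' @return list with loss components (`total`, `cls`, `box`, `dfl`),
#'   per-level gradients (`grads`) and the per-image `assign` structures.
#' @export
compute_loss <- function(levels, targets, reg_max = 16L,
                         strides = c(8L, 16L, 32L), fixed_assign = NULL) {
  B <- dim(levels[[1L]]$reg)[1L]
  if (B == 0L || length(targets) == 0L) stop("compute_loss: empty batch")
  nc <- dim(levels[[1L]]$cls)[2L]
  level_dims <- lapply(levels, function(l) dim(l$reg)[3:4])
  anchors <- anchor_table(level_dims, strides)
  na <- nrow(anchors)
  ncell <- vapply(level_dims, prod, numeric(1))
  offs <- cumsum(c(0, ncell))
  proj <- 0:(reg_max - 1L)

  assigns <- vector("list", B)
  gcls <- lapply(levels, function(l) array(0, dim = dim(l$cls)))
  greg <- lapply(levels, function(l) array(0, dim = dim(l$reg)))
  loss_cls <- 0; loss_box <- 0; loss_dfl <- 0

  for (n in seq_len(B)) {
    cls_z <- do.call(rbind, lapply(levels, function(l) flat_chw(l$cls, n)))
    reg_z <- do.call(rbind, lapply(levels, function(l) flat_chw(l$reg, n)))
    scores <- sigmoid(cls_z)
    # decode distances by softmax expectation
    P <- array(0, dim = c(na, 4L, reg_max))
    dists <- matrix(0, na, 4L)
    for (side in 1:4) {
      z <- reg_z[, (side - 1L) * reg_max + seq_len(reg_max), drop = FALSE]
      p <- softmax_rows(z)
      P[, side, ] <- p
      dists[, side] <- p %*% proj
    }
    boxes <- cbind(anchors$cx - dists[, 1L] * anchors$stride,
                   anchors$cy - dists[, 2L] * anchors$stride,
                   anchors$cx + dists[, 3L] * anchors$stride,
                   anchors$cy + dists[, 4L] * anchors$stride)
    gt <- targets[[n]]
    asg <- if (is.null(fixed_assign)) tal_assign(scores, boxes, anchors, gt)
           else fixed_assign[[n]]
    assigns[[n]] <- asg

    tmat <- matrix(0, na, nc)
    sel <- which(asg$gt > 0L)
    if (length(sel) > 0L)
      tmat[cbind(sel, gt$class_id[asg$gt[sel]] + 1L)] <- asg$align[sel]
    tss <- max(sum(tmat), 1)

    loss_cls <- loss_cls -
      sum(tmat * log(pmax(scores, 1e-12)) +
            (1 - tmat) * log(pmax(1 - scores, 1e-12))) / tss
    gcls_flat <- (scores - tmat) / tss * LOSS_W_CLS

    greg_flat <- matrix(0, na, 4L * reg_max)
    if (length(sel) > 0L) {
      for (i in sel) {
        j <- asg$gt[i]
        w <- asg$align[i] / tss
        gb <- as.numeric(gt[j, c("x1", "y1", "x2", "y2")])
        cg <- ciou_grad(boxes[i, ], gb)
        loss_box <- loss_box + w * (1 - cg$ciou)
        # chain to distances: dx1/dl = -stride, dy1/dt = -stride,
        # dx2/dr = +stride, dy2/db = +stride
        s <- anchors$stride[i]
        gdist <- LOSS_W_BOX * w * (-cg$grad) * c(-s, -s, s, s)
        # target distances for DFL, in stride units, clipped to the bin range
        td <- c(anchors$cx[i] - gb[1L], anchors$cy[i] - gb[2L],
                gb[3L] - anchors$cx[i], gb[4L] - anchors$cy[i]) / s
        td <- pmin(pmax(td, 0), reg_max - 1 - 1e-3)
        for (side in 1:4) {
          p <- P[i, side, ]
          # box-loss gradient through the expectation decode
          gz <- gdist[side] * p * (proj - dists[i, side])
          # distribution-focal cross-entropy on the two adjacent bins
          lb <- floor(td[side]); rb <- lb + 1
          wl <- rb - td[side]; wr <- td[side] - lb
          tvec <- numeric(reg_max)
          tvec[lb + 1L] <- wl; tvec[rb + 1L] <- wr
          loss_dfl <- loss_dfl + w * (-sum(tvec * log(pmax(p, 1e-12)))) / 4
          gz <- gz + LOSS_W_DFL * (w / 4) * (p - tvec)
          greg_flat[i, (side - 1L) * reg_max + seq_len(reg_max)] <- gz
        }
      }
    }
    for (l in seq_along(levels)) {
      rows <- offs[l] + seq_len(ncell[l])
      h <- level_dims[[l]][1L]; w <- level_dims[[l]][2L]
      gcls[[l]][n, , , ] <- unflat_chw(gcls_flat[rows, , drop = FALSE], h, w)
      greg[[l]][n, , , ] <- unflat_chw(greg_flat[rows, , drop = FALSE], h, w)
    }
  }
  # summed over the batch (per-image terms normalized by the assignment
  # mass), the convention of the reference training pipeline: gradient
  # magnitude per step is batch-size independent
  loss_cls <- LOSS_W_CLS * loss_cls
  loss_box <- LOSS_W_BOX * loss_box
  loss_dfl <- LOSS_W_DFL * loss_dfl
  grads <- lapply(seq_along(levels), function(l)
    list(reg = greg[[l]], cls = gcls[[l]]))
  list(total = loss_cls + loss_box + loss_dfl,
       cls = loss_cls, box = loss_box, dfl = loss_dfl, grads = grads,
       assign = assigns)
}
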