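# Detection heads: the stock decoupled head and the lightweight shared-conv
# group-normalized head (LSCD), plus anchor-free decoding and NMS.

# --------------------------------------------------------------- stock head --

v8_head <- function(nc, ch = c(64L, 128L, 256L), reg_max = 16L,
                    strides = c(8L, 16L, 32L), input_size = 640L) {
  c2h <- max(16L, ch[1L] %/% 4L, reg_max * 4L)
  c3h <- max(ch[1L], min(nc, 100L))
  sub <- list()
  for (l in seq_along(ch)) {
    sub[[paste0("r", l, "_1")]] <- conv_block(ch[l], c2h, 3L)
    sub[[paste0("r", l, "_2")]] <- conv_block(c2h, c2h, 3L)
    sub[[paste0("r", l, "_3")]] <- conv2d(c2h, 4L * reg_max, 1L, bias = TRUE)
    sub[[paste0("c", l, "_1")]] <- conv_block(ch[l], c3h, 3L)
    sub[[paste0("c", l, "_2")]] <- conv_block(c3h, c3h, 3L)
    sub[[paste0("c", l, "_3")]] <- conv2d(c3h, nc, 1L, bias = TRUE)
  }
  m <- new_module("v8_head",
                  cfg = list(nc = as.integer(nc), reg_max = as.integer(reg_max),
                             ch = ch, strides = strides),
                  p = list(dfl_proj = as.numeric(0:(reg_max - 1L))),
                  sub = sub)
  head_bias_init(m, input_size)
}

# detection-prior initialisation for the final projections: roughly five
# objects per image spread over the grid cells of each level
head_bias_init <- function(m, input_size = 640L) {
  nc <- m$cfg$nc
  for (l in seq_along(m$cfg$ch)) {
    s <- m$cfg$strides[l]
    rk <- if (m$kind == "v8_head") paste0("r", l, "_3") else "reg"
    ck <- if (m$kind == "v8_head") paste0("c", l, "_3") else "cls"
    m$sub[[rk]]$p$bias[] <- 1
    m$sub[[ck]]$p$bias[] <- log(5 / nc / (input_size / s)^2)
  }
  m
}

v8_head_fw <- function(m, xs, train) {
  levels <- list()
  caches <- list()
  for (l in seq_along(xs)) {
    x <- xs[[l]]
    cc <- list()
    r1 <- conv_block_fw(m$sub[[paste0("r", l, "_1")]], x, train)
    m$sub[[paste0("r", l, "_1")]] <- r1$m
    r2 <- conv_block_fw(m$sub[[paste0("r", l, "_2")]], r1$y, train)
    m$sub[[paste0("r", l, "_2")]] <- r2$m
    c1 <- conv_block_fw(m$sub[[paste0("c", l, "_1")]], x, train)
    m$sub[[paste0("c", l, "_1")]] <- c1$m
    c2 <- conv_block_fw(m$sub[[paste0("c", l, "_2")]], c1$y, train)
    m$sub[[paste0("c", l, "_2")]] <- c2$m
    if (train) {
      r3 <- conv2d_fw_t(m$sub[[paste0("r", l, "_3")]], r2$y)
      c3 <- conv2d_fw_t(m$sub[[paste0("c", l, "_3")]], c2$y)
      levels[[l]] <- list(reg = r3$y, cls = c3$y)
      caches[[l]] <- list(r1 = r1$cache, r2 = r2$cache, r3 = r3$cache,
                          c1 = c1$cache, c2 = c2$cache, c3 = c3$cache)
    } else {
      levels[[l]] <- list(reg = conv2d_fw(m$sub[[paste0("r", l, "_3")]], r2$y),
                          cls = conv2d_fw(m$sub[[paste0("c", l, "_3")]], c2$y))
    }
  }
  list(y = levels, cache = if (train) caches else NULL, m = m)
}

v8_head_bw <- function(m, cache, gys) {
  g <- list(sub = list())
  gx <- list()
  for (l in seq_along(gys)) {
    cc <- cache[[l]]
    br <- conv2d_bw(m$sub[[paste0("r", l, "_3")]], cc$r3, gys[[l]]$reg)
    g$sub[[paste0("r", l, "_3")]] <- br$g
    b2 <- conv_block_bw(m$sub[[paste0("r", l, "_2")]], cc$r2, br$gx)
    g$sub[[paste0("r", l, "_2")]] <- b2$g
    b1 <- conv_block_bw(m$sub[[paste0("r", l, "_1")]], cc$r1, b2$gx)
    g$sub[[paste0("r", l, "_1")]] <- b1$g
    bc <- conv2d_bw(m$sub[[paste0("c", l, "_3")]], cc$c3, gys[[l]]$cls)
    g$sub[[paste0("c", l, "_3")]] <- bc$g
    d2 <- conv_block_bw(m$sub[[paste0("c", l, "_2")]], cc$c2, bc$gx)
    g$sub[[paste0("c", l, "_2")]] <- d2$g
    d1 <- conv_block_bw(m$sub[[paste0("c", l, "_1")]], cc$c1, d2$gx)
    g$sub[[paste0("c", l, "_1")]] <- d1$g
    gx[[l]] <- b1$gx + d1$gx
  }
  list(gx = gx, g = g)
}

# --------------------------------------------------------------- LSCD head --
# Per-level 1x1 Conv_GN unifies channel widths (levels differ in input width,
# so these are not shared); two 3x3 Conv_GN and the final 1x1 projections are
# shared across levels; each level's regression output is multiplied by its
# own learnable scale.

lscd_head <- function(nc, ch = c(64L, 128L, 256L), reg_max = 16L,
                      strides = c(8L, 16L, 32L),
                      h = NULL, t1 = NULL, t2 = NULL, input_size = 640L) {
  # default trunk width: twice the P3 width, floored at 32 - at thin scales
  # the shared trunk must carry classification and regression jointly, and a
  # trunk narrower than the per-side regression channels starves the
  # classifier
  if (is.null(h)) h <- max(2L * ch[1L], 32L)
  if (is.null(t1)) t1 <- h
  if (is.null(t2)) t2 <- h
  sub <- list()
  for (l in seq_along(ch))
    sub[[paste0("u", l)]] <- conv_block(ch[l], h, 1L, norm = "gn")
  sub$t1 <- conv_block(h, t1, 3L, norm = "gn")
  sub$t2 <- conv_block(t1, t2, 3L, norm = "gn")
  sub$reg <- conv2d(t2, 4L * reg_max, 1L, bias = TRUE)
  sub$cls <- conv2d(t2, nc, 1L, bias = TRUE)
  for (l in seq_along(ch)) sub[[paste0("s", l)]] <- scale_layer(1)
  m <- new_module("lscd_head",
                  cfg = list(nc = as.integer(nc), reg_max = as.integer(reg_max),
                             ch = ch, strides = strides,
                             h = as.integer(h), t1 = as.integer(t1),
                             t2 = as.integer(t2)),
                  p = list(dfl_proj = as.numeric(0:(reg_max - 1L))),
                  sub = sub)
  head_bias_init(m, input_size)
}

lscd_head_fw <- function(m, xs, train) {
  levels <- list()
  caches <- list()
  for (l in seq_along(xs)) {
    u <- conv_block_fw(m$sub[[paste0("u", l)]], xs[[l]], train)
    m$sub[[paste0("u", l)]] <- u$m
    z1 <- conv_block_fw(m$sub$t1, u$y, train); m$sub$t1 <- z1$m
    z2 <- conv_block_fw(m$sub$t2, z1$y, train); m$sub$t2 <- z2$m
    s <- m$sub[[paste0("s", l)]]$p$s
    if (train) {
      rr <- conv2d_fw_t(m$sub$reg, z2$y)
      cc <- conv2d_fw_t(m$sub$cls, z2$y)
      levels[[l]] <- list(reg = rr$y * s, cls = cc$y)
      caches[[l]] <- list(u = u$cache, z1 = z1$cache, z2 = z2$cache,
                          rcol = rr$cache, ccol = cc$cache, reg_raw = rr$y)
    } else {
      reg_raw <- conv2d_fw(m$sub$reg, z2$y)
      levels[[l]] <- list(reg = reg_raw * s, cls = conv2d_fw(m$sub$cls, z2$y))
    }
  }
  list(y = levels, cache = if (train) caches else NULL, m = m)
}

lscd_head_bw <- function(m, cache, gys) {
  g <- list(sub = list())
  gx <- list()
  acc <- function(a, b) if (is.null(a)) b else mapply_grads(a, b)
  g_t1 <- NULL; g_t2 <- NULL; g_reg <- NULL; g_cls <- NULL
  for (l in seq_along(gys)) {
    cc <- cache[[l]]
    s <- m$sub[[paste0("s", l)]]$p$s
    g$sub[[paste0("s", l)]] <- list(p = list(s = sum(gys[[l]]$reg * cc$reg_raw)))
    greg_raw <- gys[[l]]$reg * s
    br <- conv2d_bw(m$sub$reg, cc$rcol, greg_raw)
    g_reg <- acc(g_reg, br$g)
    bc <- conv2d_bw(m$sub$cls, cc$ccol, gys[[l]]$cls)
    g_cls <- acc(g_cls, bc$g)
    gz2 <- br$gx + bc$gx
    b2 <- conv_block_bw(m$sub$t2, cc$z2, gz2)
    g_t2 <- acc(g_t2, b2$g)
    b1 <- conv_block_bw(m$sub$t1, cc$z1, b2$gx)
    g_t1 <- acc(g_t1, b1$g)
    bu <- conv_block_bw(m$sub[[paste0("u", l)]], cc$u, b1$gx)
    g$sub[[paste0("u", l)]] <- bu$g
    gx[[l]] <- bu$gx
  }
  g$sub$t1 <- g_t1; g$sub$t2 <- g_t2; g$sub$reg <- g_reg; g$sub$cls <- g_cls
  list(gx = gx, g = g)
}

# elementwise sum of two grad structures with identical shape
mapply_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  out <- a
  if (!is.null(b$p)) for (nm in names(b$p))
    out$p[[nm]] <- if (is.null(a$p[[nm]])) b$p[[nm]] else a$p[[nm]] + b$p[[nm]]
  if (!is.null(b$sub)) for (nm in names(b$sub))
    out$sub[[nm]] <- mapply_grads(a$sub[[nm]], b$sub[[nm]])
  out
}

#' Run the LSCD detection head
#'
#' @param features list of three activation maps (the P3, P4, P5 taps at
#'   strides 8, 16, 32).
#' @param head an `lscd_head` module (e.g. `model$head` of a built
#'   `lscd_only` or `yolov8_rl` model).
#' @return list of per-level raw predictions, each
#'   `list(reg = <4*reg_max channel map>, cls = <num_classes channel map>)`.
#' @export
lscd_forward <- function(features, head) {
  stopifnot(head$kind == "lscd_head")
  lapply(features, check_act_map)
  lscd_head_fw(head, features, train = FALSE)$y
}

# -------------------------------------------------------------------- decode --

softmax_rows <- function(z) {
  mx <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - mx)
  e / rowSums(e)
}

#' Decode raw head predictions into detections
#'
#' Anchor-free decoding: each cell predicts four distances (left, top, right,
#' bottom) as discrete distributions over `reg_max` bins, decoded by softmax
#' expectation in stride units; class scores pass through a logistic.
#'
#' @param raw list of per-level predictions (`reg`, `cls`), batch size 1.
#' @param reg_max number of distance bins.
#' @param conf_threshold minimum class score to keep.
#' @param strides per-level strides, default `c(8, 16, 32)`.
#' @param img_size `c(width, height)` used to clip boxes; defaults to the
#'   size implied by the first level.
#' @return data frame with columns `class_id` (0-based), `score`,
#'   `x1, y1, x2, y2` (pixels, origin top-left, half-open).
#' @export
decode_boxes <- function(raw, reg_max = 16L, conf_threshold = 0.25,
                         strides = c(8L, 16L, 32L), img_size = NULL) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1)
  if (is.null(img_size)) {
    d <- dim(raw[[1L]]$reg)
    img_size <- c(d[4L] * strides[1L], d[3L] * strides[1L])
  }
  out <- list()
  for (l in seq_along(raw)) {
    reg <- raw[[l]]$reg
    cls <- raw[[l]]$cls
    d <- dim(reg)
    stopifnot(d[1L] == 1L)
    h <- d[3L]; w <- d[4L]; nc <- dim(cls)[2L]
    s <- strides[l]
    ncell <- h * w
    # reg: (1, 4*reg_max, h, w) -> matrix (ncell*4, reg_max)
    rm <- matrix(aperm(array(reg, dim = c(4L * reg_max, h, w)),
                       c(2L, 3L, 1L)), nrow = ncell)   # ncell x (4*reg_max)
    dists <- matrix(0, ncell, 4L)
    for (side in 1:4) {
      z <- rm[, (side - 1L) * reg_max + seq_len(reg_max), drop = FALSE]
      p <- softmax_rows(z)
      dists[, side] <- p %*% (0:(reg_max - 1L))
    }
    cm <- matrix(aperm(array(cls, dim = c(nc, h, w)), c(2L, 3L, 1L)),
                 nrow = ncell)                        # ncell x nc
    scores <- sigmoid(cm)
    rows <- rep(seq_len(h) - 1L, times = w)
    cols <- rep(seq_len(w) - 1L, each = h)
    cx <- (cols + 0.5) * s
    cy <- (rows + 0.5) * s
    x1 <- cx - dists[, 1L] * s; y1 <- cy - dists[, 2L] * s
    x2 <- cx + dists[, 3L] * s; y2 <- cy + dists[, 4L] * s
    keep <- which(scores >= conf_threshold, arr.ind = TRUE)
    if (nrow(keep) > 0L) {
      i <- keep[, 1L]
      out[[length(out) + 1L]] <- data.frame(
        class_id = keep[, 2L] - 1L,
        score = scores[keep],
        x1 = pmin(pmax(x1[i], 0), img_size[1L]),
        y1 = pmin(pmax(y1[i], 0), img_size[2L]),
        x2 = pmin(pmax(x2[i], 0), img_size[1L]),
        y2 = pmin(pmax(y2[i], 0), img_size[2L]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(class_id = integer(), score = numeric(),
                      x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  dets <- do.call(rbind, out)
  dets <- dets[dets$x2 > dets$x1 & dets$y2 > dets$y1, , drop = FALSE]
  rownames(dets) <- NULL
  dets
}

#' Intersection-over-union of axis-aligned boxes
#'
#' @param a single box `c(x1, y1, x2, y2)`.
#' @param b matrix of boxes (rows) or a single box.
#' @return numeric vector of IoU values.
#' @export
box_iou <- function(a, b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  iw <- pmax(0, pmin(a[3L], b[, 3L]) - pmax(a[1L], b[, 1L]))
  ih <- pmax(0, pmin(a[4L], b[, 4L]) - pmax(a[2L], b[, 2L]))
  inter <- iw * ih
  ua <- (a[3L] - a[1L]) * (a[4L] - a[2L]) +
    (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L]) - inter
  ifelse(ua > 0, inter / ua, 0)
}

#' Greedy per-class non-maximum suppression
#'
#' Detections are processed per class in order of descending score (ties
#' broken lexicographically by box coordinates); a box is removed iff its IoU
#' with an already-kept higher-scoring box strictly exceeds the threshold.
#'
#' @param dets detection data frame from [decode_boxes()].
#' @param iou_threshold suppression threshold in (0, 1].
#' @return the surviving detections, ordered by descending score.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  if (nrow(dets) <= 1L) return(dets)
  keep_all <- list()
  for (cl in sort(unique(dets$class_id))) {
    d <- dets[dets$class_id == cl, , drop = FALSE]
    o <- order(-d$score, d$x1, d$y1, d$x2, d$y2)
    d <- d[o, , drop = FALSE]
    bx <- as.matrix(d[, c("x1", "y1", "x2", "y2")])
    live <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(d))) {
      if (!live[i]) next
      later <- which(live & seq_len(nrow(d)) > i)
      if (length(later) == 0L) next
      iou <- box_iou(bx[i, ], bx[later, , drop = FALSE])
      live[later[iou > iou_threshold]] <- FALSE
    }
    keep_all[[length(keep_all) + 1L]] <- d[live, , drop = FALSE]
  }
  out <- do.call(rbind, keep_all)
  out <- out[order(-out$score, out$x1, out$y1), , drop = FALSE]
  rownames(out) <- NULL
  out
}
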