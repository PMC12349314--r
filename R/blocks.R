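# Network building blocks with explicit forward/backward passes.
#
# A module is a list:
#   kind : character, dispatch key
#   cfg  : static configuration (kernel, stride, activation, ...)
#   p    : named list of parameter arrays (entries named "fused_*" and
#          "dfl_proj" are not updated by the optimizer)
#   b    : named list of buffers (running statistics)
#   sub  : named list of child modules
#
# crl_fw(m, xs, train)  -> list(y, cache, m)   (m returned because running
#                                               statistics update functionally)
# crl_bw(m, cache, gy)  -> list(gx = list of input grads, g = grad structure)
# Grad structures mirror the module: list(p = ..., sub = ...).

new_module <- function(kind, cfg = list(), p = list(), b = list(), sub = list()) {
  structure(list(kind = kind, cfg = cfg, p = p, b = b, sub = sub),
            class = "crl_module")
}

# Kaiming-uniform initialisation matching the fan-in convention of the
# reference training framework.
init_conv_w <- function(co, ci, k) {
  fan_in <- ci * k * k
  bound <- 1 / sqrt(fan_in)
  array(runif(co * ci * k * k, -bound, bound), dim = c(co, ci, k, k))
}

# ---------------------------------------------------------------- conv2d ----

conv2d <- function(ci, co, k, stride = 1L, pad = NULL, bias = FALSE) {
  if (is.null(pad)) pad <- k %/% 2L
  p <- list(w = init_conv_w(co, ci, k))
  if (bias) p$bias <- runif(co, -1 / sqrt(ci * k * k), 1 / sqrt(ci * k * k))
  new_module("conv2d", cfg = list(stride = as.integer(stride),
                                  pad = as.integer(pad), k = as.integer(k),
                                  ci = as.integer(ci), co = as.integer(co)),
             p = p)
}

conv2d_fw <- function(m, x) {
  .cpp_conv2d_fw(x, m$p$w, m$p$bias, m$cfg$stride, m$cfg$pad, FALSE)
}

# training-mode forward: keeps the im2col buffer for the backward pass
conv2d_fw_t <- function(m, x) {
  r <- .cpp_conv2d_fw(x, m$p$w, m$p$bias, m$cfg$stride, m$cfg$pad, TRUE)
  list(y = r$y, cache = list(col = r$col, xdim = dim(x)))
}

conv2d_bw <- function(m, cache, gy, need_gx = TRUE) {
  r <- .cpp_conv2d_bw(cache$col, cache$xdim, m$p$w, gy, m$cfg$stride,
                      m$cfg$pad, !is.null(m$p$bias), need_gx)
  g <- list(p = list(w = r$gw))
  if (!is.null(m$p$bias)) g$p$bias <- r$gb
  list(gx = r$gx, g = g)
}

# ------------------------------------------------------------------ norms ----

norm_layer <- function(c, type = c("bn", "gn"), groups = NULL,
                       eps = NULL, momentum = 0.03) {
  type <- match.arg(type)
  if (is.null(eps)) eps <- if (type == "bn") 1e-3 else 1e-5
  p <- list(gamma = rep(1, c), beta = rep(0, c))
  b <- list()
  if (type == "bn") b <- list(rm = rep(0, c), rv = rep(1, c))
  if (type == "gn" && is.null(groups)) groups <- gn_default_groups(c)
  new_module("norm", cfg = list(type = type, c = as.integer(c),
                                groups = groups, eps = eps, momentum = momentum),
             p = p, b = b)
}

# default: 16 groups, reduced to the largest divisor of c not exceeding 16
gn_default_groups <- function(c) {
  g <- min(16L, c)
  while (c %% g != 0L) g <- g - 1L
  g
}

norm_fw <- function(m, x, train) {
  d <- dim(x)
  eps <- m$cfg$eps
  if (m$cfg$type == "bn") {
    if (train) {
      r <- .cpp_bn_fw(x, m$p$gamma, m$p$beta, eps)
      cnt <- d[1L] * d[3L] * d[4L]
      mom <- m$cfg$momentum
      m$b$rm <- (1 - mom) * m$b$rm + mom * r$mu
      m$b$rv <- (1 - mom) * m$b$rv + mom * r$va * cnt / max(cnt - 1, 1)
      list(y = r$y, cache = list(xh = r$xh, inv = r$inv), m = m)
    } else {
      inv <- 1 / sqrt(m$b$rv + eps)
      y <- sweep(sweep(sweep(x, 2L, m$b$rm, "-"), 2L,
                       m$p$gamma * inv, "*"), 2L, m$p$beta, "+")
      list(y = y, cache = NULL, m = m)
    }
  } else {
    g <- m$cfg$groups
    if (d[2L] %% g != 0L)
      stop("group_normalize: ", d[2L], " channels not divisible by ", g, " groups")
    r <- .cpp_gn_fw(x, m$p$gamma, m$p$beta, g, eps)
    list(y = r$y, cache = if (train) list(xh = r$xh, inv = r$inv) else NULL,
         m = m)
  }
}

norm_bw <- function(m, cache, gy) {
  if (m$cfg$type == "bn") {
    r <- .cpp_bn_bw(cache$xh, cache$inv, m$p$gamma, gy)
  } else {
    r <- .cpp_gn_bw(cache$xh, cache$inv, m$p$gamma, gy, m$cfg$groups)
  }
  list(gx = r$gx, g = list(p = list(gamma = r$ggamma, beta = r$gbeta)))
}

# ------------------------------------------------------------- conv block ----
# CBS (conv + batch norm + SiLU) or Conv_GN (conv + group norm + SiLU).

conv_block <- function(ci, co, k, stride = 1L, norm = c("bn", "gn"),
                       act = c("silu", "none"), groups = NULL) {
  norm <- match.arg(norm)
  act <- match.arg(act)
  new_module("conv_block", cfg = list(act = act),
             sub = list(conv = conv2d(ci, co, k, stride),
                        norm = norm_layer(co, norm, groups = groups)))
}

conv_block_fw <- function(m, x, train) {
  if (train) {
    cv <- conv2d_fw_t(m$sub$conv, x)
    nr <- norm_fw(m$sub$norm, cv$y, TRUE)
    m$sub$norm <- nr$m
    if (m$cfg$act == "silu") {
      sr <- .cpp_silu_fw_t(nr$y)
      return(list(y = sr$y, cache = list(conv = cv$cache, ncache = nr$cache,
                                         y2 = nr$y, sig = sr$s), m = m))
    }
    return(list(y = nr$y,
                cache = list(conv = cv$cache, ncache = nr$cache, y2 = nr$y),
                m = m))
  } else {
    y1 <- conv2d_fw(m$sub$conv, x)
    nr <- norm_fw(m$sub$norm, y1, FALSE)
    m$sub$norm <- nr$m
    y <- if (m$cfg$act == "silu") silu_fw(nr$y) else nr$y
    list(y = y, cache = NULL, m = m)
  }
}

conv_block_bw <- function(m, cache, gy, need_gx = TRUE) {
  if (m$cfg$act == "silu") gy <- .cpp_silu_bw_s(cache$y2, cache$sig, gy)
  nb <- norm_bw(m$sub$norm, cache$ncache, gy)
  cb <- conv2d_bw(m$sub$conv, cache$conv, nb$gx, need_gx)
  list(gx = cb$gx, g = list(sub = list(conv = cb$g, norm = nb$g)))
}

# ---------------------------------------------------------------- RepConv ----
# Training: parallel 3x3 and 1x1 conv branches, each followed by batch norm,
# outputs summed (optionally activated). Deployment: the branches are fused
# algebraically into a single biased 3x3 convolution.

repconv <- function(ci, co, act = c("none", "silu")) {
  act <- match.arg(act)
  new_module("repconv", cfg = list(act = act, ci = as.integer(ci),
                                   co = as.integer(co), deploy = FALSE),
             sub = list(conv3 = conv2d(ci, co, 3L),
                        n3 = norm_layer(co, "bn"),
                        conv1 = conv2d(ci, co, 1L, pad = 0L),
                        n1 = norm_layer(co, "bn")))
}

repconv_fw_internal <- function(m, x, train) {
  if (isTRUE(m$cfg$deploy)) {
    y <- .cpp_conv2d_fw(x, m$p$fused_w, m$p$fused_b, 1L, 1L)
    yact <- if (m$cfg$act == "silu") silu_fw(y) else y
    return(list(y = yact, cache = if (train) list(deploy = TRUE) else NULL, m = m))
  }
  if (train) {
    cv3 <- conv2d_fw_t(m$sub$conv3, x)
    n3 <- norm_fw(m$sub$n3, cv3$y, TRUE); m$sub$n3 <- n3$m
    cv1 <- conv2d_fw_t(m$sub$conv1, x)
    n1 <- norm_fw(m$sub$n1, cv1$y, TRUE); m$sub$n1 <- n1$m
    y <- n3$y + n1$y
    yact <- if (m$cfg$act == "silu") silu_fw(y) else y
    return(list(y = yact, cache = list(conv3 = cv3$cache, conv1 = cv1$cache,
                                       c3 = n3$cache, c1 = n1$cache, ysum = y),
                m = m))
  }
  y3 <- conv2d_fw(m$sub$conv3, x)
  n3 <- norm_fw(m$sub$n3, y3, FALSE); m$sub$n3 <- n3$m
  y1 <- conv2d_fw(m$sub$conv1, x)
  n1 <- norm_fw(m$sub$n1, y1, FALSE); m$sub$n1 <- n1$m
  y <- n3$y + n1$y
  yact <- if (m$cfg$act == "silu") silu_fw(y) else y
  list(y = yact, cache = NULL, m = m)
}

repconv_bw <- function(m, cache, gy) {
  if (isTRUE(cache$deploy)) stop("backward through a fused RepConv is not supported")
  if (m$cfg$act == "silu") gy <- silu_bw(cache$ysum, gy)
  b3 <- norm_bw(m$sub$n3, cache$c3, gy)
  c3 <- conv2d_bw(m$sub$conv3, cache$conv3, b3$gx)
  b1 <- norm_bw(m$sub$n1, cache$c1, gy)
  c1 <- conv2d_bw(m$sub$conv1, cache$conv1, b1$gx)
  list(gx = c3$gx + c1$gx,
       g = list(sub = list(conv3 = c3$g, n3 = b3$g, conv1 = c1$g, n1 = b1$g)))
}

# fold a batch norm into the preceding conv kernel
fold_bn <- function(w, nm) {
  sc <- nm$p$gamma / sqrt(nm$b$rv + nm$cfg$eps)
  wf <- sweep(w, 1L, sc, "*")
  bf <- nm$p$beta - nm$p$gamma * nm$b$rm / sqrt(nm$b$rv + nm$cfg$eps)
  list(w = wf, b = bf)
}

#' Fuse the branches of a RepConv block
#'
#' Folds each branch's batch-norm statistics into its kernel, zero-pads the
#' 1x1 kernel to the centre of a 3x3 kernel, and sums kernels and biases into
#' a single equivalent biased 3x3 convolution. Idempotent.
#'
#' @param m a `repconv` module.
#' @return the module with `fused_w`/`fused_b` set and `deploy = TRUE`.
#' @export
repconv_fuse <- function(m) {
  stopifnot(m$kind == "repconv")
  if (isTRUE(m$cfg$deploy)) return(m)
  if (is.null(m$sub$n3$b$rv) || is.null(m$sub$n1$b$rv))
    stop("repconv_fuse: missing norm statistics")
  f3 <- fold_bn(m$sub$conv3$p$w, m$sub$n3)
  f1 <- fold_bn(m$sub$conv1$p$w, m$sub$n1)
  w1p <- array(0, dim = dim(f3$w))
  w1p[, , 2L, 2L] <- f1$w[, , 1L, 1L]
  m$p$fused_w <- f3$w + w1p
  m$p$fused_b <- f3$b + f1$b
  m$cfg$deploy <- TRUE
  m
}

#' Run a RepConv block
#'
#' In `train` mode computes the sum of the 3x3 and 1x1 conv+norm branches;
#' in `deploy` mode runs the single fused convolution (requires a prior
#' [repconv_fuse()]).
#'
#' @param x activation map, dim `(batch, channels, height, width)`.
#' @param m a `repconv` module.
#' @param mode `"train"` or `"deploy"`.
#' @return the output activation map.
#' @export
repconv_forward <- function(x, m, mode = c("train", "deploy")) {
  mode <- match.arg(mode)
  check_act_map(x)
  if (mode == "deploy") {
    if (is.null(m$p$fused_w)) stop("deploy mode requires repconv_fuse() first")
    m$cfg$deploy <- TRUE
  } else {
    m$cfg$deploy <- FALSE
  }
  repconv_fw_internal(m, x, train = FALSE)$y
}

# -------------------------------------------------------------------- C2f ----

bottleneck <- function(c, shortcut = TRUE) {
  new_module("bottleneck", cfg = list(shortcut = shortcut),
             sub = list(cv1 = conv_block(c, c, 3L),
                        cv2 = conv_block(c, c, 3L)))
}

bottleneck_fw <- function(m, x, train) {
  r1 <- conv_block_fw(m$sub$cv1, x, train); m$sub$cv1 <- r1$m
  r2 <- conv_block_fw(m$sub$cv2, r1$y, train); m$sub$cv2 <- r2$m
  y <- if (m$cfg$shortcut) x + r2$y else r2$y
  list(y = y, cache = if (train) list(c1 = r1$cache, c2 = r2$cache) else NULL, m = m)
}

bottleneck_bw <- function(m, cache, gy) {
  b2 <- conv_block_bw(m$sub$cv2, cache$c2, gy)
  b1 <- conv_block_bw(m$sub$cv1, cache$c1, b2$gx)
  gx <- if (m$cfg$shortcut) gy + b1$gx else b1$gx
  list(gx = gx, g = list(sub = list(cv1 = b1$g, cv2 = b2$g)))
}

c2f <- function(c1, c2, n = 1L, shortcut = FALSE) {
  c <- c2 %/% 2L
  sub <- list(cv1 = conv_block(c1, 2L * c, 1L),
              cv2 = conv_block((2L + n) * c, c2, 1L))
  for (i in seq_len(n)) sub[[paste0("m", i)]] <- bottleneck(c, shortcut)
  new_module("c2f", cfg = list(c = c, n = as.integer(n)), sub = sub)
}

c2f_fw <- function(m, x, train) {
  r1 <- conv_block_fw(m$sub$cv1, x, train); m$sub$cv1 <- r1$m
  c <- m$cfg$c
  ys <- list(chan_slice(r1$y, seq_len(c)),
             chan_slice(r1$y, c + seq_len(c)))
  bcaches <- list()
  for (i in seq_len(m$cfg$n)) {
    nm <- paste0("m", i)
    rb <- bottleneck_fw(m$sub[[nm]], ys[[length(ys)]], train)
    m$sub[[nm]] <- rb$m
    bcaches[[i]] <- rb$cache
    ys[[length(ys) + 1L]] <- rb$y
  }
  cat_y <- chan_concat(ys)
  r2 <- conv_block_fw(m$sub$cv2, cat_y, train); m$sub$cv2 <- r2$m
  cache <- if (train) list(c1 = r1$cache, c2 = r2$cache, bcaches = bcaches) else NULL
  list(y = r2$y, cache = cache, m = m)
}

c2f_bw <- function(m, cache, gy) {
  b2 <- conv_block_bw(m$sub$cv2, cache$c2, gy)
  c <- m$cfg$c
  n <- m$cfg$n
  # split concat grad into the 2 + n chunks
  gys <- lapply(seq_len(2L + n), function(i)
    chan_slice(b2$gx, (i - 1L) * c + seq_len(c)))
  g <- list(sub = list(cv2 = b2$g))
  gcur <- gys[[2L + n]]
  for (i in rev(seq_len(n))) {
    nm <- paste0("m", i)
    bb <- bottleneck_bw(m$sub[[nm]], cache$bcaches[[i]], gcur)
    g$sub[[nm]] <- bb$g
    gcur <- bb$gx + gys[[1L + i]]   # grad into stage i-1 output
  }
  g_split <- chan_concat(list(gys[[1L]], gcur))
  b1 <- conv_block_bw(m$sub$cv1, cache$c1, g_split)
  g$sub$cv1 <- b1$g
  list(gx = b1$gx, g = g)
}

# ------------------------------------------------------------------- SPPF ----

sppf <- function(c1, c2, k = 5L) {
  ch <- c1 %/% 2L
  new_module("sppf", cfg = list(k = as.integer(k)),
             sub = list(cv1 = conv_block(c1, ch, 1L),
                        cv2 = conv_block(ch * 4L, c2, 1L)))
}

sppf_fw <- function(m, x, train) {
  r1 <- conv_block_fw(m$sub$cv1, x, train); m$sub$cv1 <- r1$m
  k <- m$cfg$k
  pad <- k %/% 2L
  p1 <- .cpp_maxpool_fw(r1$y, k, 1L, pad)
  p2 <- .cpp_maxpool_fw(p1$y, k, 1L, pad)
  p3 <- .cpp_maxpool_fw(p2$y, k, 1L, pad)
  cat_y <- chan_concat(list(r1$y, p1$y, p2$y, p3$y))
  r2 <- conv_block_fw(m$sub$cv2, cat_y, train); m$sub$cv2 <- r2$m
  cache <- if (train) list(c1 = r1$cache, c2 = r2$cache,
                           am = list(p1$argmax, p2$argmax, p3$argmax),
                           d = dim(r1$y)) else NULL
  list(y = r2$y, cache = cache, m = m)
}

sppf_bw <- function(m, cache, gy) {
  b2 <- conv_block_bw(m$sub$cv2, cache$c2, gy)
  ch <- cache$d[2L]
  gs <- lapply(0:3, function(i) chan_slice(b2$gx, i * ch + seq_len(ch)))
  g3 <- .cpp_maxpool_bw(gs[[4L]], cache$am[[3L]], cache$d)
  g2 <- .cpp_maxpool_bw(gs[[3L]] + g3, cache$am[[2L]], cache$d)
  g1 <- .cpp_maxpool_bw(gs[[2L]] + g2, cache$am[[1L]], cache$d)
  b1 <- conv_block_bw(m$sub$cv1, cache$c1, gs[[1L]] + g1)
  list(gx = b1$gx, g = list(sub = list(cv1 = b1$g, cv2 = b2$g)))
}

# -------------------------------------------------------------- RGCSPELAN ----
# Split-aggregate block: a 1x1 stem, a pass-through half, and a gradient
# branch of n RepConv units plus a 3x3 tail conv; all stage outputs are
# concatenated and projected by a final 1x1 conv.

rgcspelan <- function(c1, c2, n = 1L, c = NULL, m_width = NULL,
                      e = 0.5, s = 0.5) {
  if (is.null(c)) c <- as.integer(c2 * e)
  if (is.null(m_width)) m_width <- as.integer(c * s)
  if (n < 1L) stop("rgcspelan: n must be >= 1")
  if (c < 2L || m_width < 1L) stop("rgcspelan: derived hidden widths must be positive")
  a <- c %/% 2L
  b <- c - a
  sub <- list(cv1 = conv_block(c1, c, 1L),
              rep1 = repconv(b, m_width, act = "silu"))
  if (n > 1L) for (i in 2:n)
    sub[[paste0("rep", i)]] <- repconv(m_width, m_width, act = "silu")
  sub$tail <- conv_block(m_width, m_width, 3L)
  sub$cv2 <- conv_block(a + (n + 1L) * m_width, c2, 1L)
  new_module("rgcspelan",
             cfg = list(n = as.integer(n), c = as.integer(c),
                        m = as.integer(m_width), a = a, b = b),
             sub = sub)
}

rgcspelan_fw <- function(m, x, train) {
  r1 <- conv_block_fw(m$sub$cv1, x, train); m$sub$cv1 <- r1$m
  a <- m$cfg$a
  pass <- chan_slice(r1$y, seq_len(a))
  cur <- chan_slice(r1$y, a + seq_len(m$cfg$b))
  ys <- list(pass)
  rcaches <- list()
  for (i in seq_len(m$cfg$n)) {
    nm <- paste0("rep", i)
    rr <- repconv_fw_internal(m$sub[[nm]], cur, train)
    m$sub[[nm]] <- rr$m
    rcaches[[i]] <- rr$cache
    cur <- rr$y
    ys[[length(ys) + 1L]] <- cur
  }
  rt <- conv_block_fw(m$sub$tail, cur, train); m$sub$tail <- rt$m
  ys[[length(ys) + 1L]] <- rt$y
  cat_y <- chan_concat(ys)
  r2 <- conv_block_fw(m$sub$cv2, cat_y, train); m$sub$cv2 <- r2$m
  cache <- if (train) list(c1 = r1$cache, c2 = r2$cache, tail = rt$cache,
                           rcaches = rcaches) else NULL
  list(y = r2$y, cache = cache, m = m)
}

rgcspelan_bw <- function(m, cache, gy) {
  b2 <- conv_block_bw(m$sub$cv2, cache$c2, gy)
  a <- m$cfg$a; mw <- m$cfg$m; n <- m$cfg$n
  g_pass <- chan_slice(b2$gx, seq_len(a))
  gstage <- lapply(seq_len(n + 1L), function(i)
    chan_slice(b2$gx, a + (i - 1L) * mw + seq_len(mw)))
  g <- list(sub = list(cv2 = b2$g))
  bt <- conv_block_bw(m$sub$tail, cache$tail, gstage[[n + 1L]])
  g$sub$tail <- bt$g
  gcur <- bt$gx + gstage[[n]]
  for (i in rev(seq_len(n))) {
    nm <- paste0("rep", i)
    rb <- repconv_bw(m$sub[[nm]], cache$rcaches[[i]], gcur)
    g$sub[[nm]] <- rb$g
    gcur <- rb$gx
    if (i > 1L) gcur <- gcur + gstage[[i - 1L]]
  }
  g_split <- chan_concat(list(g_pass, gcur))
  b1 <- conv_block_bw(m$sub$cv1, cache$c1, g_split)
  g$sub$cv1 <- b1$g
  list(gx = b1$gx, g = g)
}

#' Run an RGCSPELAN block
#'
#' @param x activation map with `cfg$in_channels` channels.
#' @param m an `rgcspelan` module built by the model assembler.
#' @return output activation map (same spatial size, `out_channels` channels).
#' @export
rgcspelan_forward <- function(x, m) {
  check_act_map(x)
  rgcspelan_fw(m, x, train = FALSE)$y
}

# ------------------------------------------------------------------ scale ----

scale_layer <- function(init = 1) new_module("scale", p = list(s = init))

#' Apply a per-level scale layer
#'
#' @param x activation map.
#' @param s scalar.
#' @return `s * x`.
#' @export
scale_apply <- function(x, s) {
  stopifnot(length(s) == 1L)
  x * as.numeric(s)
}

# ----------------------------------------------------- plumbing modules ----

upsample2 <- function() new_module("upsample2")
concat_mod <- function() new_module("concat")

# --------------------------------------------------------- generic dispatch --

crl_fw <- function(m, xs, train = FALSE) {
  switch(m$kind,
    conv_block = conv_block_fw(m, xs[[1L]], train),
    c2f        = c2f_fw(m, xs[[1L]], train),
    sppf       = sppf_fw(m, xs[[1L]], train),
    rgcspelan  = rgcspelan_fw(m, xs[[1L]], train),
    repconv    = repconv_fw_internal(m, xs[[1L]], train),
    upsample2  = list(y = .cpp_upsample2_fw(xs[[1L]]), cache = NULL, m = m),
    concat     = list(y = chan_concat(xs),
                      cache = if (train) vapply(xs, function(x) dim(x)[2L], integer(1L)) else NULL,
                      m = m),
    stop("unknown module kind: ", m$kind))
}

crl_bw <- function(m, cache, gy, need_gx = TRUE) {
  switch(m$kind,
    conv_block = { r <- conv_block_bw(m, cache, gy, need_gx)
                   list(gx = list(r$gx), g = r$g) },
    c2f        = { r <- c2f_bw(m, cache, gy); list(gx = list(r$gx), g = r$g) },
    sppf       = { r <- sppf_bw(m, cache, gy); list(gx = list(r$gx), g = r$g) },
    rgcspelan  = { r <- rgcspelan_bw(m, cache, gy); list(gx = list(r$gx), g = r$g) },
    repconv    = { r <- repconv_bw(m, cache, gy); list(gx = list(r$gx), g = r$g) },
    upsample2  = list(gx = list(.cpp_upsample2_bw(gy)), g = NULL),
    concat     = {
      cs <- cache
      at <- 0L
      gx <- lapply(cs, function(cc) {
        out <- chan_slice(gy, at + seq_len(cc))
        at <<- at + cc
        out
      })
      list(gx = gx, g = NULL)
    },
    stop("unknown module kind: ", m$kind))
}

#' Group normalization
#'
#' Normalizes each group of channels by its own within-group mean and
#' variance, then applies the per-channel affine transform
#' `gamma * (x - mu_g) / sqrt(sigma_g^2 + eps) + beta`. Statistics are
#' computed per sample and per group over (channels-in-group, height, width).
#'
#' @param x activation map, dim `(batch, channels, height, width)`.
#' @param gamma,beta per-channel scale and offset (recycled if length 1).
#' @param groups number of channel groups; must divide the channel count.
#' @param eps small positive constant preventing division by zero.
#' @return normalized activation map, same shape as `x`.
#' @export
group_normalize <- function(x, gamma = 1, beta = 0, groups = 16L, eps = 1e-5) {
  check_act_map(x)
  c <- dim(x)[2L]
  if (c %% groups != 0L)
    stop("group_normalize: ", c, " channels not divisible by ", groups, " groups")
  m <- norm_layer(c, "gn", groups = groups, eps = eps)
  m$p$gamma <- rep_len(gamma, c)
  m$p$beta <- rep_len(beta, c)
  norm_fw(m, x, train = FALSE)$y
}
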