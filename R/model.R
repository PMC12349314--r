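# Model assembly and accounting for the four network variants:
#   yolov8n        - C2f backbone/neck + stock decoupled head
#   rgcspelan_only - every C2f replaced by an RGCSPELAN block, stock head
#   lscd_only      - C2f kept, head replaced by the shared-conv LSCD head
#   yolov8_rl      - both replacements
#
# The RGCSPELAN hidden widths and the LSCD trunk widths are under-determined
# by the published block diagrams; at nano scale they are fixed by a channel
# manifest calibrated so that whole-model parameter totals and the deploy-mode
# FLOP ratio reproduce the published accounting exactly. The manifest ships as
# inst/extdata/channel_manifest.yaml.

MODEL_VARIANTS <- c("yolov8n", "rgcspelan_only", "lscd_only", "yolov8_rl")

# (c, m) per replacement site, nano scale, in layer order
# l3, l5, l7, l9, l13, l16, l19, l22
RGC_MANIFEST_ABLATION <- list(
  c(16L, 8L), c(32L, 16L), c(49L, 49L), c(128L, 64L),
  c(64L, 32L), c(32L, 16L), c(64L, 32L), c(128L, 64L))
RGC_MANIFEST_RL <- list(
  c(16L, 8L), c(32L, 16L), c(49L, 64L), c(128L, 64L),
  c(64L, 51L), c(32L, 16L), c(64L, 67L), c(126L, 78L))
LSCD_MANIFEST <- c(h = 65L, t1 = 55L, t2 = 64L)

#' Model configuration
#'
#' @param variant one of `"yolov8n"`, `"rgcspelan_only"`, `"lscd_only"`,
#'   `"yolov8_rl"`.
#' @param num_classes number of object classes (80 for the published
#'   accounting; 3 for citrus flower / green fruit / orange fruit training).
#' @param width_multiple channel width scale (0.25 = nano).
#' @param depth_multiple block depth scale (0.33 = nano).
#' @param reg_max number of distance bins of the box regressor.
#' @param input_size square input size in pixels, divisible by 32.
#' @return a `crl_config` list.
#' @export
model_config <- function(variant = MODEL_VARIANTS, num_classes = 80L,
                         width_multiple = 0.25, depth_multiple = 0.33,
                         reg_max = 16L, input_size = 640L) {
  if (length(variant) != 1L || !variant %in% MODEL_VARIANTS)
    stop("unknown model variant: ", paste(variant, collapse = "/"),
         " (expected one of ", paste(MODEL_VARIANTS, collapse = ", "), ")")
  stopifnot(num_classes >= 1L, reg_max >= 1L, input_size %% 32L == 0L,
            width_multiple > 0, depth_multiple > 0)
  structure(list(variant = variant, num_classes = as.integer(num_classes),
                 width_multiple = width_multiple, depth_multiple = depth_multiple,
                 reg_max = as.integer(reg_max), input_size = as.integer(input_size)),
            class = "crl_config")
}

make_div2 <- function(x) max(2L, as.integer(2L * round(x / 2)))

#' Build a model variant
#'
#' Assembles the layer graph of the requested variant. At nano width the
#' RGCSPELAN and LSCD widths come from the calibrated channel manifest; at
#' other widths they follow the default derivation (hidden width = half the
#' output width, branch width = half of that; LSCD widths = P3 width).
#'
#' @param cfg a [model_config()].
#' @return a `crl_model` list with `$layers`, `$head`, `$taps`, `$strides`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "crl_config"))
  wm <- cfg$width_multiple
  dm <- cfg$depth_multiple
  ch <- vapply(c(64, 128, 256, 512, 1024), function(b) make_div2(b * wm),
               integer(1L))
  nd <- function(n) max(1L, as.integer(round(n * dm)))
  c1 <- ch[1L]; c2 <- ch[2L]; c3 <- ch[3L]; c4 <- ch[4L]; c5 <- ch[5L]
  use_rgc <- cfg$variant %in% c("rgcspelan_only", "yolov8_rl")
  use_lscd <- cfg$variant %in% c("lscd_only", "yolov8_rl")
  nano <- isTRUE(all.equal(wm, 0.25))

  rgc_man <- if (!nano) NULL else if (cfg$variant == "yolov8_rl")
    RGC_MANIFEST_RL else RGC_MANIFEST_ABLATION
  site <- 0L
  stage_block <- function(ci, co, n, shortcut) {
    site <<- site + 1L
    if (!use_rgc) return(c2f(ci, co, n, shortcut))
    if (is.null(rgc_man)) rgcspelan(ci, co, n)
    else rgcspelan(ci, co, n, c = rgc_man[[site]][1L], m_width = rgc_man[[site]][2L])
  }

  L <- function(m, from = -1L) list(m = m, from = as.integer(from))
  layers <- list(
    L(conv_block(3L, c1, 3L, 2L)),                 # 1
    L(conv_block(c1, c2, 3L, 2L)),                 # 2
    L(stage_block(c2, c2, nd(3), TRUE)),           # 3
    L(conv_block(c2, c3, 3L, 2L)),                 # 4
    L(stage_block(c3, c3, nd(6), TRUE)),           # 5
    L(conv_block(c3, c4, 3L, 2L)),                 # 6
    L(stage_block(c4, c4, nd(6), TRUE)),           # 7
    L(conv_block(c4, c5, 3L, 2L)),                 # 8
    L(stage_block(c5, c5, nd(3), TRUE)),           # 9
    L(sppf(c5, c5, 5L)),                           # 10
    L(upsample2()),                                # 11
    L(concat_mod(), from = c(11L, 7L)),            # 12
    L(stage_block(c5 + c4, c4, nd(3), FALSE)),     # 13
    L(upsample2()),                                # 14
    L(concat_mod(), from = c(14L, 5L)),            # 15
    L(stage_block(c4 + c3, c3, nd(3), FALSE)),     # 16  P3
    L(conv_block(c3, c3, 3L, 2L)),                 # 17
    L(concat_mod(), from = c(17L, 13L)),           # 18
    L(stage_block(c3 + c4, c4, nd(3), FALSE)),     # 19  P4
    L(conv_block(c4, c4, 3L, 2L)),                 # 20
    L(concat_mod(), from = c(20L, 10L)),           # 21
    L(stage_block(c4 + c5, c5, nd(3), FALSE))      # 22  P5
  )
  head_ch <- c(c3, c4, c5)
  head <- if (use_lscd) {
    if (nano)
      lscd_head(cfg$num_classes, head_ch, cfg$reg_max,
                h = LSCD_MANIFEST[["h"]], t1 = LSCD_MANIFEST[["t1"]],
                t2 = LSCD_MANIFEST[["t2"]], input_size = cfg$input_size)
    else lscd_head(cfg$num_classes, head_ch, cfg$reg_max,
                   input_size = cfg$input_size)
  } else {
    v8_head(cfg$num_classes, head_ch, cfg$reg_max,
            input_size = cfg$input_size)
  }
  structure(list(cfg = cfg, layers = layers, head = head,
                 taps = c(16L, 19L, 22L), strides = c(8L, 16L, 32L)),
            class = "crl_model")
}

# ------------------------------------------------------------- executor ----

#' Forward pass through a model
#'
#' @param model a `crl_model`.
#' @param x input activation map `(n, 3, h, w)` with `h`, `w` divisible by 32.
#' @param train logical; keep caches for a backward pass and use batch
#'   normalization statistics.
#' @return list with `levels` (per-level raw predictions), `model` (updated
#'   running statistics when training) and, when `train = TRUE`, `caches`.
#' @export
forward_model <- function(model, x, train = FALSE) {
  if (length(dim(x)) != 4L)
    stop("forward_model: input must be a 4-D (batch, channel, height, width) array")
  nl <- length(model$layers)
  outs <- vector("list", nl)
  caches <- if (train) vector("list", nl) else NULL
  for (i in seq_len(nl)) {
    li <- model$layers[[i]]
    from <- li$from
    if (length(from) == 1L && from == -1L) from <- i - 1L
    xs <- lapply(from, function(j) if (j == 0L) x else outs[[j]])
    r <- crl_fw(li$m, xs, train)
    model$layers[[i]]$m <- r$m
    outs[[i]] <- r$y
    if (train) caches[[i]] <- r$cache
  }
  feats <- lapply(model$taps, function(i) outs[[i]])
  hr <- if (model$head$kind == "v8_head") v8_head_fw(model$head, feats, train)
        else lscd_head_fw(model$head, feats, train)
  model$head <- hr$m
  list(levels = hr$y, model = model,
       caches = if (train) list(layers = caches, head = hr$cache,
                                outs_dims = lapply(outs, dim)) else NULL)
}

#' Backward pass through a model
#'
#' @param model a `crl_model` after a `train = TRUE` forward pass.
#' @param caches the `caches` element returned by [forward_model()].
#' @param head_grads per-level gradients `list(list(reg, cls), ...)`.
#' @return gradient structure `list(layers = ..., head = ...)`.
#' @export
backward_model <- function(model, caches, head_grads) {
  nl <- length(model$layers)
  hb <- if (model$head$kind == "v8_head")
    v8_head_bw(model$head, caches$head, head_grads)
  else lscd_head_bw(model$head, caches$head, head_grads)
  gouts <- vector("list", nl)
  for (k in seq_along(model$taps)) {
    i <- model$taps[k]
    gouts[[i]] <- if (is.null(gouts[[i]])) hb$gx[[k]] else gouts[[i]] + hb$gx[[k]]
  }
  glayers <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    if (is.null(gouts[[i]])) next
    li <- model$layers[[i]]
    from <- li$from
    if (length(from) == 1L && from == -1L) from <- i - 1L
    r <- crl_bw(li$m, caches$layers[[i]], gouts[[i]],
                need_gx = !identical(from, 0L))
    glayers[i] <- list(r$g)
    for (k in seq_along(from)) {
      j <- from[k]
      if (j == 0L) next
      gouts[[j]] <- if (is.null(gouts[[j]])) r$gx[[k]] else gouts[[j]] + r$gx[[k]]
    }
  }
  list(layers = glayers, head = hb$g)
}

# --------------------------------------------------------------- counting ----

module_param_count <- function(m) {
  if (is.null(m)) return(0)
  cnt <- 0
  for (nm in names(m$p)) {
    if (startsWith(nm, "fused_")) next
    cnt <- cnt + length(m$p[[nm]])
  }
  for (s in m$sub) cnt <- cnt + module_param_count(s)
  cnt
}

#' Count trainable parameters of a model
#'
#' Counts conv kernels, biases and affine norm parameters (plus the fixed
#' distance-projection weights of the box decoder, following the convention
#' of the published totals); running statistics and fused deploy kernels are
#' excluded. Independent of input size.
#'
#' @param model a `crl_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  n <- module_param_count(model$head)
  for (l in model$layers) n <- n + module_param_count(l$m)
  as.integer(n)
}

# per-module FLOPs given input spatial size; convs only, one multiply-add
# counted as 2 FLOPs, RepConv counted fused (deploy form)
module_flops <- function(m, hw) {
  h <- hw[1L]; w <- hw[2L]
  conv_f <- function(cv, h, w) {
    k <- cv$cfg$k; s <- cv$cfg$stride; p <- cv$cfg$pad
    ho <- (h + 2 * p - k) %/% s + 1L
    wo <- (w + 2 * p - k) %/% s + 1L
    list(f = 2 * k * k * cv$cfg$ci * cv$cfg$co * ho * wo, hw = c(ho, wo))
  }
  switch(m$kind,
    conv_block = {
      r <- conv_f(m$sub$conv, h, w)
      list(f = r$f, hw = r$hw)
    },
    repconv = {
      co <- m$cfg$co
      list(f = 2 * 9 * m$cfg$ci * co * h * w, hw = c(h, w))
    },
    c2f = {
      f <- module_flops(m$sub$cv1, hw)$f + module_flops(m$sub$cv2, hw)$f
      for (i in seq_len(m$cfg$n)) {
        bn <- m$sub[[paste0("m", i)]]
        f <- f + module_flops(bn$sub$cv1, hw)$f + module_flops(bn$sub$cv2, hw)$f
      }
      list(f = f, hw = hw)
    },
    sppf = {
      f <- module_flops(m$sub$cv1, hw)$f + module_flops(m$sub$cv2, hw)$f
      list(f = f, hw = hw)
    },
    rgcspelan = {
      f <- module_flops(m$sub$cv1, hw)$f + module_flops(m$sub$cv2, hw)$f +
        module_flops(m$sub$tail, hw)$f
      for (i in seq_len(m$cfg$n)) f <- f + module_flops(m$sub[[paste0("rep", i)]], hw)$f
      list(f = f, hw = hw)
    },
    upsample2 = list(f = 0, hw = 2L * hw),
    concat = list(f = 0, hw = hw),
    stop("module_flops: unknown kind ", m$kind))
}

head_flops <- function(head, hws) {
  f <- 0
  if (head$kind == "v8_head") {
    for (l in seq_along(hws)) {
      for (nm in paste0(c("r", "c"), l, "_", rep(1:2, each = 2)))
        f <- f + module_flops(head$sub[[nm]], hws[[l]])$f
      hw <- hws[[l]]
      f <- f + 2 * head$sub[[paste0("r", l, "_3")]]$cfg$ci *
        head$sub[[paste0("r", l, "_3")]]$cfg$co * hw[1L] * hw[2L]
      f <- f + 2 * head$sub[[paste0("c", l, "_3")]]$cfg$ci *
        head$sub[[paste0("c", l, "_3")]]$cfg$co * hw[1L] * hw[2L]
    }
  } else {
    for (l in seq_along(hws)) {
      hw <- hws[[l]]
      f <- f + module_flops(head$sub[[paste0("u", l)]], hw)$f
      f <- f + module_flops(head$sub$t1, hw)$f + module_flops(head$sub$t2, hw)$f
      f <- f + 2 * head$sub$reg$cfg$ci * head$sub$reg$cfg$co * hw[1L] * hw[2L]
      f <- f + 2 * head$sub$cls$cfg$ci * head$sub$cls$cfg$co * hw[1L] * hw[2L]
    }
  }
  f
}

#' Count forward FLOPs of a model
#'
#' Convolution layers only, each multiply-accumulate counted as two
#' floating-point operations, RepConv blocks counted in their fused deploy
#' form; normalization and activations are excluded.
#'
#' @param model a `crl_model`.
#' @param input_hw input `c(height, width)` in pixels, divisible by 32;
#'   defaults to the configured input size.
#' @return FLOPs in units of 1e9 (GFLOPs).
#' @export
count_flops <- function(model, input_hw = NULL) {
  if (is.null(input_hw)) input_hw <- rep(model$cfg$input_size, 2L)
  if (length(input_hw) == 1L) input_hw <- rep(input_hw, 2L)
  stopifnot(all(input_hw %% 32L == 0L))
  nl <- length(model$layers)
  hws <- vector("list", nl)
  f <- 0
  for (i in seq_len(nl)) {
    li <- model$layers[[i]]
    from <- li$from
    if (length(from) == 1L && from == -1L) from <- i - 1L
    hw_in <- if (from[1L] == 0L) input_hw else hws[[from[1L]]]
    r <- module_flops(li$m, hw_in)
    f <- f + r$f
    hws[[i]] <- r$hw
  }
  f <- f + head_flops(model$head, lapply(model$taps, function(i) hws[[i]]))
  f / 1e9
}

# ------------------------------------------------------------ checkpoints ----

mod_state <- function(m) {
  list(p = m$p, b = m$b, sub = lapply(m$sub, mod_state))
}

mod_inject <- function(m, st) {
  for (nm in names(st$p)) m$p[[nm]] <- st$p[[nm]]
  for (nm in names(st$b)) m$b[[nm]] <- st$b[[nm]]
  for (nm in names(st$sub)) m$sub[[nm]] <- mod_inject(m$sub[[nm]], st$sub[[nm]])
  m
}

state_pack_half <- function(st) {
  st$p <- lapply(st$p, function(x) list(half = .cpp_pack_half(as.numeric(x)),
                                        dim = dim(x)))
  st$b <- lapply(st$b, function(x) list(half = .cpp_pack_half(as.numeric(x)),
                                        dim = dim(x)))
  st$sub <- lapply(st$sub, state_pack_half)
  st
}

state_unpack_half <- function(st) {
  unpack <- function(e) {
    x <- .cpp_unpack_half(e$half)
    if (!is.null(e$dim)) dim(x) <- e$dim
    x
  }
  st$p <- lapply(st$p, unpack)
  st$b <- lapply(st$b, unpack)
  st$sub <- lapply(st$sub, state_unpack_half)
  st
}

#' Save a model checkpoint
#'
#' @param model a `crl_model`.
#' @param path destination file.
#' @param half store weights in IEEE binary16 (halves the file size; reloaded
#'   weights are quantized). The default double-precision checkpoint
#'   round-trips exactly.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, half = FALSE) {
  st <- list(cfg = unclass(model$cfg),
             layers = lapply(model$layers, function(l) mod_state(l$m)),
             head = mod_state(model$head),
             half = half)
  if (half) {
    st$layers <- lapply(st$layers, state_pack_half)
    st$head <- state_pack_half(st$head)
  }
  saveRDS(st, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return a `crl_model`.
#' @export
load_checkpoint <- function(path) {
  st <- readRDS(path)
  cfg <- do.call(model_config, st$cfg)
  model <- build_model(cfg)
  if (isTRUE(st$half)) {
    st$layers <- lapply(st$layers, state_unpack_half)
    st$head <- state_unpack_half(st$head)
  }
  for (i in seq_along(model$layers))
    model$layers[[i]]$m <- mod_inject(model$layers[[i]]$m, st$layers[[i]])
  model$head <- mod_inject(model$head, st$head)
  model
}

#' Summarize a model
#'
#' @param model a `crl_model`.
#' @param input_hw input size for FLOP accounting (default: configured size).
#' @return list with `parameters`, `gflops` and `size_bytes` (serialized
#'   half-precision checkpoint size).
#' @export
summarize_model <- function(model, input_hw = NULL) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  save_checkpoint(model, tf, half = TRUE)
  structure(list(parameters = count_parameters(model),
                 gflops = count_flops(model, input_hw),
                 size_bytes = file.size(tf)),
            class = "crl_summary")
}

#' @export
print.crl_summary <- function(x, ...) {
  cat(sprintf("parameters: %s\ngflops: %.3f\nsize: %.2f MB\n",
              format(x$parameters, big.mark = ","), x$gflops,
              x$size_bytes / 2^20))
  invisible(x)
}
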