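# SGD training loop and model evaluation.

#' Training hyperparameters
#'
#' Defaults follow the published training recipe: SGD with initial learning
#' rate 0.001, momentum 0.937, weight decay 0.0005, batch 16, 640-pixel
#' inputs; weights are saved every 10 epochs.
#'
#' @param lr0 initial learning rate.
#' @param lrf final learning rate fraction (linear decay to `lr0 * lrf`).
#' @param momentum SGD momentum factor.
#' @param weight_decay L2 penalty on conv kernels.
#' @param batch batch size.
#' @param img input image size in pixels.
#' @param epochs number of epochs (>= 0).
#' @param seed RNG seed for shuffling (and any stochastic augmentation).
#' @param optimizer only `"sgd"` is supported.
#' @param save_period checkpoint/validation interval in epochs.
#' @param ema_decay decay of the exponential moving average of the weights
#'   kept alongside the raw SGD iterates (the averaged weights are returned
#'   and validated); set to 0 to disable.
#' @param warmup_epochs linear warmup of the learning rate (from lr0/10) and
#'   momentum (from 0.8) over the first epochs; 0 disables.
#' @param clip_norm global gradient-norm clipping threshold; 0 disables.
#' @return a `crl_hyper` list.
#' @export
hyperparams <- function(lr0 = 0.001, lrf = 0.01, momentum = 0.937,
                        weight_decay = 0.0005, batch = 16L, img = 640L,
                        epochs = 100L, seed = 0L, optimizer = "sgd",
                        save_period = 10L, ema_decay = 0.995,
                        warmup_epochs = 3, clip_norm = 10) {
  if (optimizer != "sgd") stop("only the sgd optimizer is supported")
  stopifnot(lr0 > 0, momentum > 0, weight_decay >= 0, batch >= 1L,
            img > 0, epochs >= 0L, save_period >= 1L,
            ema_decay >= 0, ema_decay < 1, warmup_epochs >= 0, clip_norm >= 0)
  structure(list(lr0 = lr0, lrf = lrf, momentum = momentum,
                 weight_decay = weight_decay, batch = as.integer(batch),
                 img = as.integer(img), epochs = as.integer(epochs),
                 seed = as.integer(seed), optimizer = optimizer,
                 save_period = as.integer(save_period), ema_decay = ema_decay,
                 warmup_epochs = warmup_epochs, clip_norm = clip_norm),
            class = "crl_hyper")
}

# global gradient norm over a grad structure
grad_sumsq <- function(g) {
  if (is.null(g)) return(0)
  s <- 0
  for (nm in names(g$p)) s <- s + sum(g$p[[nm]]^2)
  for (nm in names(g$sub)) s <- s + grad_sumsq(g$sub[[nm]])
  s
}

grad_scale <- function(g, k) {
  if (is.null(g)) return(g)
  for (nm in names(g$p)) g$p[[nm]] <- g$p[[nm]] * k
  for (nm in names(g$sub)) g$sub[[nm]] <- grad_scale(g$sub[[nm]], k)
  g
}

# exponential moving average of parameters (buffers are copied verbatim)
ema_blend <- function(ema_m, m, d) {
  for (nm in names(m$p)) {
    if (startsWith(nm, "fused_") || nm == "dfl_proj") next
    ema_m$p[[nm]] <- d * ema_m$p[[nm]] + (1 - d) * m$p[[nm]]
  }
  ema_m$b <- m$b
  for (nm in names(m$sub))
    ema_m$sub[[nm]] <- ema_blend(ema_m$sub[[nm]], m$sub[[nm]], d)
  ema_m
}

ema_update <- function(ema, model, d, step) {
  # ramped decay: early steps track the raw weights closely so the random
  # initialization washes out of the average
  d <- d * (1 - exp(-step / 50))
  for (i in seq_along(model$layers))
    ema$layers[[i]]$m <- ema_blend(ema$layers[[i]]$m, model$layers[[i]]$m, d)
  ema$head <- ema_blend(ema$head, model$head, d)
  ema
}

# one SGD step on a module given its grad structure; returns (module, velocity)
sgd_update <- function(m, g, v, lr, momentum, wd) {
  if (is.null(g)) return(list(m = m, v = v))
  if (is.null(v)) v <- list(p = list(), sub = list())
  for (nm in names(g$p)) {
    if (startsWith(nm, "fused_") || nm == "dfl_proj") next
    gr <- g$p[[nm]]
    if (nm == "w") gr <- gr + wd * m$p[[nm]]
    vv <- v$p[[nm]]
    if (is.null(vv)) vv <- gr * 0
    vv <- momentum * vv + gr
    v$p[[nm]] <- vv
    m$p[[nm]] <- m$p[[nm]] - lr * vv
  }
  for (nm in names(g$sub)) {
    r <- sgd_update(m$sub[[nm]], g$sub[[nm]], v$sub[[nm]], lr, momentum, wd)
    m$sub[[nm]] <- r$m
    v$sub[[nm]] <- r$v
  }
  list(m = m, v = v)
}

# convert an (h, w, 3) raster in 0..255 to a (1, 3, h, w) activation map
image_to_input <- function(image) {
  x <- aperm(image / 255, c(3L, 1L, 2L))
  dim(x) <- c(1L, dim(x))
  x
}

# normalized labels -> pixel boxes
labels_to_boxes <- function(labels, width, height) {
  if (nrow(labels) == 0L)
    return(data.frame(class_id = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  data.frame(class_id = labels$class_id,
             x1 = (labels$cx - labels$w / 2) * width,
             y1 = (labels$cy - labels$h / 2) * height,
             x2 = (labels$cx + labels$w / 2) * width,
             y2 = (labels$cy + labels$h / 2) * height)
}

#' Train a detection model
#'
#' Plain SGD with momentum and linear learning-rate decay, deterministic under
#' the hyperparameter seed (single-threaded batch order). Checkpoints are
#' written every `save_period` epochs when `run_dir` is given; when a
#' validation set is supplied, the best checkpoint by validation mAP at 0.5 is
#' kept as `best.rds`.
#'
#' @param model a `crl_model`.
#' @param dataset list of scenes (`$image` raster 0..255, `$labels`
#'   normalized label frame) as produced by [generate_scene()].
#' @param hp a [hyperparams()] object.
#' @param val optional validation set in the same format.
#' @param run_dir optional directory for checkpoints and logs.
#' @param verbose print per-epoch losses.
#' @return list with `model` (final weights), `history` (per-epoch data
#'   frame), and `best` (path of the best checkpoint, if any).
#' @export
train <- function(model, dataset, hp = hyperparams(), val = NULL,
                  run_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "crl_model"), inherits(hp, "crl_hyper"))
  if (length(dataset) == 0L) stop("train: empty dataset")
  history <- data.frame(epoch = integer(), loss = numeric(), cls = numeric(),
                        box = numeric(), dfl = numeric(), lr = numeric(),
                        val_map50 = numeric())
  if (hp$epochs == 0L)
    return(list(model = model, history = history, best = NULL))
  set.seed(hp$seed)
  if (!is.null(run_dir)) dir.create(run_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  xs <- lapply(dataset, function(d) image_to_input(d$image))
  hgt <- dim(dataset[[1L]]$image)[1L]
  wdt <- dim(dataset[[1L]]$image)[2L]
  gts <- lapply(dataset, function(d) labels_to_boxes(d$labels, wdt, hgt))
  vel <- NULL
  ema <- if (hp$ema_decay > 0) model else NULL
  steps_per_epoch <- ceiling(length(dataset) / hp$batch)
  step <- 0L
  best_map <- -Inf
  best_path <- NULL
  for (epoch in seq_len(hp$epochs)) {
    lr <- hp$lr0 * (1 - (1 - hp$lrf) * (epoch - 1) / max(hp$epochs - 1, 1))
    idx <- sample(seq_along(dataset))
    ep <- c(total = 0, cls = 0, box = 0, dfl = 0)
    nb <- 0L
    for (start in seq(1L, length(idx), by = hp$batch)) {
      bi <- idx[start:min(start + hp$batch - 1L, length(idx))]
      xb <- do.call(abind_batch, xs[bi])
      fr <- forward_model(model, xb, train = TRUE)
      model <- fr$model
      ls <- compute_loss(fr$levels, gts[bi], model$head$cfg$reg_max,
                         model$strides)
      gr <- backward_model(model, fr$caches, ls$grads)
      # warmup: ramp lr and momentum over the first warmup_epochs of steps
      wsteps <- hp$warmup_epochs * steps_per_epoch
      frac <- if (wsteps > 0 && step < wsteps) (step + 1) / wsteps else 1
      lr_step <- lr * (0.1 + 0.9 * frac)
      mom_step <- 0.8 + (hp$momentum - 0.8) * frac
      if (hp$clip_norm > 0) {
        gn <- sqrt(sum(vapply(gr$layers, grad_sumsq, numeric(1))) +
                     grad_sumsq(gr$head))
        if (gn > hp$clip_norm) {
          k <- hp$clip_norm / gn
          gr$layers <- lapply(gr$layers, grad_scale, k = k)
          gr$head <- grad_scale(gr$head, k)
        }
      }
      if (is.null(vel)) vel <- list(layers = vector("list", length(model$layers)),
                                    head = NULL)
      for (i in seq_along(model$layers)) {
        r <- sgd_update(model$layers[[i]]$m, gr$layers[[i]], vel$layers[[i]],
                        lr_step, mom_step, hp$weight_decay)
        model$layers[[i]]$m <- r$m
        vel$layers[i] <- list(r$v)
      }
      r <- sgd_update(model$head, gr$head, vel$head, lr_step, mom_step,
                      hp$weight_decay)
      model$head <- r$m
      vel$head <- r$v
      step <- step + 1L
      if (!is.null(ema)) ema <- ema_update(ema, model, hp$ema_decay, step)
      ep <- ep + c(ls$total, ls$cls, ls$box, ls$dfl)
      nb <- nb + 1L
    }
    ep <- ep / nb
    vmap <- NA_real_
    if (epoch %% hp$save_period == 0L || epoch == hp$epochs) {
      eval_model <- if (is.null(ema)) model else ema
      if (!is.null(val)) {
        ev <- evaluate_model(eval_model, val)
        vmap <- ev$mAP50
        if (!is.null(run_dir) && vmap >= best_map) {
          best_map <- vmap
          best_path <- file.path(run_dir, "best.rds")
          save_checkpoint(eval_model, best_path)
        }
      }
      if (!is.null(run_dir))
        save_checkpoint(eval_model, file.path(run_dir,
                                              sprintf("epoch%03d.rds", epoch)))
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = ep[["total"]],
                                         cls = ep[["cls"]], box = ep[["box"]],
                                         dfl = ep[["dfl"]], lr = lr,
                                         val_map50 = vmap))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f (cls %.4f box %.4f dfl %.4f) lr %.2e%s",
                      epoch, ep[["total"]], ep[["cls"]], ep[["box"]],
                      ep[["dfl"]], lr,
                      if (is.na(vmap)) "" else sprintf("  val mAP50 %.3f", vmap)))
  }
  if (!is.null(run_dir))
    write.csv(history, file.path(run_dir, "history.csv"), row.names = FALSE)
  list(model = if (is.null(ema)) model else ema, raw_model = model,
       history = history, best = best_path)
}

# stack (1, C, H, W) inputs into a (B, C, H, W) batch
abind_batch <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  out <- array(0, dim = c(length(xs), d[2L], d[3L], d[4L]))
  for (i in seq_along(xs)) out[i, , , ] <- xs[[i]][1L, , , ]
  out
}

#' Run a model on one image and return detections
#'
#' @param model a `crl_model`.
#' @param image raster array `(h, w, 3)` in 0..255.
#' @param conf_threshold,nms_iou decode and suppression thresholds.
#' @return detection data frame (see [decode_boxes()]).
#' @export
predict_image <- function(model, image, conf_threshold = 0.25,
                          nms_iou = 0.45) {
  x <- image_to_input(image)
  fr <- forward_model(model, x, train = FALSE)
  dets <- decode_boxes(fr$levels, model$head$cfg$reg_max, conf_threshold,
                       model$strides,
                       img_size = c(dim(image)[2L], dim(image)[1L]))
  nms(dets, nms_iou)
}

#' Evaluate a model on a labelled dataset
#'
#' Decodes at a low confidence threshold (0.001) for a faithful
#' precision-recall curve, applies per-class NMS, and accumulates all-point
#' interpolated AP at IoU 0.5 per class.
#'
#' @param model a `crl_model`.
#' @param dataset list of scenes (`$image`, `$labels`).
#' @param conf_threshold,nms_iou decode and suppression thresholds.
#' @return metrics list from [evaluate_detections()].
#' @export
evaluate_model <- function(model, dataset, conf_threshold = 0.001,
                           nms_iou = 0.45) {
  hgt <- dim(dataset[[1L]]$image)[1L]
  wdt <- dim(dataset[[1L]]$image)[2L]
  det_list <- lapply(dataset, function(d)
    predict_image(model, d$image, conf_threshold, nms_iou))
  gt_list <- lapply(dataset, function(d) labels_to_boxes(d$labels, wdt, hgt))
  evaluate_detections(det_list, gt_list, model$head$cfg$nc)
}

#' Count detected objects per class in one image
#'
#' @inheritParams predict_image
#' @param class_names optional class names for the result.
#' @return named integer vector of per-class counts.
#' @export
count_objects <- function(model, image, conf_threshold = 0.25, nms_iou = 0.45,
                          class_names = NULL) {
  dets <- predict_image(model, image, conf_threshold, nms_iou)
  nc <- model$head$cfg$nc
  cnt <- tabulate(dets$class_id + 1L, nbins = nc)
  names(cnt) <- if (is.null(class_names)) paste0("class", seq_len(nc) - 1L)
                else class_names
  cnt
}
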