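# Synthetic orchard scenes: three phenological classes (0 = flower,
# 1 = green fruit, 2 = orange fruit) drawn as shaded blobs over layered
# foliage, with center-biased cluster placement, leaf occlusion, lighting
# variation and YOLO-format labels. Images are (h, w, 3) arrays in 0..255.

CITRUS_CLASSES <- c("flower", "green_fruit", "orange_fruit")

#' Specification of one synthetic orchard scene
#'
#' @param width,height canvas size in pixels (>= 64).
#' @param counts named integer vector of objects per class
#'   (`flower`, `green_fruit`, `orange_fruit`).
#' @param cluster_rate mean objects per cluster (>= 1); larger values give
#'   denser, more adherent clusters.
#' @param occlusion_fraction upper bound on the fraction of each object that
#'   a foreground leaf may cover, in `[0, 1]`.
#' @param lighting_gamma gamma applied to the finished scene (> 0).
#' @param backlight darken and wash out the scene as in back-lit captures.
#' @param object_scale mean object radius as a fraction of the short canvas
#'   side.
#' @param min_separation minimum centre distance between objects as a
#'   multiple of the sum of their radii; values below 1 allow overlapping,
#'   adherent fruit, larger values give sparser scenes.
#' @param seed RNG seed; the same spec renders byte-identically.
#' @return a `crl_scene_spec` list.
#' @export
scene_spec <- function(width = 640L, height = 640L,
                       counts = c(flower = 4L, green_fruit = 6L,
                                  orange_fruit = 6L),
                       cluster_rate = 2, occlusion_fraction = 0.25,
                       lighting_gamma = 1, backlight = FALSE,
                       object_scale = 0.05, min_separation = 0.8, seed = 0L) {
  stopifnot(width >= 64L, height >= 64L, all(counts >= 0L),
            cluster_rate >= 1, occlusion_fraction >= 0,
            occlusion_fraction <= 1, lighting_gamma > 0, object_scale > 0,
            min_separation > 0)
  counts <- counts[CITRUS_CLASSES]
  counts[is.na(counts)] <- 0L
  names(counts) <- CITRUS_CLASSES
  structure(list(width = as.integer(width), height = as.integer(height),
                 counts = counts, cluster_rate = cluster_rate,
                 occlusion_fraction = occlusion_fraction,
                 lighting_gamma = lighting_gamma, backlight = backlight,
                 object_scale = object_scale,
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "crl_scene_spec")
}

# pixel indices and normalized radial coordinate of a rotated ellipse
ellipse_px <- function(cx, cy, rx, ry, theta, W, H) {
  R <- max(rx, ry)
  x0 <- max(1L, floor(cx - R)); x1 <- min(W, ceiling(cx + R))
  y0 <- max(1L, floor(cy - R)); y1 <- min(H, ceiling(cy + R))
  if (x0 > x1 || y0 > y1)
    return(list(rows = integer(), cols = integer(), u = numeric()))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(ys * 0, xs - cx, "+")
  dy <- outer(ys - cy, xs * 0, "+")
  ct <- cos(theta); st <- sin(theta)
  u2 <- ((dx * ct + dy * st) / rx)^2 + ((-dx * st + dy * ct) / ry)^2
  sel <- which(u2 <= 1)
  list(rows = ((sel - 1L) %% length(ys)) + y0,
       cols = ((sel - 1L) %/% length(ys)) + x0,
       u = sqrt(u2[sel]))
}

paint <- function(img, rows, cols, color, shade = NULL) {
  if (length(rows) == 0L) return(img)
  for (ch in 1:3) {
    v <- color[ch]
    v <- if (is.null(shade)) rep(v, length(rows)) else v * shade
    img[cbind(rows, cols, ch)] <- v
  }
  img
}

draw_foliage_background <- function(W, H) {
  img <- array(0, dim = c(H, W, 3))
  base <- c(44, 92, 40)
  grad <- matrix(seq(0.85, 1.1, length.out = H), H, W)
  for (ch in 1:3) img[, , ch] <- base[ch] * grad
  n_leaf <- max(20L, as.integer(W * H / 12000))
  for (i in seq_len(n_leaf)) {
    cx <- runif(1, 1, W); cy <- runif(1, 1, H)
    r <- runif(1, 0.03, 0.10) * min(W, H)
    e <- ellipse_px(cx, cy, r, r * runif(1, 0.35, 0.7), runif(1, 0, pi), W, H)
    col <- c(30, 70, 28) * runif(1, 0.7, 1.5)
    img <- paint(img, e$rows, e$cols, col, shade = 1 - 0.3 * e$u)
  }
  noise <- array(rnorm(H * W, 0, 4), dim = c(H, W))
  for (ch in 1:3) img[, , ch] <- img[, , ch] + noise
  img
}

draw_object <- function(img, class_id, cx, cy, rx, ry, W, H) {
  if (class_id == 0L) {                      # flower: petal rosette + centre
    np <- 6L
    for (k in seq_len(np)) {
      th <- 2 * pi * k / np + runif(1, -0.2, 0.2)
      px <- cx + 0.55 * rx * cos(th)
      py <- cy + 0.55 * ry * sin(th)
      e <- ellipse_px(px, py, 0.5 * rx, 0.4 * ry, th, W, H)
      img <- paint(img, e$rows, e$cols, c(238, 240, 228),
                   shade = 1 - 0.25 * e$u)
    }
    e <- ellipse_px(cx, cy, 0.3 * rx, 0.3 * ry, 0, W, H)
    img <- paint(img, e$rows, e$cols, c(248, 208, 90), shade = 1 - 0.2 * e$u)
  } else {
    col <- if (class_id == 1L) c(128, 186, 74) else c(247, 152, 38)
    e <- ellipse_px(cx, cy, rx, ry, 0, W, H)
    img <- paint(img, e$rows, e$cols, col, shade = 0.72 + 0.28 * (1 - e$u^2))
    hl <- ellipse_px(cx - 0.3 * rx, cy - 0.3 * ry, 0.28 * rx, 0.28 * ry, 0, W, H)
    hcol <- if (class_id == 1L) c(178, 220, 120) else c(255, 206, 120)
    img <- paint(img, hl$rows, hl$cols, hcol, shade = 1 - 0.3 * hl$u)
  }
  img
}

#' Render a synthetic orchard scene
#'
#' Deterministic under the spec seed. Objects are placed with a center bias
#' in clusters; leaves drawn after the objects occlude up to
#' `occlusion_fraction` of each object, and labels cover the remaining
#' visible extent. Objects whose visible area falls below 8 px^2 are not
#' labelled.
#'
#' @param spec a [scene_spec()].
#' @return a `crl_scene`: list with `image` ((h, w, 3) array, 0..255) and
#'   `labels` (data frame `class_id, cx, cy, w, h`, normalized).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "crl_scene_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  W <- spec$width; H <- spec$height
  rbase <- spec$object_scale * min(W, H)
  n_obj <- sum(spec$counts)
  if (n_obj * pi * (1.2 * rbase)^2 > 0.8 * W * H)
    stop("generate_scene: impossible packing - too many objects for the canvas")
  img <- draw_foliage_background(W, H)

  # cluster placement, centre-biased; a cluster holds one class (flower
  # trusses and fruit hands are single-stage in the field)
  objs <- list()
  class_ids <- rep(0:2, times = spec$counts)
  remaining <- sample(class_ids)
  while (length(remaining) > 0L) {
    cid <- remaining[1L]
    k <- min(sum(remaining == cid),
             1L + stats::rpois(1, spec$cluster_rate - 1))
    ccx <- W * stats::rbeta(1, 2.2, 2.2)
    ccy <- H * stats::rbeta(1, 2.2, 2.2)
    for (i in seq_len(k)) {
      placed <- FALSE
      for (try in 1:400) {
        if (try %% 80L == 0L) {          # crowded cluster: move its centre
          ccx <- W * stats::rbeta(1, 2.2, 2.2)
          ccy <- H * stats::rbeta(1, 2.2, 2.2)
        }
        r <- rbase * runif(1, 0.7, 1.4)
        asp <- runif(1, 0.9, 1.1)
        rx <- r * sqrt(asp); ry <- r / sqrt(asp)
        if (try <= 240L) {
          cx <- ccx + rnorm(1, 0, 2.2 * r)
          cy <- ccy + rnorm(1, 0, 2.2 * r)
        } else {                          # crowded canvas: drop the centre bias
          cx <- runif(1, rx + 1, W - rx - 1)
          cy <- runif(1, ry + 1, H - ry - 1)
        }
        if (cx - rx < 1 || cx + rx > W - 1 || cy - ry < 1 || cy + ry > H - 1)
          next
        ok <- TRUE
        for (o in objs) {
          if (sqrt((cx - o$cx)^2 + (cy - o$cy)^2) <
              spec$min_separation * (max(rx, ry) + max(o$rx, o$ry))) {
            ok <- FALSE
            break
          }
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed)
        stop("generate_scene: impossible packing - no room after bounded retries")
      objs[[length(objs) + 1L]] <- list(class_id = cid, cx = cx, cy = cy,
                                        rx = rx, ry = ry)
      remaining <- remaining[-match(cid, remaining)]
    }
  }
  for (o in objs) img <- draw_object(img, o$class_id, o$cx, o$cy, o$rx, o$ry, W, H)

  # foreground leaves: occlude up to occlusion_fraction of each object
  leaf_mask <- matrix(FALSE, H, W)
  if (spec$occlusion_fraction > 0) {
    for (o in objs) {
      u <- runif(1, 0, spec$occlusion_fraction)
      if (u < 0.02) next
      r <- max(o$rx, o$ry)
      rl <- r * runif(1, 0.8, 1.1)
      th <- runif(1, 0, 2 * pi)
      d <- (r + rl) * (1 - u)
      lx <- o$cx + d * cos(th); ly <- o$cy + d * sin(th)
      e <- ellipse_px(lx, ly, rl, rl * runif(1, 0.5, 0.8), runif(1, 0, pi), W, H)
      img <- paint(img, e$rows, e$cols, c(34, 76, 30) * runif(1, 0.8, 1.2),
                   shade = 1 - 0.25 * e$u)
      leaf_mask[cbind(e$rows, e$cols)] <- TRUE
    }
  }

  # labels: bounding box of each object's extent not covered by leaves
  labels <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                       w = numeric(), h = numeric())
  for (o in objs) {
    e <- ellipse_px(o$cx, o$cy, o$rx, o$ry, 0, W, H)
    vis <- !leaf_mask[cbind(e$rows, e$cols)]
    if (sum(vis) < 8L) next
    rr <- e$rows[vis]; cc <- e$cols[vis]
    x1 <- min(cc) - 1; x2 <- max(cc); y1 <- min(rr) - 1; y2 <- max(rr)
    labels <- rbind(labels, data.frame(
      class_id = o$class_id,
      cx = (x1 + x2) / 2 / W, cy = (y1 + y2) / 2 / H,
      w = (x2 - x1) / W, h = (y2 - y1) / H))
  }

  if (spec$backlight) {
    glow <- matrix(seq(60, 0, length.out = H), H, W)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * 0.62 + glow
  }
  img <- pmin(pmax(img, 0), 255)
  if (spec$lighting_gamma != 1)
    img <- 255 * (img / 255)^spec$lighting_gamma
  structure(list(image = round(img), labels = labels, spec = spec),
            class = "crl_scene")
}

# ------------------------------------------------------------ augmentation --

#' Photometric augmentation
#'
#' `gamma`: per-channel power-law mapping `255 * (x/255)^param`, rounded.
#' `equalize`: histogram equalization of the luminance channel with chroma
#' preserved (channels rescaled by the luminance ratio); constant images are
#' returned unchanged.
#'
#' @param img (h, w, 3) array in 0..255.
#' @param kind `"gamma"` or `"equalize"`.
#' @param param gamma exponent (> 0); ignored for `"equalize"`.
#' @return augmented image.
#' @export
photometric_augment <- function(img, kind = c("gamma", "equalize"),
                                param = 1) {
  kind <- match.arg(kind)
  if (kind == "gamma") {
    stopifnot(param > 0)
    return(round(255 * (img / 255)^param))
  }
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  yi <- pmin(pmax(round(y), 0), 255)
  if (diff(range(yi)) == 0) return(img)      # degenerate histogram
  h <- tabulate(yi + 1L, nbins = 256L)
  cdf <- cumsum(h)
  cdf0 <- min(cdf[cdf > 0])
  lut <- round((cdf - cdf0) / (sum(h) - cdf0) * 255)
  y2 <- lut[yi + 1L]
  ratio <- ifelse(y > 0.5, y2 / pmax(y, 0.5), 1)
  out <- img
  for (ch in 1:3) out[, , ch] <- pmin(pmax(img[, , ch] * ratio, 0), 255)
  round(out)
}

#' Mixup of two labelled scenes
#'
#' Pixel-wise convex combination; both label sets are kept.
#'
#' @param a,b `crl_scene` objects of identical size.
#' @param lam mixing weight in `[0, 1]` applied to `a`.
#' @return a `crl_scene`.
#' @export
mixup <- function(a, b, lam = 0.5) {
  stopifnot(lam >= 0, lam <= 1)
  if (!identical(dim(a$image), dim(b$image)))
    stop("mixup: images must have the same size")
  structure(list(image = lam * a$image + (1 - lam) * b$image,
                 labels = rbind(a$labels, b$labels)),
            class = "crl_scene")
}

resize_nearest <- function(img, h2, w2) {
  d <- dim(img)
  ri <- pmin(d[1L], pmax(1L, ceiling(seq_len(h2) * d[1L] / h2)))
  ci <- pmin(d[2L], pmax(1L, ceiling(seq_len(w2) * d[2L] / w2)))
  img[ri, ci, , drop = FALSE]
}

#' Mosaic of four labelled scenes
#'
#' A junction point is sampled in the central half of the canvas; each input
#' is rescaled into its quadrant. Labels are rescaled and shifted with the
#' pixels; labels whose area falls below 8 px^2 are dropped.
#'
#' @param quad list of four `crl_scene` objects.
#' @param canvas_size output square size in pixels.
#' @param seed RNG seed for the junction point.
#' @param junction optional fixed junction point `c(x, y)` in pixels,
#'   overriding the random draw.
#' @return a `crl_scene`.
#' @export
mosaic <- function(quad, canvas_size = 640L, seed = 0L, junction = NULL) {
  stopifnot(length(quad) == 4L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  S <- as.integer(canvas_size)
  if (is.null(junction)) {
    jx <- as.integer(round(runif(1, 0.25, 0.75) * S))
    jy <- as.integer(round(runif(1, 0.25, 0.75) * S))
  } else {
    jx <- as.integer(junction[1L]); jy <- as.integer(junction[2L])
  }
  rects <- list(c(1L, 1L, jx, jy), c(jx + 1L, 1L, S, jy),
                c(1L, jy + 1L, jx, S), c(jx + 1L, jy + 1L, S, S))
  img <- array(0, dim = c(S, S, 3))
  labels <- list()
  for (k in 1:4) {
    r <- rects[[k]]
    wq <- r[3L] - r[1L] + 1L; hq <- r[4L] - r[2L] + 1L
    img[r[2L]:r[4L], r[1L]:r[3L], ] <- resize_nearest(quad[[k]]$image, hq, wq)
    lb <- quad[[k]]$labels
    if (nrow(lb) > 0L) {
      px_area <- lb$w * wq * lb$h * hq
      lb <- data.frame(class_id = lb$class_id,
                       cx = (lb$cx * wq + r[1L] - 1L) / S,
                       cy = (lb$cy * hq + r[2L] - 1L) / S,
                       w = lb$w * wq / S, h = lb$h * hq / S)
      labels[[k]] <- lb[px_area >= 8, , drop = FALSE]
    }
  }
  lab <- do.call(rbind, labels)
  if (is.null(lab))
    lab <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric())
  structure(list(image = img, labels = lab), class = "crl_scene")
}

# ---------------------------------------------------------------- splitting --

#' Split items into train/validation/test sets
#'
#' Seeded shuffle followed by largest-remainder apportionment, so partition
#' sizes differ from the exact ratios by less than one item each.
#'
#' @param item_ids vector of item identifiers.
#' @param ratios train/val/test proportions summing to 1 (default 7:1:2).
#' @param seed shuffle seed.
#' @return named list `train`, `val`, `test` of disjoint id vectors.
#' @export
split_dataset <- function(item_ids, ratios = c(0.7, 0.1, 0.2), seed = 0L) {
  if (length(item_ids) == 0L) stop("split_dataset: empty input")
  stopifnot(abs(sum(ratios) - 1) < 1e-9, length(ratios) == 3L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- length(item_ids)
  ideal <- n * ratios
  sizes <- floor(ideal)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    o <- order(-(ideal - sizes))
    sizes[o[seq_len(rem)]] <- sizes[o[seq_len(rem)]] + 1L
  }
  ids <- sample(item_ids)
  list(train = ids[seq_len(sizes[1L])],
       val = ids[sizes[1L] + seq_len(sizes[2L])],
       test = ids[sizes[1L] + sizes[2L] + seq_len(sizes[3L])])
}

# ----------------------------------------------------------------- label IO --

#' Write YOLO-format labels
#'
#' One `class cx cy w h` line per object, 6-decimal fixed format.
#'
#' @param labels data frame with `class_id, cx, cy, w, h` (normalized), or a
#'   `crl_scene`.
#' @param path output text file.
#' @export
write_yolo_labels <- function(labels, path) {
  if (inherits(labels, "crl_scene")) labels <- labels$labels
  lines <- character(0)
  if (nrow(labels) > 0L)
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", labels$class_id,
                     labels$cx, labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-format labels
#'
#' @param path label text file.
#' @return data frame with `class_id, cx, cy, w, h`.
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                    w = numeric(), h = numeric())
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(tok) != 5L || any(is.na(vals)))
      stop("read_yolo_labels: malformed line ", i, ": '", lines[i], "'")
    out <- rbind(out, data.frame(class_id = as.integer(vals[1L]),
                                 cx = vals[2L], cy = vals[3L],
                                 w = vals[4L], h = vals[5L]))
  }
  out
}

#' Save a scene as PNG plus YOLO labels
#'
#' @param scene a `crl_scene`.
#' @param img_path PNG destination.
#' @param lbl_path label txt destination (default: same name, `.txt`).
#' @export
save_scene <- function(scene, img_path,
                       lbl_path = sub("\\.png$", ".txt", img_path)) {
  png::writePNG(scene$image / 255, img_path)
  write_yolo_labels(scene$labels, lbl_path)
  invisible(img_path)
}

#' Load an image (PNG/JPEG written by [save_scene()]) and its labels
#'
#' @param img_path PNG file.
#' @param lbl_path label txt file (default: same name, `.txt`).
#' @return a `crl_scene`.
#' @export
load_scene <- function(img_path,
                       lbl_path = sub("\\.png$", ".txt", img_path)) {
  img <- png::readPNG(img_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  structure(list(image = round(img[, , 1:3] * 255),
                 labels = read_yolo_labels(lbl_path)),
            class = "crl_scene")
}

#' Generate a synthetic dataset
#'
#' Renders `n` scenes from a template spec with consecutive seeds.
#'
#' @param n number of scenes.
#' @param template a [scene_spec()] whose seed is used as the base.
#' @return list of `crl_scene` objects.
#' @export
synth_dataset <- function(n, template = scene_spec()) {
  lapply(seq_len(n), function(i) {
    sp <- template
    sp$seed <- template$seed + i - 1L
    generate_scene(sp)
  })
}

# -------------------------------------------------------------- tree counts --

#' Simulate tree-level visible/true fruit count pairs
#'
#' Emulates single-side-view network counts against whole-tree truth: visible
#' counts are drawn uniformly over the observed field range (40-90) and the
#' true count follows the linear relation
#' `actual = alpha * detect + beta + noise`, floored at the visible count so
#' that `detect <= actual` always holds.
#'
#' @param n_trees number of trees.
#' @param alpha slope of the count-to-yield relation (> 0); if `visibility`
#'   is given, `alpha = 1 / visibility`.
#' @param beta intercept.
#' @param sigma standard deviation of the count noise.
#' @param visibility optional fraction of fruit visible from one side,
#'   in (0, 1].
#' @param seed RNG seed.
#' @param detect_range range of visible counts.
#' @return data frame `tree_id, detect, actual`.
#' @export
generate_tree_views <- function(n_trees, alpha = 1.44, beta = 0, sigma = 5,
                                visibility = NULL, seed = 0L,
                                detect_range = c(40L, 90L)) {
  if (!is.null(visibility)) {
    if (visibility <= 0 || visibility > 1)
      stop("generate_tree_views: visibility must be in (0, 1]")
    alpha <- 1 / visibility
  }
  stopifnot(alpha > 0, sigma >= 0, n_trees >= 1L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  detect <- sample(seq(detect_range[1L], detect_range[2L]), n_trees,
                   replace = TRUE)
  actual <- pmax(detect,
                 round(alpha * detect + beta + rnorm(n_trees, 0, sigma)))
  data.frame(tree_id = seq_len(n_trees), detect = as.integer(detect),
             actual = as.integer(actual))
}
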