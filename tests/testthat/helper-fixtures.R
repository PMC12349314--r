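# Shared fixtures. Tiny models are cached per session; the nano-scale
# variants used for accounting are cheap to build but not free, so build once.

tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(1)
      cache <<- build_model(model_config("yolov8_rl", num_classes = 3L,
                                         width_multiple = 0.0625,
                                         input_size = 64L))
    }
    cache
  }
})

nano_model <- local({
  cache <- list()
  function(variant, nc = 80L) {
    key <- paste(variant, nc)
    if (is.null(cache[[key]])) {
      set.seed(1)
      cache[[key]] <<- build_model(model_config(variant, num_classes = nc))
    }
    cache[[key]]
  }
})

# a repconv with non-trivial batch-norm statistics, as after training
random_repconv <- function(ci, co, act = "none") {
  m <- citrusRL:::repconv(ci, co, act = act)
  m$sub$n3$b$rm <- rnorm(co); m$sub$n3$b$rv <- runif(co, 0.4, 2)
  m$sub$n3$p$gamma <- runif(co, 0.5, 1.5); m$sub$n3$p$beta <- rnorm(co, 0, 0.3)
  m$sub$n1$b$rm <- rnorm(co); m$sub$n1$b$rv <- runif(co, 0.4, 2)
  m$sub$n1$p$gamma <- runif(co, 0.5, 1.5); m$sub$n1$p$beta <- rnorm(co, 0, 0.3)
  m
}

rand_map <- function(n, c, h, w) array(rnorm(n * c * h * w), dim = c(n, c, h, w))

# brute-force all-point interpolated AP: for every distinct recall level,
# take the maximum precision among all cutoffs reaching at least that recall
ap_oracle <- function(flags, n_gt) {
  if (n_gt == 0L || length(flags) == 0L) return(0)
  tp <- cumsum(flags); fp <- cumsum(!flags)
  rec <- tp / n_gt
  prec <- tp / (tp + fp)
  ap <- 0
  prev_r <- 0
  for (r in sort(unique(rec[flags]))) {       # recall increases only at TPs
    p_at <- max(prec[rec >= r])
    ap <- ap + (r - prev_r) * p_at
    prev_r <- r
  }
  ap
}

small_scene_spec <- function(seed = 0L, ...) {
  args <- list(width = 128L, height = 128L,
               counts = c(flower = 1L, green_fruit = 2L, orange_fruit = 2L),
               occlusion_fraction = 0.1, object_scale = 0.1, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(scene_spec, args)
}
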