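# Activation maps are 4-D arrays, dim = c(batch, channels, height, width).

#' Create an activation map
#'
#' Wraps a numeric vector or array into the 4-D layout used throughout the
#' package: `dim = c(batch, channels, height, width)`.
#'
#' @param values numeric vector or array of length `n * c * h * w`.
#' @param n,c,h,w batch size, channels, height, width.
#' @return a 4-D numeric array.
#' @export
act_map <- function(values, n = 1L, c = 1L, h = 1L, w = 1L) {
  x <- array(as.numeric(values), dim = c(n, c, h, w))
  check_act_map(x)
  x
}

check_act_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("activation map must be a 4-D array (batch, channels, height, width)")
  if (any(d <= 0L)) stop("activation map dimensions must be positive")
  if (!all(is.finite(x))) stop("activation map contains non-finite values")
  invisible(x)
}

act_dims <- function(x) {
  d <- dim(x)
  list(n = d[1L], c = d[2L], h = d[3L], w = d[4L])
}

# channel slice, keeping 4-D shape
chan_slice <- function(x, idx) {
  x[, idx, , , drop = FALSE]
}

chan_concat <- function(xs) {
  d <- dim(xs[[1L]])
  cs <- vapply(xs, function(x) dim(x)[2L], integer(1L))
  out <- array(0, dim = c(d[1L], sum(cs), d[3L], d[4L]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[2L]
    out[, at + seq_len(cc), , ] <- x
    at <- at + cc
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

silu_fw <- function(x) .cpp_silu_fw(x)

silu_bw <- function(x, gy) .cpp_silu_bw(x, gy)
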