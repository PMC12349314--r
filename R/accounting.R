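# Closed-form parameter accounting per block kind. These formulas are the
# independent arithmetic against which the assembled models are checked:
# conv kernels + conv biases + affine norm parameters; running statistics
# excluded. All counts are independent of input spatial size.

#' Closed-form trainable-parameter count of a building block
#'
#' @param kind one of `"CBS"`, `"Conv_GN"`, `"RepConv"`, `"RGCSPELAN"`,
#'   `"C2f"`, `"SPPF"`, `"Conv2d"`.
#' @param cin,cout input/output channels.
#' @param k kernel size (for `"CBS"`, `"Conv_GN"`, `"Conv2d"`).
#' @param n number of inner units (`"C2f"` bottlenecks / `"RGCSPELAN"`
#'   RepConv units).
#' @param c,m RGCSPELAN stem and branch widths (default `cout/2`, `c/2`).
#' @param bias whether a bare `"Conv2d"` carries a bias.
#' @return integer parameter count.
#' @export
block_param_count <- function(kind, cin, cout, k = 3L, n = 1L,
                              c = NULL, m = NULL, bias = TRUE) {
  conv_n <- function(ci, co, k) k * k * ci * co + 2L * co     # conv + affine norm
  as.integer(switch(kind,
    CBS = ,
    Conv_GN = conv_n(cin, cout, k),
    Conv2d = k * k * cin * cout + if (bias) cout else 0L,
    RepConv = conv_n(cin, cout, 3L) + conv_n(cin, cout, 1L),
    C2f = {
      ch <- cout %/% 2L
      conv_n(cin, 2L * ch, 1L) + conv_n((2L + n) * ch, cout, 1L) +
        n * 2L * conv_n(ch, ch, 3L)
    },
    SPPF = {
      ch <- cin %/% 2L
      conv_n(cin, ch, 1L) + conv_n(4L * ch, cout, 1L)
    },
    RGCSPELAN = {
      if (is.null(c)) c <- cout %/% 2L
      if (is.null(m)) m <- c %/% 2L
      a <- c %/% 2L
      b <- c - a
      conv_n(cin, c, 1L) +
        (conv_n(b, m, 3L) + conv_n(b, m, 1L)) +
        (n - 1L) * (conv_n(m, m, 3L) + conv_n(m, m, 1L)) +
        conv_n(m, m, 3L) +
        conv_n(a + (n + 1L) * m, cout, 1L)
    },
    stop("block_param_count: unknown block kind ", kind)
  ))
}
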