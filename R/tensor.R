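#' Feature maps
#'
#' Activation tensors are plain numeric arrays with `dim = c(N, C, H, W)`
#' (batch, channel, height, width). These helpers validate and query them.
#'
#' @param x an object to check or query.
#' @return `as_feature_map()` returns the validated array; `fm_dim()` its
#'   dimension vector named `n`, `c`, `h`, `w`.
#' @examples
#' x <- array(rnorm(2 * 3 * 4 * 4), dim = c(2, 3, 4, 4))
#' fm_dim(x)
#' @export
as_feature_map <- function(x) {
  if (!is.numeric(x) || length(dim(x)) != 4L)
    stop("a feature map must be a numeric array with 4 dimensions (N, C, H, W)")
  storage.mode(x) <- "double"
  x
}

#' @rdname as_feature_map
#' @export
fm_dim <- function(x) {
  d <- dim(x)
  if (length(d) != 4L) stop("not a feature map (need 4 dimensions)")
  c(n = d[1], c = d[2], h = d[3], w = d[4])
}

#' 2-D convolution (internal workhorse)
#'
#' Thin wrapper over the C++ im2col/GEMM kernel. Weights have
#' `dim = c(out_channels, in_channels / groups, kh, kw)`.
#'
#' @param x feature map, dim (N, C, H, W).
#' @param w kernel array as above.
#' @param b optional bias vector of length `out_channels`, or `NULL`.
#' @param stride,pad integer stride and zero-padding (same on both axes).
#' @param groups number of channel groups (`groups = C` is depthwise).
#' @return output feature map, dim (N, OC, OH, OW).
#' @keywords internal
conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  x <- as_feature_map(x)
  wd <- dim(w)
  if (!is.null(b)) {
    # fast paths for the two conv shapes that dominate the network
    if (wd[3] == 3L && wd[4] == 3L && wd[2] == 1L && stride == 1L &&
        pad == 1L && groups == dim(x)[2] && wd[1] == groups)
      return(dwconv3_fwd_cpp(x, w, b))
    if (wd[3] == 1L && wd[4] == 1L && stride == 1L && pad == 0L && groups == 1L)
      return(pwconv_fwd_cpp(x, w, b))
  }
  conv2d_fwd_cpp(x, w, b, as.integer(stride), as.integer(pad), as.integer(groups))
}

conv2d_grad <- function(x, w, gy, has_bias, stride = 1L, pad = 0L, groups = 1L,
                        need_gx = TRUE) {
  wd <- dim(w)
  if (has_bias && need_gx) {
    if (wd[3] == 3L && wd[4] == 3L && wd[2] == 1L && stride == 1L &&
        pad == 1L && groups == dim(x)[2] && wd[1] == groups)
      return(dwconv3_bwd_cpp(x, w, gy))
    if (wd[3] == 1L && wd[4] == 1L && stride == 1L && pad == 0L && groups == 1L)
      return(pwconv_bwd_cpp(x, w, gy))
  }
  conv2d_bwd_cpp(x, w, gy, has_bias, as.integer(stride), as.integer(pad),
                 as.integer(groups), need_gx)
}

#' Exact GELU activation
#'
#' The Gaussian error linear unit in its exact (erf-based) form,
#' `gelu(x) = x * pnorm(x)`, applied elementwise. The derivative is
#' `pnorm(x) + x * dnorm(x)`.
#'
#' @param x numeric vector or array.
#' @return object of the same shape.
#' @examples
#' gelu(c(-1, 0, 1))  # c(-0.1587, 0, 0.8413)
#' @export
gelu <- function(x) gelu_cpp(x)

gelu_grad <- function(x) gelu_grad_cpp(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Row-wise max of a numeric matrix plus argmax with deterministic ("first")
# tie-breaking; used by both pooling paths and their backward routing.
row_max_which <- function(m) {
  idx <- max.col(m, ties.method = "first")
  list(max = m[cbind(seq_len(nrow(m)), idx)], idx = idx)
}
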