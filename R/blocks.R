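#' GRN-GELU convolution module, downsample layer, and stem
#'
#' The GRN-GELU module is the residual building block of the network:
#' a depthwise 3x3 convolution (one filter per channel, with bias), global
#' response normalization, exact GELU, a pointwise 1x1 convolution (with
#' bias), a residual addition of the block input, and a final GELU:
#' `y = GELU(x + pw(GELU(GRN(dw(x)))))`. Channels are preserved, so the
#' trainable-parameter count per module is exactly `C^2 + 13 C`
#' (`C^2 + C` pointwise, `10 C` depthwise, `2 C` GRN).
#'
#' The downsample layer halves the spatial resolution with a 2x2 stride-2
#' convolution (with bias) while doubling the channel count; it carries no
#' normalization or activation of its own (`8 C^2 + 2 C` parameters). The stem
#' maps the 3-channel image to the base width with a 3x3 stride-2 padding-1
#' convolution without bias, followed by GRN and GELU.
#'
#' @param channels channel count `C` of the module input (and output).
#' @param init `"zeros"` or `"random"` (truncated normal, sd 0.02; biases and
#'   GRN parameters always start at zero).
#' @return parameter lists, or output feature maps.
#' @examples
#' p <- gge_conv_params(4)
#' x <- array(rnorm(64), dim = c(1, 4, 4, 4))
#' y <- gge_conv_forward(x, p)      # == gelu(x) at zero-initialized weights
#' stopifnot(max(abs(y - gelu(x))) < 1e-12)
#' @export
gge_conv_params <- function(channels, init = "zeros") {
  dw <- array(0, dim = c(channels, 1, 3, 3))
  pw <- array(0, dim = c(channels, channels, 1, 1))
  if (init == "random") {
    dw[] <- trunc_normal(length(dw), sqrt(2 / 9))
    pw[] <- trunc_normal(length(pw), sqrt(2 / channels))
  }
  list(dw_w = dw, dw_b = numeric(channels),
       grn = grn_params(channels),
       pw_w = pw, pw_b = numeric(channels))
}

#' @rdname gge_conv_params
#' @export
downsample_params <- function(channels, init = "zeros") {
  w <- array(0, dim = c(2 * channels, channels, 2, 2))
  if (init == "random") w[] <- trunc_normal(length(w), sqrt(2 / (4 * channels)))
  list(w = w, b = numeric(2 * channels))
}

#' @rdname gge_conv_params
#' @param out_channels stem output width (the network base width).
#' @export
stem_params <- function(out_channels, init = "zeros") {
  w <- array(0, dim = c(out_channels, 3, 3, 3))
  if (init == "random") w[] <- trunc_normal(length(w), sqrt(2 / 27))
  list(w = w, grn = grn_params(out_channels))
}

#' @rdname gge_conv_params
#' @param x feature map, dim (N, C, H, W); the stem expects C = 3.
#' @param p a parameter list from the matching constructor.
#' @export
gge_conv_forward <- function(x, p) gge_fwd(x, p)$y

#' @rdname gge_conv_params
#' @export
downsample_forward <- function(x, p) down_fwd(x, p)$y

#' @rdname gge_conv_params
#' @export
stem_forward <- function(x, p) stem_fwd(x, p)$y

gge_fwd <- function(x, p) {
  x <- as_feature_map(x)
  C <- dim(x)[2]
  if (dim(p$pw_w)[1] != C)
    stop(sprintf("GRN-GELU module built for %d channels, input has %d", dim(p$pw_w)[1], C))
  t1 <- conv2d(x, p$dw_w, p$dw_b, stride = 1, pad = 1, groups = C)
  g <- grn_fwd(t1, p$grn)
  gf <- gelu_fused_cpp(g$y)
  t4 <- conv2d(gf$y, p$pw_w, p$pw_b, stride = 1, pad = 0)
  r <- x + t4
  rf <- gelu_fused_cpp(r)
  list(y = rf$y,
       cache = list(x = x, grn = g$cache, ugrad = gf$grad, a = gf$y,
                    rgrad = rf$grad))
}

gge_bwd <- function(p, cache, gy) {
  C <- dim(cache$x)[2]
  gr <- gy * cache$rgrad
  pwb <- conv2d_grad(cache$a, p$pw_w, gr, TRUE, stride = 1, pad = 0)
  gu <- pwb$gx * cache$ugrad
  gb <- grn_bwd(p$grn, cache$grn, gu)
  dwb <- conv2d_grad(cache$x, p$dw_w, gb$gx, TRUE, stride = 1, pad = 1, groups = C)
  list(gx = gr + dwb$gx,
       grads = list(dw_w = dwb$gw, dw_b = dwb$gb,
                    grn = list(gamma = gb$gamma, beta = gb$beta),
                    pw_w = pwb$gw, pw_b = pwb$gb))
}

down_fwd <- function(x, p) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[3] < 2 || d[4] < 2)
    stop("downsample: spatial dimensions must be at least 2")
  list(y = conv2d(x, p$w, p$b, stride = 2, pad = 0), cache = list(x = x))
}

down_bwd <- function(p, cache, gy) {
  cb <- conv2d_grad(cache$x, p$w, gy, TRUE, stride = 2, pad = 0)
  list(gx = cb$gx, grads = list(w = cb$gw, b = cb$gb))
}

stem_fwd <- function(x, p) {
  x <- as_feature_map(x)
  if (dim(x)[2] != 3)
    stop("stem expects a 3-channel (RGB) input")
  t1 <- conv2d(x, p$w, NULL, stride = 2, pad = 1)
  g <- grn_fwd(t1, p$grn)
  gf <- gelu_fused_cpp(g$y)
  list(y = gf$y, cache = list(x = x, grn = g$cache, ugrad = gf$grad))
}

stem_bwd <- function(p, cache, gy, need_gx = FALSE) {
  gu <- gy * cache$ugrad
  gb <- grn_bwd(p$grn, cache$grn, gu)
  cb <- conv2d_grad(cache$x, p$w, gb$gx, FALSE, stride = 2, pad = 1,
                    need_gx = need_gx)
  list(gx = cb$gx,
       grads = list(w = cb$gw, grn = list(gamma = gb$gamma, beta = gb$beta)))
}

# ---- classifier head: global average pool + linear ------------------------

head_params <- function(channels, n_classes, init = "zeros") {
  w <- matrix(0, n_classes, channels)
  if (init == "random") w[] <- trunc_normal(length(w), sqrt(1 / channels))
  list(w = w, b = numeric(n_classes))
}

head_fwd <- function(x, p) {
  d <- dim(x); N <- d[1]; C <- d[2]; HW <- d[3] * d[4]
  xm <- x; dim(xm) <- c(N * C, HW)
  pooled <- matrix(rowMeans(xm), N, C)
  list(y = pooled %*% t(p$w) + rep(p$b, each = N),
       cache = list(d = d, pooled = pooled))
}

head_bwd <- function(p, cache, gy) {
  d <- cache$d; N <- d[1]; C <- d[2]; HW <- d[3] * d[4]
  gpool <- gy %*% p$w                              # N x C
  gx <- array(rep(as.vector(gpool) / HW, times = HW), dim = d)
  list(gx = gx,
       grads = list(w = t(gy) %*% cache$pooled, b = colSums(gy)))
}
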