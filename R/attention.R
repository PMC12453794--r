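#' Channel and spatial attention (convolutional block attention)
#'
#' The attention module gates a feature map twice, in sequence. Channel
#' attention pools each channel globally by average and by max, pushes both
#' descriptors through one shared bottleneck MLP (`C -> C/r -> C`, ReLU in the
#' middle, no biases), sums the two outputs, and applies a sigmoid to obtain a
#' per-channel gate in (0, 1). Spatial attention then pools the gated map
#' across channels (mean and max), stacks the two single-channel maps, applies
#' one `k x k` convolution (2 input channels, 1 output, no bias, same
#' padding), and a sigmoid to obtain a per-position gate. Both gates multiply
#' the tensor elementwise, so the module output never exceeds its input in
#' magnitude.
#'
#' `attention_module()` composes the two sequentially — the spatial gate is
#' computed on, and applied to, the channel-gated tensor — and its output is
#' the "attention map" that knowledge distillation transfers. Setting
#' `literal_eq11 = TRUE` instead evaluates the literal printed algebra
#' `out_s(x) * (out_c(x) * x)`, in which the raw input enters the product
#' twice; it is provided for study only and has no backward pass.
#'
#' @param channels number of input channels `C`.
#' @param r reduction ratio of the bottleneck MLP; must divide `channels`.
#' @param k spatial kernel size (odd; default 7, padded by `(k-1)/2`).
#' @param init `"zeros"` or `"random"` (truncated normal, sd 0.02).
#' @return parameter lists, or the gated feature map (same shape as input).
#' @examples
#' x <- array(rnorm(32), dim = c(1, 2, 4, 4))
#' cp <- channel_attention_params(2, r = 2)
#' sp <- spatial_attention_params(k = 3)
#' y <- attention_module(x, cp, sp)   # == 0.25 * x at zero-initialized weights
#' stopifnot(max(abs(y - 0.25 * x)) < 1e-12)
#' @export
channel_attention_params <- function(channels, r = 16, init = "zeros") {
  if (channels %% r != 0)
    stop(sprintf("reduction ratio r = %d must divide the channel count C = %d", r, channels))
  cr <- channels %/% r
  list(w1 = init_mat(cr, channels, init, fan_in = channels),
       w2 = init_mat(channels, cr, init, fan_in = cr),
       r = r)
}

#' @rdname channel_attention_params
#' @export
spatial_attention_params <- function(k = 7, init = "zeros") {
  if (k %% 2 != 1) stop("spatial attention kernel size k must be odd")
  kern <- array(0, dim = c(1, 2, k, k))
  if (init == "random") kern[] <- trunc_normal(length(kern), sqrt(1 / (2 * k^2)))
  list(kernel = kern, k = k)
}

init_mat <- function(nr, nc, init, fan_in = nc) {
  m <- matrix(0, nr, nc)
  if (init == "random") m[] <- trunc_normal(nr * nc, sqrt(1 / fan_in))
  m
}

# Truncated (at 2 sd) normal draw; sd is chosen from the receiving fan-in so
# activations neither explode nor vanish through the unnormalized stack.
trunc_normal <- function(n, sd) {
  qnorm(runif(n, pnorm(-2), pnorm(2))) * sd
}

#' @rdname channel_attention_params
#' @param x feature map, dim (N, C, H, W).
#' @param p,cp,sp parameter lists from the constructors above.
#' @export
channel_attention <- function(x, p) ca_fwd(x, p)$y

#' @rdname channel_attention_params
#' @export
spatial_attention <- function(x, p) sa_fwd(x, p)$y

#' @rdname channel_attention_params
#' @param literal_eq11 evaluate the literal (double-counting) product instead
#'   of the sequential composition; forward only.
#' @export
attention_module <- function(x, cp, sp, literal_eq11 = FALSE) {
  if (literal_eq11) {
    gate_c <- ca_fwd(x, cp)$gate_full
    gate_s <- sa_fwd(x, sp)$gate_full
    return((x * gate_s) * ((x * gate_c) * x))
  }
  sa_fwd(ca_fwd(x, cp)$y, sp)$y
}

# ---- channel attention internals ------------------------------------------

ca_fwd <- function(x, p) {
  x <- as_feature_map(x)
  d <- dim(x); N <- d[1]; C <- d[2]; HW <- d[3] * d[4]
  if (ncol(p$w1) != C)
    stop(sprintf("channel attention built for %d channels, input has %d", ncol(p$w1), C))
  xm <- x; dim(xm) <- c(N * C, HW)
  Am <- matrix(rowMeans(xm), N, C)
  mw <- row_max_which(xm)
  Mm <- matrix(mw$max, N, C)

  H1a <- Am %*% t(p$w1); H1ar <- relu(H1a)
  H1m <- Mm %*% t(p$w1); H1mr <- relu(H1m)
  z <- H1ar %*% t(p$w2) + H1mr %*% t(p$w2)
  gate <- sigmoid(z)                               # N x C
  ym <- xm * as.vector(gate)
  y <- ym; dim(y) <- d
  gate_full <- array(rep(as.vector(gate), times = HW), dim = d)
  list(y = y,
       gate_full = gate_full,
       cache = list(x = x, d = d, Am = Am, Mm = Mm, midx = mw$idx,
                    H1a = H1a, H1ar = H1ar, H1m = H1m, H1mr = H1mr,
                    gate = gate))
}

ca_bwd <- function(p, cache, gy) {
  d <- cache$d; N <- d[1]; C <- d[2]; HW <- d[3] * d[4]
  xm <- cache$x; dim(xm) <- c(N * C, HW)
  gym <- gy; dim(gym) <- c(N * C, HW)
  gate <- cache$gate

  ggate <- matrix(rowSums(gym * xm), N, C)
  gxm <- gym * as.vector(gate)
  gz <- ggate * gate * (1 - gate)

  # both MLP branches share w1/w2
  gH1ar <- gz %*% p$w2; gH1a <- gH1ar * (cache$H1a > 0)
  gH1mr <- gz %*% p$w2; gH1m <- gH1mr * (cache$H1m > 0)
  gw2 <- t(gz) %*% cache$H1ar + t(gz) %*% cache$H1mr
  gw1 <- t(gH1a) %*% cache$Am + t(gH1m) %*% cache$Mm
  gA <- gH1a %*% p$w1                              # N x C
  gM <- gH1m %*% p$w1

  gxm <- gxm + as.vector(gA) / HW                  # average-pool backward
  sc <- cbind(seq_len(N * C), cache$midx)          # max-pool backward
  gxm[sc] <- gxm[sc] + as.vector(gM)
  gx <- gxm; dim(gx) <- d
  list(gx = gx, w1 = gw1, w2 = gw2)
}

# ---- spatial attention internals ------------------------------------------

sa_fwd <- function(x, p) {
  x <- as_feature_map(x)
  d <- dim(x); N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  pad <- (p$k - 1L) %/% 2L
  xp <- aperm(x, c(1, 3, 4, 2))                    # (N, H, W, C)
  xpm <- xp; dim(xpm) <- c(N * H * W, C)
  avg <- rowMeans(xpm)
  mw <- row_max_which(xpm)

  xcat <- array(0, dim = c(N, 2, H, W))
  xcat[, 1, , ] <- array(avg, dim = c(N, H, W))
  xcat[, 2, , ] <- array(mw$max, dim = c(N, H, W))
  s <- conv2d(xcat, p$kernel, NULL, stride = 1, pad = pad)
  gate <- sigmoid(s)                               # (N, 1, H, W)
  gate_v <- as.vector(gate)                        # ordered (n, h, w)
  ypm <- xpm * gate_v
  y <- ypm; dim(y) <- c(N, H, W, C); y <- aperm(y, c(1, 4, 2, 3))
  gate_full <- aperm(array(rep(gate_v, times = C), dim = c(N, H, W, C)),
                     c(1, 4, 2, 3))
  list(y = y, gate_full = gate_full,
       cache = list(d = d, xpm = xpm, midx = mw$idx, xcat = xcat,
                    s = s, gate_v = gate_v, pad = pad))
}

sa_bwd <- function(p, cache, gy) {
  d <- cache$d; N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  gyp <- aperm(gy, c(1, 3, 4, 2))
  gypm <- gyp; dim(gypm) <- c(N * H * W, C)

  ggate_v <- rowSums(gypm * cache$xpm)
  gxpm <- gypm * cache$gate_v

  gate_v <- cache$gate_v
  gs <- ggate_v * gate_v * (1 - gate_v)
  gs <- array(gs, dim = c(N, 1, H, W))
  cb <- conv2d_grad(cache$xcat, p$kernel, gs, FALSE, stride = 1, pad = cache$pad)
  gavg <- as.vector(cb$gx[, 1, , ])
  gmax <- as.vector(cb$gx[, 2, , ])

  gxpm <- gxpm + gavg / C                          # mean-pool backward
  sc <- cbind(seq_len(N * H * W), cache$midx)      # channel-max backward
  gxpm[sc] <- gxpm[sc] + gmax
  gx <- gxpm; dim(gx) <- c(N, H, W, C); gx <- aperm(gx, c(1, 4, 2, 3))
  list(gx = gx, kernel = cb$gw)
}

# ---- composed module (sequential) -----------------------------------------

cbam_fwd <- function(x, params) {
  ca <- ca_fwd(x, params$ca)
  sa <- sa_fwd(ca$y, params$sa)
  list(y = sa$y, cache = list(ca = ca$cache, sa = sa$cache))
}

cbam_bwd <- function(params, cache, gy) {
  sb <- sa_bwd(params$sa, cache$sa, gy)
  cbk <- ca_bwd(params$ca, cache$ca, sb$gx)
  list(gx = cbk$gx,
       grads = list(ca = list(w1 = cbk$w1, w2 = cbk$w2),
                    sa = list(kernel = sb$kernel)))
}
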