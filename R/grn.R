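#' Global response normalization (GRN)
#'
#' Per sample, the layer aggregates each channel over space with a Euclidean
#' norm, `G_c = sqrt(sum_{i,j} x_c[i,j]^2)`, divides by the cross-channel mean,
#' `N_c = G_c / (mean_c G + 1e-6)`, and rescales the input with learnable
#' per-channel gain and shift around a residual pass-through:
#' `y = gamma_c * (x * N_c) + beta_c + x`.
#'
#' With `gamma = beta = 0` (the default initialization) the layer is exactly
#' the identity, which keeps early training stable. The `1e-6` stabilizer sits
#' only in the denominator of `N_c` and is never trained.
#'
#' @param channels number of channels `C` the layer operates on.
#' @param gamma,beta numeric vectors of length `channels` (recycled from a
#'   scalar); the 2C learnable parameters.
#' @param epsilon stabilizer added to the cross-channel mean; fixed, positive.
#' @return `grn_params()` returns a parameter list; `grn_forward()` the
#'   normalized feature map, same shape as the input.
#' @examples
#' p <- grn_params(2)
#' x <- array(rnorm(1 * 2 * 3 * 3), dim = c(1, 2, 3, 3))
#' stopifnot(identical(grn_forward(x, p), x))  # identity at zero parameters
#' @export
grn_params <- function(channels, gamma = 0, beta = 0, epsilon = 1e-6) {
  stopifnot(channels >= 1, epsilon > 0)
  list(gamma = rep_len(as.double(gamma), channels),
       beta  = rep_len(as.double(beta), channels),
       epsilon = epsilon)
}

#' @rdname grn_params
#' @param x feature map, dim (N, C, H, W).
#' @param params a `grn_params()` list.
#' @export
grn_forward <- function(x, params) grn_fwd(x, params)$y

grn_fwd <- function(x, params) {
  x <- as_feature_map(x)
  C <- dim(x)[2]
  if (length(params$gamma) != C || length(params$beta) != C)
    stop(sprintf("GRN channel mismatch: input has %d channels, parameters have %d",
                 C, length(params$gamma)))
  res <- grn_fwd_cpp(x, params$gamma, params$beta, params$epsilon)
  list(y = res$y,
       cache = list(x = x, G = res$G, mn = res$mn, Nx = res$Nx))
}

grn_bwd <- function(params, cache, gy) {
  res <- grn_bwd_cpp(cache$x, gy, params$gamma, cache$G, cache$mn, cache$Nx,
                     params$epsilon)
  list(gx = res$gx, gamma = res$gamma, beta = res$beta)
}
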