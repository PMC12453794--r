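# Loop-based reference implementations of the layer equations, kept naive on
# purpose: they are the independent oracles the vectorized/C++ paths are
# checked against.

rand_fm <- function(n, c, h, w, sd = 1) {
  array(rnorm(n * c * h * w, sd = sd), dim = c(n, c, h, w))
}

naive_conv <- function(x, w, b, stride = 1, pad = 0, groups = 1) {
  d <- dim(x); N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  wd <- dim(w); OC <- wd[1]; ICg <- wd[2]; KH <- wd[3]; KW <- wd[4]
  OCg <- OC / groups
  OH <- (H + 2 * pad - KH) %/% stride + 1
  OW <- (W + 2 * pad - KW) %/% stride + 1
  y <- array(0, c(N, OC, OH, OW))
  for (n in 1:N) for (oc in 1:OC) {
    g <- (oc - 1) %/% OCg
    for (oh in 1:OH) for (ow in 1:OW) {
      acc <- if (is.null(b)) 0 else b[oc]
      for (ic in 1:ICg) for (kh in 1:KH) for (kw in 1:KW) {
        hh <- (oh - 1) * stride - pad + kh
        wp <- (ow - 1) * stride - pad + kw
        if (hh >= 1 && hh <= H && wp >= 1 && wp <= W)
          acc <- acc + x[n, g * ICg + ic, hh, wp] * w[oc, ic, kh, kw]
      }
      y[n, oc, oh, ow] <- acc
    }
  }
  y
}

# G_c = sqrt(sum_spatial x^2); N_c = G_c / (mean_c G + eps); y = g*(x*N) + b + x
naive_grn <- function(x, gamma, beta, eps = 1e-6) {
  d <- dim(x); y <- array(0, d)
  for (n in 1:d[1]) {
    G <- sapply(1:d[2], function(c) sqrt(sum(x[n, c, , ]^2)))
    Nx <- G / (mean(G) + eps)
    for (c in 1:d[2])
      y[n, c, , ] <- gamma[c] * (x[n, c, , ] * Nx[c]) + beta[c] + x[n, c, , ]
  }
  y
}

naive_channel_attention <- function(x, w1, w2) {
  d <- dim(x); y <- array(0, d)
  sig <- function(z) 1 / (1 + exp(-z))
  for (n in 1:d[1]) {
    avg <- sapply(1:d[2], function(c) mean(x[n, c, , ]))
    mx <- sapply(1:d[2], function(c) max(x[n, c, , ]))
    mlp <- function(v) as.vector(w2 %*% pmax(w1 %*% v, 0))
    z <- mlp(avg) + mlp(mx)
    for (c in 1:d[2]) y[n, c, , ] <- x[n, c, , ] * sig(z[c])
  }
  y
}

naive_spatial_attention <- function(x, kernel) {
  d <- dim(x); k <- dim(kernel)[3]; pad <- (k - 1) / 2
  sig <- function(z) 1 / (1 + exp(-z))
  y <- array(0, d)
  for (n in 1:d[1]) {
    avg <- apply(x[n, , , , drop = FALSE], c(3, 4), mean)
    mx <- apply(x[n, , , , drop = FALSE], c(3, 4), max)
    xcat <- array(0, c(1, 2, d[3], d[4]))
    xcat[1, 1, , ] <- avg; xcat[1, 2, , ] <- mx
    s <- naive_conv(xcat, kernel, NULL, 1, pad, 1)
    gate <- sig(s[1, 1, , ])
    for (c in 1:d[2]) y[n, c, , ] <- x[n, c, , ] * gate
  }
  y
}

exact_gelu <- function(x) x * pnorm(x)

naive_gge <- function(x, p) {
  C <- dim(x)[2]
  t1 <- naive_conv(x, p$dw_w, p$dw_b, 1, 1, groups = C)
  t2 <- naive_grn(t1, p$grn$gamma, p$grn$beta, p$grn$epsilon)
  a <- exact_gelu(t2)
  t4 <- naive_conv(a, p$pw_w, p$pw_b, 1, 0, 1)
  exact_gelu(x + t4)
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(b)))
}

# Small randomly-weighted parameter sets for the oracle comparisons
rand_gge_params <- function(C) {
  p <- gge_conv_params(C, init = "random")
  p$grn$gamma <- rnorm(C, sd = 0.3)
  p$grn$beta <- rnorm(C, sd = 0.3)
  p$dw_b <- rnorm(C, sd = 0.1)
  p$pw_b <- rnorm(C, sd = 0.1)
  p
}

# Central-difference numeric gradient of f at v
num_grad <- function(f, v, eps = 1e-5) {
  g <- v
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- v[i] + eps
    vm <- v; vm[i] <- v[i] - eps
    g[i] <- (f(vp) - f(vm)) / (2 * eps)
  }
  g
}

# Tiny deterministic image batch for optimization smoke tests (not files)
toy_batch <- function(n = 8, size = 64, seed = 1) {
  set.seed(seed)
  x <- rand_fm(n, 3, size, size, sd = 0.5)
  y <- rep_len(1:4, n)
  # give each class a distinct channel-mean signature so it is learnable
  for (i in seq_len(n)) x[i, (y[i] - 1) %% 3 + 1, , ] <-
      x[i, (y[i] - 1) %% 3 + 1, , ] + 0.5 * y[i]
  list(x = x, y = y)
}

toy_spec <- function(base_width = 2, n_classes = 4, input_size = 64)
  ggenet_spec(base_width, n_classes, attention_r = 2, spatial_k = 3,
              input_size = input_size)
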