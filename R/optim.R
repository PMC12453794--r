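# Adam over arbitrarily nested lists of numeric arrays. Parameters, gradients
# and moment estimates share one nesting structure; non-trainable fields
# (epsilon, r, k) are skipped wherever they appear.

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) return(lapply(p, zero_like))
    if (is.numeric(p)) { p[] <- 0; p } else p
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        nm <- if (is.null(nms)) "" else nms[i]
        if (nm %in% c("epsilon", "r", "k")) next
        if (!is.numeric(p[[i]]) && !is.list(p[[i]])) next
        gi <- if (nzchar(nm)) g[[nm]] else g[[i]]
        if (is.null(gi)) next
        res <- walk(p[[i]], gi, m[[i]], v[[i]])
        p[[i]] <- res$p; m[[i]] <- res$m; v[[i]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

# Convenience: one Adam step over a whole network's layer list.
adam_step_net <- function(net, grads, state, lr = 1e-3) {
  for (i in seq_along(net$layers)) {
    res <- adam_step(net$layers[[i]]$params, grads[[i]],
                     list(m = state$m[[i]], v = state$v[[i]], t = state$t), lr = lr)
    net$layers[[i]]$params <- res$params
    state$m[[i]] <- res$state$m
    state$v[[i]] <- res$state$v
  }
  state$t <- state$t + 1L
  list(net = net, state = state)
}

adam_init_net <- function(net) {
  list(m = lapply(net$layers, function(l) adam_init(l$params)$m),
       v = lapply(net$layers, function(l) adam_init(l$params)$v),
       t = 0L)
}
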