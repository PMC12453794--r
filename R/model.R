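#' GGENet model specification and construction
#'
#' A GGENet is assembled from a fixed stage plan shared by teacher and
#' student; only the base width differs (32 for GGENet-T, 16 for GGENet-S).
#' After a stride-2 stem to `base_width` channels the plan is: 2 GRN-GELU
#' modules, downsample, attention, 2 modules, downsample, 2 modules,
#' downsample, attention, 3 modules, downsample, 3 modules, downsample,
#' attention, 3 modules, then global average pooling and a biased linear
#' classifier. Each downsample doubles the channels, so the width sequence is
#' `base_width * c(1, 2, 4, 8, 16, 32)` and the three attention modules sit at
#' widths `base_width * c(2, 8, 32)` — their outputs are the attention maps
#' used for distillation.
#'
#' @param base_width channels after the stem (32 = teacher, 16 = student).
#' @param n_classes number of output classes.
#' @param attention_r reduction ratio of channel attention; must divide all
#'   three attention widths.
#' @param spatial_k spatial-attention kernel size (odd).
#' @param input_size nominal square input size in pixels; inputs must survive
#'   the stem and five downsamples (so at least 64 is practical).
#' @return `ggenet_spec()` returns a specification object; `build_ggenet()` a
#'   `ggenet_network` with initialized parameters.
#' @examples
#' net <- build_ggenet(ggenet_spec(base_width = 2, attention_r = 2,
#'                                 input_size = 64), seed = 1)
#' count_parameters(net)
#' @export
ggenet_spec <- function(base_width = 32, n_classes = 6, attention_r = 16,
                        spatial_k = 7, input_size = 224) {
  stopifnot(base_width >= 1, n_classes >= 2, spatial_k %% 2 == 1)
  att_widths <- base_width * c(2, 8, 32)
  bad <- att_widths[att_widths %% attention_r != 0]
  if (length(bad))
    stop(sprintf("attention_r = %d does not divide attention width(s) %s",
                 attention_r, paste(bad, collapse = ", ")))
  structure(list(base_width = as.integer(base_width),
                 n_classes = as.integer(n_classes),
                 attention_r = as.integer(attention_r),
                 spatial_k = as.integer(spatial_k),
                 input_size = as.integer(input_size)),
            class = "ggenet_spec")
}

# The fixed stage plan: one row per layer after the stem.
ggenet_plan <- function(base_width) {
  w <- base_width
  list(
    list(type = "gge",  c = w),      list(type = "gge",  c = w),
    list(type = "down", c = w),
    list(type = "cbam", c = 2 * w, capture = 1L),
    list(type = "gge",  c = 2 * w),  list(type = "gge",  c = 2 * w),
    list(type = "down", c = 2 * w),
    list(type = "gge",  c = 4 * w),  list(type = "gge",  c = 4 * w),
    list(type = "down", c = 4 * w),
    list(type = "cbam", c = 8 * w, capture = 2L),
    list(type = "gge",  c = 8 * w),  list(type = "gge",  c = 8 * w),
    list(type = "gge",  c = 8 * w),
    list(type = "down", c = 8 * w),
    list(type = "gge",  c = 16 * w), list(type = "gge",  c = 16 * w),
    list(type = "gge",  c = 16 * w),
    list(type = "down", c = 16 * w),
    list(type = "cbam", c = 32 * w, capture = 3L),
    list(type = "gge",  c = 32 * w), list(type = "gge",  c = 32 * w),
    list(type = "gge",  c = 32 * w)
  )
}

#' @rdname ggenet_spec
#' @param spec a `ggenet_spec` object.
#' @param init `"random"` (truncated normal, sd 0.02, zero biases and GRN) or
#'   `"zeros"`.
#' @param seed optional integer seed for the weight draw.
#' @export
build_ggenet <- function(spec, init = "random", seed = NULL) {
  stopifnot(inherits(spec, "ggenet_spec"))
  if (!is.null(seed)) set.seed(seed)
  layers <- list(list(type = "stem", params = stem_params(spec$base_width, init)))
  for (entry in ggenet_plan(spec$base_width)) {
    params <- switch(entry$type,
      gge  = gge_conv_params(entry$c, init),
      down = downsample_params(entry$c, init),
      cbam = list(ca = channel_attention_params(entry$c, spec$attention_r, init),
                  sa = spatial_attention_params(spec$spatial_k, init)))
    layers[[length(layers) + 1L]] <-
      c(list(type = entry$type, params = params),
        if (!is.null(entry$capture)) list(capture = entry$capture))
  }
  layers[[length(layers) + 1L]] <-
    list(type = "head", params = head_params(32L * spec$base_width,
                                             spec$n_classes, init))
  structure(list(spec = spec, layers = layers), class = "ggenet_network")
}

layer_fwd <- function(layer, x) {
  switch(layer$type,
    stem = stem_fwd(x, layer$params),
    gge  = gge_fwd(x, layer$params),
    down = down_fwd(x, layer$params),
    cbam = cbam_fwd(x, layer$params),
    head = head_fwd(x, layer$params))
}

layer_bwd <- function(layer, cache, gy) {
  switch(layer$type,
    stem = stem_bwd(layer$params, cache, gy),
    gge  = gge_bwd(layer$params, cache, gy),
    down = down_bwd(layer$params, cache, gy),
    cbam = cbam_bwd(layer$params, cache, gy),
    head = head_bwd(layer$params, cache, gy))
}

#' Run a GGENet forward, optionally capturing attention maps
#'
#' `ggenet_forward()` returns the class logits; `forward_with_attention()`
#' additionally returns the outputs of the three attention modules
#' (shallow to deep), which are the maps transferred during distillation.
#' Capturing is pure plumbing: the logits are bit-identical either way.
#'
#' @param net a `ggenet_network`.
#' @param x feature map, dim (N, 3, H, W).
#' @param want_cache keep per-layer caches for backpropagation (internal).
#' @return `ggenet_forward()`: an N x n_classes logit matrix.
#'   `forward_with_attention()`: list with `logits` and `maps` (list of 3).
#' @export
ggenet_forward <- function(net, x, want_cache = FALSE) {
  out <- net_fwd(net, x, want_cache)
  if (want_cache) out else out$logits
}

#' @rdname ggenet_forward
#' @export
forward_with_attention <- function(net, x) {
  out <- net_fwd(net, x, want_cache = FALSE)
  list(logits = out$logits, maps = out$maps)
}

net_fwd <- function(net, x, want_cache = FALSE) {
  maps <- vector("list", 3L)
  caches <- if (want_cache) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    layer <- net$layers[[i]]
    res <- layer_fwd(layer, x)
    x <- res$y
    if (want_cache) caches[[i]] <- res$cache
    if (!is.null(layer$capture)) maps[[layer$capture]] <- x
  }
  list(logits = x, maps = maps, caches = caches)
}

# Backward through the whole network. glogits is the gradient at the logits;
# gmaps (optional, list of 3) are extra gradients injected at the captured
# attention-map outputs (used by attention distillation). Returns per-layer
# gradient lists mirroring the parameter structure, plus the input gradient.
net_bwd <- function(net, caches, glogits, gmaps = NULL) {
  n <- length(net$layers)
  grads <- vector("list", n)
  g <- glogits
  for (i in rev(seq_len(n))) {
    layer <- net$layers[[i]]
    if (!is.null(layer$capture) && !is.null(gmaps[[layer$capture]]))
      g <- g + gmaps[[layer$capture]]
    res <- layer_bwd(layer, caches[[i]], g)
    g <- res$gx
    grads[[i]] <- if (is.null(res$grads)) res[setdiff(names(res), "gx")] else res$grads
  }
  list(grads = grads, gx = g)
}

#' Count trainable parameters
#'
#' `count_parameters()` walks the built network and counts every trainable
#' scalar (the GRN stabilizer epsilon and structural integers are excluded).
#' `audit_param_count()` evaluates the closed-form layerwise total for the
#' same recipe: stem `27 C0 + 2 C0`; each GRN-GELU module `C^2 + 13 C`; each
#' downsample `8 C^2 + 2 C`; each attention module `2 C^2 / r + 2 k^2`; head
#' `32 C0 K + K`. The two must agree for every configuration; for the teacher
#' (base width 32, 6 classes, r = 16, k = 7) both give 7,190,092.
#' `adapter_param_count()` gives the parameters of the three biased 1x1
#' distillation adapters between a student and teacher of the given widths.
#'
#' @param net a `ggenet_network`.
#' @return integer-valued numeric count.
#' @examples
#' audit_param_count(32)   # 7190092, the published teacher size
#' @export
count_parameters <- function(net) {
  count_rec <- function(p) {
    if (is.list(p)) {
      keep <- setdiff(names(p), c("epsilon", "r", "k"))
      return(sum(vapply(p[keep], count_rec, numeric(1))))
    }
    if (is.numeric(p)) length(p) else 0
  }
  sum(vapply(net$layers, function(l) count_rec(l$params), numeric(1)))
}

#' @rdname count_parameters
#' @param base_width,n_classes,attention_r,spatial_k as in [ggenet_spec()].
#' @export
audit_param_count <- function(base_width, n_classes = 6, attention_r = 16,
                              spatial_k = 7) {
  w <- base_width; r <- attention_r; k <- spatial_k
  module <- function(C) C^2 + 13 * C
  down <- function(C) 8 * C^2 + 2 * C
  cbam <- function(C) 2 * C^2 / r + 2 * k^2
  stem <- 27 * w + 2 * w
  counts <- c(stem,
              2 * module(w), down(w),
              cbam(2 * w), 2 * module(2 * w), down(2 * w),
              2 * module(4 * w), down(4 * w),
              cbam(8 * w), 3 * module(8 * w), down(8 * w),
              3 * module(16 * w), down(16 * w),
              cbam(32 * w), 3 * module(32 * w),
              32 * w * n_classes + n_classes)
  sum(counts)
}

#' @rdname count_parameters
#' @param student_width,teacher_width base widths of the two networks.
#' @export
adapter_param_count <- function(student_width, teacher_width) {
  cs <- student_width * c(2, 8, 32)
  ct <- teacher_width * c(2, 8, 32)
  sum(ct * cs + ct)
}

#' @export
print.ggenet_spec <- function(x, ...) {
  cat(sprintf(
    "GGENet spec: base width %d (widths %s), %d classes, r = %d, k = %d, input %dpx\n",
    x$base_width, paste(x$base_width * c(1, 2, 4, 8, 16, 32), collapse = "/"),
    x$n_classes, x$attention_r, x$spatial_k, x$input_size))
  invisible(x)
}

#' @export
print.ggenet_network <- function(x, ...) {
  print(x$spec)
  cat(sprintf("%d layers, %s trainable parameters\n", length(x$layers),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
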