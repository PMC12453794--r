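# Expected per-layer output channels for the fixed stage plan at base width w
plan_channels <- function(w)
  c(w,                     # stem
    w, w, 2 * w,           # 2 modules + downsample
    2 * w,                 # attention
    2 * w, 2 * w, 4 * w,   # 2 modules + downsample
    4 * w, 4 * w, 8 * w,   # 2 modules + downsample
    8 * w,                 # attention
    8 * w, 8 * w, 8 * w, 16 * w,
    16 * w, 16 * w, 16 * w, 32 * w,
    32 * w,                # attention
    32 * w, 32 * w, 32 * w)

# Spatial sizes for a 224 input: stem to 112, five downsamples to 3
plan_sizes_224 <- c(112, 112, 112, 56, 56, 56, 56, 28, 28, 28, 14, 14,
                    14, 14, 14, 7, 7, 7, 7, 3, 3, 3, 3, 3)

layer_shapes <- function(net, x) {
  shapes <- list()
  for (i in seq_along(net$layers)) {
    x <- ggenet:::layer_fwd(net$layers[[i]], x)$y
    shapes[[i]] <- dim(x)
  }
  shapes
}

test_that("spec validates the attention reduction ratio", {
  expect_s3_class(ggenet_spec(16), "ggenet_spec")
  expect_error(ggenet_spec(2, attention_r = 16), "does not divide")
  expect_error(ggenet_spec(4, attention_r = 16), "does not divide")
  expect_s3_class(ggenet_spec(4, attention_r = 8), "ggenet_spec")
})

test_that("teacher and student reproduce every tabulated layer shape", {
  for (cfg in list(list(w = 32L, r = 16), list(w = 16L, r = 16))) {
    net <- build_ggenet(ggenet_spec(cfg$w, attention_r = cfg$r), init = "zeros")
    shp <- layer_shapes(net, array(0, c(1, 3, 224, 224)))
    chans <- vapply(shp[1:24], `[`, integer(1), 2)
    sizes <- vapply(shp[1:24], `[`, integer(1), 3)
    expect_identical(chans, as.integer(plan_channels(cfg$w)))
    expect_identical(sizes, as.integer(plan_sizes_224))
    expect_identical(shp[[25]], c(1L, 6L))   # classifier logits
  }
})

test_that("toy configurations build and run end to end", {
  net <- build_ggenet(toy_spec(2), seed = 1)
  logits <- ggenet_forward(net, rand_fm(2, 3, 64, 64))
  expect_identical(dim(logits), c(2L, 4L))
  expect_true(all(is.finite(logits)))
})

test_that("attention-map capture is pure plumbing", {
  set.seed(2)
  net <- build_ggenet(toy_spec(2), seed = 3)
  x <- rand_fm(2, 3, 64, 64)
  plain <- ggenet_forward(net, x)
  cap <- forward_with_attention(net, x)
  expect_identical(cap$logits, plain)
  expect_length(cap$maps, 3)
  # widths 2w, 8w, 32w at spatial 16, 4, 1 for a 64px input
  expect_identical(lapply(cap$maps, dim),
                   list(c(2L, 4L, 16L, 16L), c(2L, 16L, 4L, 4L), c(2L, 64L, 1L, 1L)))
})

test_that("teacher and student maps share spatial dims at a 2x channel ratio", {
  tmap <- forward_with_attention(build_ggenet(toy_spec(4), seed = 1),
                                 rand_fm(1, 3, 64, 64))$maps
  smap <- forward_with_attention(build_ggenet(toy_spec(2), seed = 1),
                                 rand_fm(1, 3, 64, 64))$maps
  for (i in 1:3) {
    expect_identical(dim(tmap[[i]])[3:4], dim(smap[[i]])[3:4])
    expect_identical(dim(tmap[[i]])[2], 2L * dim(smap[[i]])[2])
  }
})

test_that("parameter counter equals the closed-form audit across widths", {
  cfgs <- list(c(2, 2), c(4, 4), c(16, 16), c(32, 16))
  for (cfg in cfgs) {
    spec <- ggenet_spec(cfg[1], attention_r = cfg[2])
    net <- build_ggenet(spec, init = "zeros")
    expect_identical(count_parameters(net),
                     audit_param_count(cfg[1], attention_r = cfg[2]))
  }
  # quadratic terms dominate: doubling the width roughly quadruples the count
  ratio <- audit_param_count(32) / audit_param_count(16)
  expect_gt(ratio, 3.5); expect_lt(ratio, 4.5)
})

test_that("forward passes are deterministic given the weights", {
  net <- build_ggenet(toy_spec(2), seed = 9)
  x <- rand_fm(2, 3, 64, 64)
  expect_identical(ggenet_forward(net, x), ggenet_forward(net, x))
})

test_that("too-small inputs fail before the collapsing stage", {
  net <- build_ggenet(toy_spec(2, input_size = 16), init = "zeros")
  expect_error(ggenet_forward(net, array(0, c(1, 3, 16, 16))), "at least 2")
})
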