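# Training smoke tests run at toy widths on a small deterministic synthetic
# set so the whole file stays in the tens of seconds.

fit_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "ggenet-fit-fixture")
      idx <- generate_synthetic(synthetic_spec(n_per_class = 12, seed = 77), dir)
      cache <<- load_images(idx, size = 64)
    }
    cache
  }
})

test_that("supervised training fits the easy synthetic set", {
  dir <- file.path(tempdir(), "ggenet-easy-fixture")
  idx <- generate_synthetic(synthetic_spec(n_per_class = 50, difficulty = 0.1,
                                           seed = 77), dir)
  dat <- load_images(idx, size = 64)
  spec <- ggenet_spec(4, 6, attention_r = 2, input_size = 64)
  fit <- ggenet_fit(dat$x, dat$y, spec, epochs = 15, seed = 4,
                    classes = dat$classes)
  expect_s3_class(fit, "ggenet_fit")
  h <- fit$history
  expect_true(all(is.finite(h$train_loss)))
  expect_gt(h$train_acc[nrow(h)], 0.95)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # prediction surface
  probs <- predict(fit, dat$x[1:4, , , , drop = FALSE])
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-12)
  cls <- predict(fit, dat$x[1:4, , , , drop = FALSE], type = "class")
  expect_s3_class(cls, "factor")
  expect_identical(levels(cls), dat$classes)
})

test_that("training histories are reproducible under a fixed seed", {
  dat <- fit_fixture()
  spec <- ggenet_spec(2, 6, attention_r = 2, input_size = 64)
  f1 <- ggenet_fit(dat$x, dat$y, spec, epochs = 2, seed = 11)
  f2 <- ggenet_fit(dat$x, dat$y, spec, epochs = 2, seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network, f2$network)
  f3 <- ggenet_fit(dat$x, dat$y, spec, epochs = 2, seed = 12)
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("validation carve-out drives best-checkpoint selection", {
  dat <- fit_fixture()
  spec <- ggenet_spec(2, 6, attention_r = 2, input_size = 64)
  val <- seq(1, 72, by = 6)
  fit <- ggenet_fit(dat$x, dat$y, spec, epochs = 4, seed = 5, val = val)
  expect_true(all(is.finite(fit$history$val_acc)))
  best_ep <- which.max(fit$history$val_acc)
  expect_gte(max(fit$history$val_acc), fit$history$val_acc[1])
  expect_error(ggenet_fit(dat$x[0, , , , drop = FALSE], integer(), spec),
               "empty|length")
})

test_that("evaluation ties the fitted model to the metric suite", {
  dat <- fit_fixture()
  spec <- ggenet_spec(2, 6, attention_r = 2, input_size = 64)
  fit <- ggenet_fit(dat$x, dat$y, spec, epochs = 10, seed = 6)
  ev <- evaluate(fit, dat$x, dat$y)
  expect_identical(dim(ev$confusion), c(6L, 6L))
  expect_identical(sum(ev$confusion), length(dat$y))
  expect_equal(as.vector(rowSums(ev$confusion)),
               as.vector(table(dat$y)), ignore_attr = TRUE)
  expect_equal(ev$metrics$recall, ev$metrics$accuracy, tolerance = 1e-12)
  expect_true(ev$metrics$auc >= 0 && ev$metrics$auc <= 1)
})

test_that("checkpoints round-trip with a JSON sidecar", {
  dat <- fit_fixture()
  spec <- ggenet_spec(2, 6, attention_r = 2, input_size = 64)
  fit <- ggenet_fit(dat$x, dat$y, spec, epochs = 1, seed = 7)
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_checkpoint(fit, path)
  expect_true(file.exists(path))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$spec$base_width, 2L)
  expect_equal(side$parameters, count_parameters(fit$network))
  back <- load_checkpoint(path)
  expect_identical(predict(back, dat$x[1:2, , , , drop = FALSE]),
                   predict(fit, dat$x[1:2, , , , drop = FALSE]))
  expect_error(load_checkpoint(file.path(tempdir(), "nope.rds")), "not found")
})

test_that("the distillation driver logs an internally consistent breakdown", {
  dat <- fit_fixture()
  tspec <- ggenet_spec(4, 6, attention_r = 4, input_size = 64)
  sspec <- ggenet_spec(2, 6, attention_r = 2, input_size = 64)
  tfit <- ggenet_fit(dat$x, dat$y, tspec, epochs = 5, seed = 8)
  before <- tfit$network
  dfit <- ggenet_distill(tfit, sspec, dat$x, dat$y, epochs = 3, seed = 9)
  expect_s3_class(dfit, "ggenet_distill_fit")
  expect_identical(tfit$network, before)       # teacher frozen bit-for-bit
  bd <- dfit$breakdown
  expect_true(all(bd$weight_hidden >= 0.25 & bd$weight_hidden <= 0.75))
  expect_equal(bd$weight_hidden,
               mapply(hidden_weight, bd$loss_hidden, bd$loss_ce))
  expect_equal(bd$loss_total,
               bd$weight_hidden * bd$loss_hidden +
                 (1 - bd$weight_hidden) * bd$loss_ce)
  # logit mode records the alpha algebra instead
  lfit <- ggenet_distill(tfit, sspec, dat$x, dat$y, mode = "logit",
                         epochs = 1, seed = 10)
  lb <- lfit$breakdown
  expect_equal(lb$alpha, mapply(adaptive_alpha, lb$loss_ce, lb$loss_distill))
})
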