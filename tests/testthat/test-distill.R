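test_that("soft targets behave like a tempered softmax", {
  expect_equal(soft_targets(c(1, 1, 1), tau = 3), rep(1 / 3, 3))
  p <- soft_targets(c(2, 0), tau = 2)
  expect_equal(p, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  flat <- soft_targets(c(5, -3, 1), tau = 1e6)
  expect_lt(max(flat) - min(flat), 1e-3)
  expect_error(soft_targets(c(1, 2), tau = 0), "positive")
  # matrix input: one distribution per row
  m <- soft_targets(rbind(c(2, 0), c(0, 0)), tau = 2)
  expect_equal(rowSums(m), c(1, 1))
})

test_that("the adaptive weight follows the loss-ratio closed form", {
  expect_equal(adaptive_alpha(1, 1), 0.5)
  expect_equal(adaptive_alpha(3, 1), 0.75)
  expect_equal(adaptive_alpha(1, 0), 1.0)
  expect_equal(adaptive_alpha(0, 0), 0.5)        # documented degenerate case
  expect_error(adaptive_alpha(-1, 1), "non-negative")
  # strictly decreasing in the distillation loss
  a <- sapply(c(0.1, 0.5, 1, 5), function(d) adaptive_alpha(2, d))
  expect_true(all(diff(a) < 0))
})

test_that("the adaptive total equals the harmonic-mean identity", {
  expect_equal(logit_kd_total(3, 1), 1.5)
  expect_equal(logit_kd_total(7, 7), 7)
  expect_equal(logit_kd_total(1, 0), 0)
  set.seed(1)
  for (i in 1:50) {
    a <- runif(1, 0, 10); b <- runif(1, 0, 10)
    expect_equal(logit_kd_total(a, b), 2 * a * b / (a + b), tolerance = 1e-12)
  }
  expect_equal(logit_kd_total(2, 10, alpha = 0.25), 0.75 * 2 + 0.25 * 10)
})

test_that("the hidden weight is the clamped ratio", {
  expect_equal(hidden_weight(1, 1), 0.5)
  expect_equal(hidden_weight(9, 1), 0.75)
  expect_equal(hidden_weight(0.01, 0.99), 0.25)
  expect_equal(hidden_weight(0, 0), 0.5)
  expect_equal(attention_kd_total(9, 1), 0.75 * 9 + 0.25 * 1)
  expect_equal(attention_kd_total(5, 5), 5)
  set.seed(2)
  for (i in 1:100) {
    lh <- rexp(1); lc <- rexp(1)
    w <- hidden_weight(lh, lc)
    expect_gte(w, 0.25); expect_lte(w, 0.75)
    tot <- attention_kd_total(lh, lc)
    expect_gte(tot, min(lh, lc) - 1e-12)
    expect_lte(tot, max(lh, lc) + 1e-12)
  }
})

test_that("adapters project the channel gap and the hidden loss averages MSEs", {
  sspec <- toy_spec(2); tspec <- toy_spec(4)
  ad <- adapter_bank(sspec, tspec, seed = 1)
  expect_identical(vapply(ad, function(a) dim(a$w)[1:2], integer(2)),
                   matrix(c(8L, 4L, 32L, 16L, 128L, 64L), 2))
  smaps <- forward_with_attention(build_ggenet(sspec, seed = 2),
                                  rand_fm(2, 3, 64, 64))$maps
  tmaps <- forward_with_attention(build_ggenet(tspec, seed = 3),
                                  rand_fm(2, 3, 64, 64))$maps
  # matching maps through identity adapters give zero loss
  adI <- adapter_bank(tspec, tspec, init = "identity")
  expect_equal(hidden_loss(tmaps, tmaps, adI), 0)
  # constant offset d in every adapted map gives d^2
  adO <- adapter_bank(tspec, tspec, init = "identity")
  for (i in 1:3) adO[[i]]$b <- adO[[i]]$b + 0.3
  expect_equal(hidden_loss(tmaps, tmaps, adO), 0.09, tolerance = 1e-12)
  # mean of the per-map MSEs, cross-checked elementwise
  hl <- ggenet:::hidden_loss_grad(smaps, tmaps, ad)
  man <- sapply(1:3, function(i) {
    proj <- ggenet:::conv2d(smaps[[i]], ad[[i]]$w, ad[[i]]$b)
    mean((proj - tmaps[[i]])^2)
  })
  expect_equal(hl$loss, mean(man), tolerance = 1e-12)
  expect_equal(hl$mses, man, tolerance = 1e-12)
  # shape mismatch after adaptation is an explicit error
  expect_error(hidden_loss(tmaps, smaps, ad), "shape")
})

test_that("temperature-scaled KL distillation has the analytic gradient", {
  set.seed(3)
  zs <- matrix(rnorm(8), 2, 4); zt <- matrix(rnorm(8), 2, 4)
  kd <- ggenet:::kl_distill(zs, zt, tau = 4)
  expect_gte(kd$loss, 0)
  expect_equal(ggenet:::kl_distill(zt, zt, 4)$loss, 0, tolerance = 1e-12)
  gn <- num_grad(function(v) ggenet:::kl_distill(matrix(v, 2, 4), zt, 4)$loss,
                 as.vector(zs))
  expect_equal(as.vector(kd$glogits), gn, tolerance = 1e-6)
})

test_that("a distill step trains only the student and adapters", {
  set.seed(4)
  b <- toy_batch(n = 6)
  teacher <- build_ggenet(toy_spec(4), seed = 5)
  student <- build_ggenet(toy_spec(2), seed = 6)
  adapters <- adapter_bank(toy_spec(2), toy_spec(4), seed = 7)
  opt <- ggenet:::distill_opt_init(student, adapters)
  tbefore <- teacher
  st <- distill_step(teacher, student, adapters, b$x, b$y, opt)
  expect_identical(teacher, tbefore)                 # teacher untouched
  expect_false(identical(st$student, student))       # student updated
  expect_false(identical(st$adapters, adapters))     # adapters updated
  bd <- st$breakdown
  expect_equal(bd$weight_hidden, hidden_weight(bd$loss_hidden, bd$loss_ce))
  expect_equal(bd$loss_total,
               bd$weight_hidden * bd$loss_hidden +
                 (1 - bd$weight_hidden) * bd$loss_ce)
})

test_that("matched width-equal pairs engage the lower clamp", {
  set.seed(5)
  b <- toy_batch(n = 4)
  net <- build_ggenet(toy_spec(2), seed = 8)
  adapters <- adapter_bank(toy_spec(2), toy_spec(2), init = "identity")
  opt <- ggenet:::distill_opt_init(net, adapters)
  st <- distill_step(net, net, adapters, b$x, b$y, opt)
  expect_equal(st$breakdown$loss_hidden, 0)
  expect_equal(st$breakdown$weight_hidden, 0.25)
})

test_that("the total loss falls over 50 steps on a fixed batch", {
  set.seed(6)
  b <- toy_batch(n = 8, seed = 42)
  teacher <- build_ggenet(toy_spec(4), seed = 9)
  student <- build_ggenet(toy_spec(2), seed = 10)
  adapters <- adapter_bank(toy_spec(2), toy_spec(4), seed = 11)
  opt <- ggenet:::distill_opt_init(student, adapters)
  first <- NULL; last <- NULL
  for (i in 1:50) {
    st <- distill_step(teacher, student, adapters, b$x, b$y, opt)
    student <- st$student; adapters <- st$adapters; opt <- st$opt
    if (i == 1) first <- st$breakdown$loss_total
    last <- st$breakdown$loss_total
  }
  expect_lt(last, first)
  expect_lt(st$breakdown$loss_ce, 0.5)   # memorizes the tiny batch
})

test_that("logit mode follows Algorithm 2's loss combination", {
  set.seed(7)
  b <- toy_batch(n = 4)
  teacher <- build_ggenet(toy_spec(4), seed = 12)
  student <- build_ggenet(toy_spec(2), seed = 13)
  opt <- ggenet:::distill_opt_init(student)
  st <- distill_step(teacher, student, NULL, b$x, b$y, opt, mode = "logit",
                     tau = 4)
  bd <- st$breakdown
  expect_equal(bd$alpha, adaptive_alpha(bd$loss_ce, bd$loss_distill))
  expect_equal(bd$loss_total,
               (1 - bd$alpha) * bd$loss_ce + bd$alpha * bd$loss_distill)
})
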