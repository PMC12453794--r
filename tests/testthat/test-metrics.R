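test_that("folds partition the data with stratified 72/8/20 arithmetic", {
  y <- rep(c("a", "b"), each = 50)
  folds <- make_folds(y, seed = 1)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f$train_idx, 72)
    expect_length(f$val_idx, 8)
    expect_length(f$test_idx, 20)
    all_idx <- c(f$train_idx, f$val_idx, f$test_idx)
    expect_setequal(all_idx, seq_along(y))
    expect_identical(anyDuplicated(all_idx), 0L)
    # stratification: half of each set from each class
    expect_identical(sum(f$test_idx <= 50), 10L)
    expect_identical(sum(f$val_idx <= 50), 4L)
  }
  expect_identical(make_folds(y, seed = 1), make_folds(y, seed = 1))
  expect_false(identical(make_folds(y, seed = 1), make_folds(y, seed = 2)))
  expect_error(make_folds(c("a", "a", "b"), seed = 1), "at least 5")
})

test_that("preprocessing standardizes with the ImageNet constants", {
  white <- array(1, dim = c(10, 12, 3))
  x <- preprocess(white, size = 8)
  expect_identical(dim(x), c(3L, 8L, 8L))
  expect_equal(unique(round(as.vector(x[1, , ]), 4)), 2.2489)
  expect_equal(unique(round(as.vector(x[2, , ]), 4)), 2.4286)
  expect_equal(unique(round(as.vector(x[3, , ]), 4)), 2.64)
  mean_img <- array(rep(c(0.485, 0.456, 0.406), each = 25), c(5, 5, 3))
  expect_equal(max(abs(preprocess(mean_img, size = 5))), 0, tolerance = 1e-12)
  # any input size lands on the requested square output
  expect_identical(dim(preprocess(array(0.5, c(17, 31, 3)), size = 224)),
                   c(3L, 224L, 224L))
  expect_error(preprocess(array(0, c(4, 4, 2))), "RGB")
})

test_that("metrics reproduce the hand-computed three-class table", {
  truth <- c(1, 1, 2, 2, 3, 3)
  pred <- c(1, 2, 2, 2, 3, 1)
  cm <- confusion_matrix(truth, pred, 3)
  expect_identical(rowSums(cm), c(2, 2, 2))
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 0.6667, tolerance = 1e-4)
  expect_equal(m$precision, 0.7222, tolerance = 1e-4)
  expect_equal(m$recall, 0.6667, tolerance = 1e-4)
  expect_equal(m$f1, 0.6556, tolerance = 1e-4)
})

test_that("perfect predictions score 1 on every metric", {
  y <- rep(1:4, each = 5)
  cm <- confusion_matrix(y, y, 4)
  scores <- diag(4)[y, ]
  scores <- (scores + 0.01) / rowSums(scores + 0.01)
  m <- compute_metrics(cm, scores, y)
  expect_equal(unlist(m), c(accuracy = 1, precision = 1, recall = 1, f1 = 1,
                            auc = 1))
})

test_that("weighted recall equals accuracy and micro-F1 equals accuracy", {
  set.seed(1)
  for (i in 1:20) {
    K <- sample(3:6, 1)
    n <- sample(30:80, 1)
    truth <- sample(K, n, replace = TRUE, prob = runif(K) + 0.2)
    if (length(unique(truth)) < K) truth[seq_len(K)] <- 1:K
    pred <- ifelse(runif(n) < 0.6, truth, sample(K, n, replace = TRUE))
    cm <- confusion_matrix(truth, pred, K)
    m <- compute_metrics(cm)
    expect_equal(m$recall, m$accuracy, tolerance = 1e-12)
    tp <- sum(diag(cm))
    microf1 <- 2 * tp / (2 * tp + (sum(cm) - tp) + (sum(cm) - tp))
    expect_equal(microf1, m$accuracy, tolerance = 1e-12)
  }
})

test_that("the package AUC matches a naive trapezoid oracle", {
  naive_auc <- function(resp, sc) {
    pos <- sc[resp == 1]; neg <- sc[resp == 0]
    cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    mean(cmp)
  }
  set.seed(2)
  for (i in 1:10) {
    n <- 40; K <- 3
    truth <- sample(K, n, replace = TRUE)
    scores <- matrix(rexp(n * K), n, K)
    scores <- scores / rowSums(scores)
    m <- compute_metrics(confusion_matrix(truth, max.col(scores), K),
                         scores, truth)
    w <- as.vector(table(factor(truth, levels = 1:K))) / n
    ref <- sum(sapply(1:K, function(k)
      naive_auc(as.integer(truth == k), scores[, k])) * w)
    expect_equal(m$auc, ref, tolerance = 1e-10)
  }
})

test_that("a class absent from truth is excluded with a warning", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), 3)
  expect_warning(m <- compute_metrics(cm), "excluded")
  expect_equal(m$recall, m$accuracy, tolerance = 1e-12)
})

test_that("fold reports append a cross-fold average row per model", {
  fm <- data.frame(accuracy = c(0.9, 0.8), precision = c(0.9, 0.8),
                   recall = c(0.9, 0.8), f1 = c(0.9, 0.8), auc = c(1, 0.9))
  rep <- fold_report(list(teacher = fm, student = fm))
  expect_identical(nrow(rep), 6L)
  expect_identical(rep$fold[c(3, 6)], c("Average", "Average"))
  expect_equal(rep$accuracy[3], 0.85)
})
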