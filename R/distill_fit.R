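#' Distill a teacher GGENet into a student
#'
#' Trains a student network under a frozen, pre-trained teacher. In
#' `"attention"` mode (the headline procedure) the three student attention
#' maps are projected through trained 1x1 adapters and matched to the
#' teacher's maps by mean-squared error; the hidden loss and the student's
#' cross-entropy are combined with the clamped dynamic weight. In `"logit"`
#' mode the classical temperature-softened KL distillation with the adaptive
#' alpha weight is used. The teacher's parameters are never updated.
#'
#' @param teacher a fitted [ggenet_fit()] (or a bare `ggenet_network`).
#' @param student_spec [ggenet_spec()] for the student.
#' @param x,y training data as in [ggenet_fit()].
#' @param mode `"attention"` or `"logit"`.
#' @param epochs,lr,batch_size optimizer settings.
#' @param tau temperature for logit mode.
#' @param val optional validation indices (model selection as in
#'   [ggenet_fit()]).
#' @param seed seed for student/adapter initialization and shuffling.
#' @param verbose print per-epoch progress.
#' @return a `ggenet_distill_fit`, which inherits from `ggenet_fit` (the
#'   student is the fitted model) and adds `adapters`, `mode`, and
#'   `breakdown` — the per-step record of cross-entropy, distillation/hidden
#'   loss, dynamic weight, and total loss.
#' @export
ggenet_distill <- function(teacher, student_spec, x, y,
                           mode = c("attention", "logit"), epochs = 20,
                           lr = 1e-3, batch_size = 16, tau = 4, val = NULL,
                           seed = 1, verbose = FALSE) {
  mode <- match.arg(mode)
  tnet <- if (inherits(teacher, "ggenet_fit")) teacher$network else teacher
  if (!inherits(tnet, "ggenet_network")) stop("teacher must be a ggenet_fit or ggenet_network")
  x <- as_feature_map(x)
  classes <- if (is.factor(y)) levels(y) else NULL
  y <- as.integer(if (is.factor(y)) y else y)
  if (tnet$spec$n_classes != student_spec$n_classes)
    stop("teacher and student class counts differ")
  if (!is.null(val)) {
    vx <- x[val, , , , drop = FALSE]; vy <- y[val]
    keep <- setdiff(seq_along(y), val)
    x <- x[keep, , , , drop = FALSE]; y <- y[keep]
  }
  student <- build_ggenet(student_spec, seed = seed)
  adapters <- if (mode == "attention")
    adapter_bank(student_spec, tnet$spec, seed = seed + 1L)
  opt <- distill_opt_init(student, adapters)
  N <- length(y)
  steps <- list(); hist_rows <- vector("list", epochs)
  best_acc <- -Inf; best_student <- student
  for (ep in seq_len(epochs)) {
    set.seed(seed * 10000L + ep)
    ord <- sample(N)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      st <- distill_step(tnet, student, adapters, x[b, , , , drop = FALSE],
                         y[b], opt, mode = mode, tau = tau, lr = lr)
      student <- st$student; adapters <- st$adapters; opt <- st$opt
      steps[[length(steps) + 1L]] <- cbind(epoch = ep, st$breakdown)
    }
    row <- data.frame(epoch = ep, train_loss = NA_real_, train_acc = NA_real_,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val)) {
      vl <- ggenet_forward(student, vx)
      row$val_loss <- cross_entropy(vl, vy)$loss
      row$val_acc <- mean(max.col(vl, ties.method = "first") == vy)
      if (row$val_acc >= best_acc) { best_acc <- row$val_acc; best_student <- student }
    }
    hist_rows[[ep]] <- row
    if (verbose) {
      last <- steps[[length(steps)]]
      message(sprintf("epoch %3d  total %.4f  ce %.4f%s", ep, last$loss_total,
                      last$loss_ce,
                      if (!is.na(row$val_acc)) sprintf("  val %.4f", row$val_acc) else ""))
    }
  }
  if (is.null(val)) best_student <- student
  structure(list(network = best_student, final_network = student,
                 adapters = adapters, mode = mode,
                 breakdown = do.call(rbind, steps),
                 history = do.call(rbind, hist_rows),
                 config = list(epochs = epochs, lr = lr,
                               batch_size = batch_size, tau = tau, seed = seed,
                               mode = mode),
                 spec = student_spec,
                 classes = classes %||% as.character(seq_len(student_spec$n_classes))),
            class = c("ggenet_distill_fit", "ggenet_fit"))
}

#' @export
print.ggenet_distill_fit <- function(x, ...) {
  cat(sprintf("GGENet student distilled in %s mode\n", x$mode))
  print(x$spec)
  bd <- x$breakdown
  cat(sprintf("%d steps; final total loss %.4f (ce %.4f)\n", nrow(bd),
              bd$loss_total[nrow(bd)], bd$loss_ce[nrow(bd)]))
  invisible(x)
}
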