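#' Run the five-fold training and evaluation protocol
#'
#' Executes the full experimental protocol on a class-per-folder dataset:
#' stratified five-fold splitting ([make_folds()]), supervised training of
#' the requested model on each fold ([ggenet_fit()] with best-validation
#' model selection), and test-set evaluation ([evaluate()]). Returns the
#' per-fold metric table plus the cross-fold average, in the layout of the
#' protocol's result tables.
#'
#' @param x,y preprocessed inputs and integer labels (see [load_images()]).
#' @param spec model specification.
#' @param n_folds number of folds (default 5).
#' @param epochs,lr,batch_size training settings.
#' @param seed protocol seed (drives splits, initialization, shuffling).
#' @param verbose print progress.
#' @return list with `metrics` (per-fold data.frame), `fits` (per-fold
#'   models), `confusions` (per-fold matrices), `folds`.
#' @export
run_protocol <- function(x, y, spec, n_folds = 5, epochs = 100, lr = 1e-3,
                         batch_size = 16, seed = 1, verbose = FALSE) {
  folds <- make_folds(y, seed = seed, n_folds = n_folds)
  fits <- list(); mets <- list(); cms <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    tr <- c(fold$train_idx, fold$val_idx)
    fit <- ggenet_fit(x[tr, , , , drop = FALSE], y[tr], spec, epochs = epochs,
                      lr = lr, batch_size = batch_size,
                      val = match(fold$val_idx, tr), seed = seed + f,
                      verbose = verbose)
    ev <- evaluate(fit, x, y, fold$test_idx)
    fits[[f]] <- fit
    mets[[f]] <- ev$metrics
    cms[[f]] <- ev$confusion
    if (verbose) message(sprintf("fold %d: test acc %.4f", f,
                                 ev$metrics$accuracy))
  }
  list(metrics = do.call(rbind, mets), fits = fits, confusions = cms,
       folds = folds)
}
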