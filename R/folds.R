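#' Stratified five-fold experimental splits
#'
#' Builds the evaluation protocol's folds: each fold is an independent seeded
#' stratified 80/20 train/test split, with a further stratified 10% of the
#' training portion carved out as a validation set. (With 20% of the total
#' not being a clean fifth of typical dataset sizes, independent splits — not
#' a rotating partition — are the consistent reading of the protocol.) The
#' same `(seed, fold)` pair always yields the same split.
#'
#' @param labels factor (or coercible) of class labels, one per sample.
#' @param seed integer seed.
#' @param n_folds number of folds (default 5).
#' @return list of `fold_split` lists with `fold_id`, `train_idx`, `val_idx`,
#'   `test_idx`; the three index sets partition `seq_along(labels)`.
#' @examples
#' f <- make_folds(rep(c("a", "b"), each = 50), seed = 1)
#' lengths(f[[1]][c("train_idx", "val_idx", "test_idx")])  # 72 / 8 / 20
#' @export
make_folds <- function(labels, seed = 1, n_folds = 5) {
  labels <- as.factor(labels)
  cnt <- table(labels)
  if (any(cnt < n_folds))
    stop("every class needs at least ", n_folds, " samples; smallest has ",
         min(cnt))
  lapply(seq_len(n_folds), function(f) {
    set.seed(seed * 131L + f)
    tr <- integer(); va <- integer(); te <- integer()
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      idx <- sample(idx)
      n_te <- round(0.2 * length(idx))
      te_i <- idx[seq_len(n_te)]
      rest <- idx[-seq_len(n_te)]
      n_va <- round(0.1 * length(rest))
      va_i <- rest[seq_len(n_va)]
      tr_i <- rest[-seq_len(n_va)]
      tr <- c(tr, tr_i); va <- c(va, va_i); te <- c(te, te_i)
    }
    list(fold_id = f, train_idx = sort(tr), val_idx = sort(va),
         test_idx = sort(te))
  })
}
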