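# Classification and distillation losses, with analytic gradients w.r.t. the
# student logits. Losses are means over the batch, in nats.

log_softmax <- function(z) {
  z <- as.matrix(z)
  m <- apply(z, 1, max)
  zs <- z - m
  zs - log(rowSums(exp(zs)))
}

#' Temperature-softened class probabilities
#'
#' `softmax(logits / tau)`: the soft targets used in logit distillation.
#' Higher temperatures flatten the distribution toward uniform.
#'
#' @param logits numeric vector, or matrix with one row per sample.
#' @param tau temperature, strictly positive.
#' @return probabilities of the same shape; each row sums to 1.
#' @examples
#' soft_targets(c(2, 0), tau = 2)  # c(0.7311, 0.2689)
#' @export
soft_targets <- function(logits, tau = 1) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    stop("temperature tau must be a single positive number")
  vec <- is.null(dim(logits))
  if (vec) logits <- matrix(logits, nrow = 1)
  p <- exp(log_softmax(logits / tau))
  if (vec) drop(p) else p
}

# Cross-entropy from logits against integer labels in 1..K.
cross_entropy <- function(logits, y) {
  N <- nrow(logits)
  ls <- log_softmax(logits)
  idx <- cbind(seq_len(N), y)
  loss <- -mean(ls[idx])
  p <- exp(ls)
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, glogits = g / N)
}

# Temperature-scaled KL distillation: tau^2 * mean_n KL(p_T || p_S) with both
# distributions softened at tau. Gradient is w.r.t. the student logits; the
# teacher is a constant.
kl_distill <- function(student_logits, teacher_logits, tau) {
  N <- nrow(student_logits)
  ls <- log_softmax(student_logits / tau)
  lt <- log_softmax(teacher_logits / tau)
  pt <- exp(lt)
  loss <- tau^2 * sum(pt * (lt - ls)) / N
  ps <- exp(ls)
  g <- tau * (ps - pt) / N
  list(loss = loss, glogits = g)
}

mse_loss <- function(a, b) mean((a - b)^2)
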