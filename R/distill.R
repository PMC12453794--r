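#' Adaptive loss weighting for knowledge distillation
#'
#' In logit distillation the total loss mixes the student's cross-entropy with
#' a distillation term, `loss_total = (1 - alpha) loss_CE + alpha
#' loss_distill`. The adaptive variant recomputes the mixing weight each step
#' from the current loss magnitudes, `alpha = loss_CE / (loss_CE +
#' loss_distill)`, so a noisy teacher (large distillation loss) is trusted
#' less. Substituting the adaptive alpha into the total gives the harmonic
#' mean form `2ab / (a + b)`.
#'
#' In attention distillation the hidden (attention-map) loss is weighted by
#' `weight_hidden = clamp(loss_hidden / (loss_hidden + loss_CE), 0.25, 0.75)`
#' and the cross-entropy by `1 - weight_hidden`; the clamp keeps either term
#' from dominating. When both losses are exactly zero the ratio is undefined
#' and both weights fall back to 0.5.
#'
#' @param loss_ce,loss_distill,loss_hidden non-negative scalar losses.
#' @return a scalar weight or combined loss.
#' @examples
#' adaptive_alpha(3, 1)        # 0.75
#' logit_kd_total(3, 1)        # 1.5 == 2*3*1/(3+1)
#' hidden_weight(9, 1)         # 0.75 (raw 0.9, clamped)
#' attention_kd_total(9, 1)    # 0.75*9 + 0.25*1 = 7
#' @export
adaptive_alpha <- function(loss_ce, loss_distill) {
  check_losses(loss_ce, loss_distill)
  if (loss_ce + loss_distill == 0) return(0.5)
  loss_ce / (loss_ce + loss_distill)
}

#' @rdname adaptive_alpha
#' @param alpha optional fixed weight; by default the adaptive weight is used.
#' @export
logit_kd_total <- function(loss_ce, loss_distill, alpha = NULL) {
  if (is.null(alpha)) alpha <- adaptive_alpha(loss_ce, loss_distill)
  (1 - alpha) * loss_ce + alpha * loss_distill
}

#' @rdname adaptive_alpha
#' @export
hidden_weight <- function(loss_hidden, loss_ce) {
  check_losses(loss_hidden, loss_ce)
  if (loss_hidden + loss_ce == 0) return(0.5)
  max(0.25, min(loss_hidden / (loss_hidden + loss_ce), 0.75))
}

#' @rdname adaptive_alpha
#' @export
attention_kd_total <- function(loss_hidden, loss_ce) {
  w <- hidden_weight(loss_hidden, loss_ce)
  w * loss_hidden + (1 - w) * loss_ce
}

check_losses <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1 || length(b) != 1 ||
      is.na(a) || is.na(b) || a < 0 || b < 0)
    stop("losses must be single non-negative numbers")
  invisible(TRUE)
}

#' Channel adapters between student and teacher attention maps
#'
#' The student's attention maps have half the teacher's channels (same
#' spatial size), so a bank of three biased 1x1 stride-1 convolutions
#' projects each student map up to the teacher's channel count before the
#' map-matching loss is computed. Adapters are trained jointly with the
#' student and discarded at inference.
#'
#' @param student_spec,teacher_spec `ggenet_spec` objects.
#' @param init `"random"` (default), `"zeros"`, or `"identity"` (requires
#'   equal widths; useful in tests).
#' @param seed optional seed for the weight draw.
#' @return an `adapter_bank`: list of three `list(w, b)` 1x1 convolutions.
#' @export
adapter_bank <- function(student_spec, teacher_spec, init = "random",
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cs <- student_spec$base_width * c(2, 8, 32)
  ct <- teacher_spec$base_width * c(2, 8, 32)
  bank <- lapply(1:3, function(i) {
    w <- array(0, dim = c(ct[i], cs[i], 1, 1))
    if (init == "random") w[] <- trunc_normal(length(w), sqrt(2 / cs[i]))
    if (init == "identity") {
      if (cs[i] != ct[i]) stop("identity adapters need equal widths")
      w[cbind(1:ct[i], 1:cs[i], 1, 1)] <- 1
    }
    list(w = w, b = numeric(ct[i]))
  })
  structure(bank, class = "adapter_bank")
}

#' Attention-map (hidden) distillation loss
#'
#' Projects each of the three student attention maps through its 1x1 adapter
#' and averages the three mean-squared errors against the corresponding
#' teacher maps: `loss_hidden = (mse_1 + mse_2 + mse_3) / 3`, each MSE taken
#' over all tensor elements.
#'
#' @param student_maps,teacher_maps lists of three feature maps (shallow to
#'   deep), e.g. from [forward_with_attention()].
#' @param adapters an [adapter_bank()].
#' @return scalar loss (use `hidden_loss_grad()` internally for gradients).
#' @export
hidden_loss <- function(student_maps, teacher_maps, adapters) {
  hidden_loss_grad(student_maps, teacher_maps, adapters)$loss
}

hidden_loss_grad <- function(student_maps, teacher_maps, adapters) {
  gmaps <- vector("list", 3L)
  gadapt <- vector("list", 3L)
  mses <- numeric(3)
  for (i in 1:3) {
    s <- student_maps[[i]]; t <- teacher_maps[[i]]; ad <- adapters[[i]]
    proj <- conv2d(s, ad$w, ad$b)
    if (!identical(dim(proj), dim(t)))
      stop(sprintf("attention map %d: adapted student shape (%s) != teacher shape (%s)",
                   i, paste(dim(proj), collapse = "x"), paste(dim(t), collapse = "x")))
    diff <- proj - t
    mses[i] <- mean(diff^2)
    gproj <- 2 * diff / length(diff) / 3          # d(mean of three MSEs)/dproj
    cb <- conv2d_grad(s, ad$w, gproj, TRUE)
    gmaps[[i]] <- cb$gx
    gadapt[[i]] <- list(w = cb$gw, b = cb$gb)
  }
  list(loss = mean(mses), mses = mses, gmaps = gmaps, gadapt = gadapt)
}

#' One optimization step of teacher-student distillation
#'
#' Runs the frozen teacher and the trainable student on one mini-batch and
#' takes a single Adam step on the student (and, in attention mode, the
#' adapters) against the combined loss. In `"attention"` mode the loss is
#' `weight_hidden * loss_hidden + (1 - weight_hidden) * loss_CE` with the
#' clamped dynamic weight; in `"logit"` mode it is the adaptive convex
#' combination of cross-entropy and temperature-scaled KL divergence. The
#' dynamic weights are treated as constants of the step (no gradient flows
#' through them), and the teacher's parameters are never touched.
#'
#' @param teacher,student `ggenet_network` objects (teacher is frozen).
#' @param adapters an [adapter_bank()] (attention mode; ignored otherwise).
#' @param x mini-batch input, dim (N, 3, H, W).
#' @param y integer class labels in `1..n_classes`.
#' @param opt optimizer bundle from `distill_opt_init()`.
#' @param mode `"attention"` (default) or `"logit"`.
#' @param tau softmax temperature for logit mode.
#' @param lr Adam learning rate.
#' @return list with the updated `student`, `adapters`, `opt`, and
#'   `breakdown` (one-row data frame: loss_ce, the distillation/hidden loss,
#'   the dynamic weight, loss_total).
#' @export
distill_step <- function(teacher, student, adapters, x, y, opt,
                         mode = c("attention", "logit"), tau = 4, lr = 1e-3) {
  mode <- match.arg(mode)
  if (!identical(dim(x)[2], 3L) && dim(x)[2] != 3)
    stop("distill_step expects RGB input")
  sfw <- net_fwd(student, x, want_cache = TRUE)
  ce <- cross_entropy(sfw$logits, y)

  if (mode == "attention") {
    tfw <- net_fwd(teacher, x, want_cache = FALSE)
    hl <- hidden_loss_grad(sfw$maps, tfw$maps, adapters)
    w <- hidden_weight(hl$loss, ce$loss)
    total <- w * hl$loss + (1 - w) * ce$loss
    glogits <- (1 - w) * ce$glogits
    gmaps <- lapply(hl$gmaps, function(g) w * g)
    sbk <- net_bwd(student, sfw$caches, glogits, gmaps)
    ares <- adam_step(unclass(adapters), lapply(hl$gadapt, function(g)
      list(w = w * g$w, b = w * g$b)), opt$adapt, lr = lr)
    adapters <- structure(ares$params, class = "adapter_bank")
    opt$adapt <- ares$state
    breakdown <- data.frame(loss_ce = ce$loss, loss_hidden = hl$loss,
                            weight_hidden = w, loss_total = total)
  } else {
    tlogits <- ggenet_forward(teacher, x)
    kd <- kl_distill(sfw$logits, tlogits, tau)
    a <- adaptive_alpha(ce$loss, kd$loss)
    total <- (1 - a) * ce$loss + a * kd$loss
    glogits <- (1 - a) * ce$glogits + a * kd$glogits
    sbk <- net_bwd(student, sfw$caches, glogits)
    breakdown <- data.frame(loss_ce = ce$loss, loss_distill = kd$loss,
                            alpha = a, loss_total = total)
  }
  sres <- adam_step_net(student, sbk$grads, opt$student, lr = lr)
  list(student = sres$net, adapters = adapters,
       opt = list(student = sres$state, adapt = opt$adapt),
       breakdown = breakdown)
}

distill_opt_init <- function(student, adapters = NULL) {
  list(student = adam_init_net(student),
       adapt = if (!is.null(adapters)) adam_init(unclass(adapters)))
}
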