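#' @title Region-based segmentation losses
#'
#' @description Soft Dice, Tversky, Focal Tversky and the modified /
#' asymmetric Focal Tversky losses. Region scores are computed per batch
#' item (never pooled across the batch, so batch size does not change loss
#' semantics) from probability-weighted soft confusion counts, with an
#' epsilon smoothing term added to numerator and denominator so empty
#' classes cannot produce 0/0. Probabilities are clipped before counting so
#' the score never reaches exactly 1 and its gradient stays finite.
#'
#' @name region-losses
NULL

# ---- shared scaffolding -----------------------------------------------------

.region_prep <- function(p, y, epsilon) {
  .check_prob_label_pair(p, y)
  B <- .n_batch(p); C <- .n_classes(p); Npos <- .n_positions(p)
  inside <- p > epsilon & p < 1 - epsilon
  pc <- clip_probabilities(p, epsilon)
  counts <- .soft_counts(pc, y)
  list(P = .as_class_matrix(pc), G = .as_class_matrix(y),
       tp = counts$tp, fp = counts$fp, fn = counts$fn,
       inside = inside, B = B, C = C, Npos = Npos, dim = dim(p),
       epsilon = epsilon)
}

# B x C matrix of Tversky indices from prepped counts
.ti_matrix <- function(prep, alpha, beta) {
  (prep$tp + prep$epsilon) /
    (prep$tp + alpha * prep$fp + beta * prep$fn + prep$epsilon)
}

.class_set_idx <- function(class_set, C) {
  switch(class_set, all = seq_len(C), foreground = seq(2L, C))
}

# per-item loss from a B x C matrix of per-class terms over a class subset
.region_assemble <- function(term, cls, B, name, settings) {
  per_item <- rowSums(matrix(term[, cls], nrow = B))
  new_loss_value(mean(per_item), per_item, name, settings)
}

# gradient of sum_c coef_bc * TI_bc (mean over batch) w.r.t. p, where `coef`
# is a B x C matrix (zero outside the class set); uses
# dTI/dp_ic = (g*D - N*(g*(1-beta) + alpha*(1-g))) / D^2
.region_gradient <- function(prep, coef, alpha, beta) {
  N <- prep$tp + prep$epsilon
  D <- prep$tp + alpha * prep$fp + beta * prep$fn + prep$epsilon
  grad <- matrix(0, nrow = nrow(prep$P), ncol = prep$C)
  for (cl in seq_len(prep$C)) {
    if (all(coef[, cl] == 0)) next
    g <- prep$G[, cl]
    Ne <- rep(N[, cl], times = prep$Npos)
    De <- rep(D[, cl], times = prep$Npos)
    ce <- rep(coef[, cl], times = prep$Npos)
    dTI <- (g * De - Ne * (g * (1 - beta) + alpha * (1 - g))) / De^2
    grad[, cl] <- ce * dTI / prep$B
  }
  array(grad * .as_class_matrix(prep$inside), dim = prep$dim)
}

# d[(1 - TI)^q]/dTI = -q (1 - TI)^(q - 1); the base is floored away from 0
# so degenerate parameter corners (e.g. beta = 0 with a perfectly covered
# class) cannot emit infinite gradients
.power_coef <- function(ti, q) {
  base <- pmax(1 - ti, 1e-12)
  -q * base^(q - 1)
}

# ---- region scores ----------------------------------------------------------

.region_score_tbl <- function(score, B, C, name) {
  tibble::tibble(
    item  = rep(seq_len(B), times = C),
    class = rep(seq_len(C) - 1L, each = B),
    score = as.vector(score),
    measure = name)
}

#' Soft Dice similarity coefficient
#'
#' Per-class, per-item soft Dice score
#' `(2 tp + eps) / (2 tp + fp + fn + eps)` computed from probability-weighted
#' confusion counts. Equals 1 (up to epsilon) iff the prediction matches the
#' ground truth on that class, and coincides with the hard Dice metric when
#' `p` is one-hot.
#'
#' @inheritParams loss_cross_entropy
#' @return A tibble with columns `item`, `class`, `score`, `measure`.
#' @export
soft_dice <- function(p, y, epsilon = 1e-6) {
  prep <- .region_prep(p, y, epsilon)
  .region_score_tbl(.ti_matrix(prep, 0.5, 0.5), prep$B, prep$C, "soft_dice")
}

#' Tversky index
#'
#' Generalises the soft Dice score by weighting false positives by `alpha`
#' and false negatives by `beta`:
#' `(tp + eps) / (tp + alpha fp + beta fn + eps)`. `alpha = beta = 0.5`
#' recovers [soft_dice()] exactly; `beta > alpha` (commonly 0.7 / 0.3)
#' trades precision for recall.
#'
#' @inheritParams soft_dice
#' @param alpha False-positive weight, `>= 0`.
#' @param beta False-negative weight, `>= 0`.
#' @export
tversky_index <- function(p, y, alpha = 0.3, beta = 0.7, epsilon = 1e-6) {
  if (alpha < 0 || beta < 0) {
    stop("`alpha` and `beta` must be non-negative", call. = FALSE)
  }
  prep <- .region_prep(p, y, epsilon)
  .region_score_tbl(.ti_matrix(prep, alpha, beta), prep$B, prep$C,
                    "tversky_index")
}

#' Modified Tversky index
#'
#' The Tversky index re-parameterised by the single output-imbalance weight
#' `delta`: `alpha = delta`, `beta = 1 - delta`. `delta = 0.5` recovers
#' [soft_dice()].
#'
#' @inheritParams soft_dice
#' @param delta Output-imbalance weight in `[0, 1]`.
#' @export
modified_tversky_index <- function(p, y, delta = 0.6, epsilon = 1e-6) {
  if (delta < 0 || delta > 1) stop("`delta` must lie in [0, 1]", call. = FALSE)
  prep <- .region_prep(p, y, epsilon)
  .region_score_tbl(.ti_matrix(prep, delta, 1 - delta), prep$B, prep$C,
                    "modified_tversky_index")
}

# ---- region losses ----------------------------------------------------------

#' Dice loss
#'
#' `sum over the class set of (1 - soft Dice)`, averaged over the batch.
#' Identical to [loss_tversky()] with `alpha = beta = 0.5`.
#'
#' @inheritParams soft_dice
#' @param class_set `"all"` (default) sums over every class including
#'   background; `"foreground"` sums over classes `1..C-1` only.
#' @export
loss_dice <- function(p, y, class_set = c("all", "foreground"),
                      epsilon = 1e-6) {
  loss_tversky(p, y, alpha = 0.5, beta = 0.5, class_set = class_set,
               epsilon = epsilon)
}

.grad_dice <- function(p, y, class_set = "all", epsilon = 1e-6) {
  .grad_tversky(p, y, alpha = 0.5, beta = 0.5, class_set = class_set,
                epsilon = epsilon)
}

#' Tversky loss
#'
#' `sum over the class set of (1 - Tversky index)`, averaged over the batch.
#'
#' @inheritParams tversky_index
#' @inheritParams loss_dice
#' @export
loss_tversky <- function(p, y, alpha = 0.3, beta = 0.7,
                         class_set = c("all", "foreground"),
                         epsilon = 1e-6) {
  class_set <- match.arg(class_set)
  if (alpha < 0 || beta < 0) {
    stop("`alpha` and `beta` must be non-negative", call. = FALSE)
  }
  prep <- .region_prep(p, y, epsilon)
  ti <- .ti_matrix(prep, alpha, beta)
  .region_assemble(1 - ti, .class_set_idx(class_set, prep$C), prep$B,
                   if (alpha == 0.5 && beta == 0.5) "dice" else "tversky",
                   list(alpha = alpha, beta = beta, class_set = class_set,
                        epsilon = epsilon))
}

.grad_tversky <- function(p, y, alpha = 0.3, beta = 0.7, class_set = "all",
                          epsilon = 1e-6) {
  prep <- .region_prep(p, y, epsilon)
  cls <- .class_set_idx(class_set, prep$C)
  coef <- matrix(0, prep$B, prep$C)
  coef[, cls] <- -1                      # d(1 - TI)/dTI
  .region_gradient(prep, coef, alpha, beta)
}

#' Focal Tversky loss
#'
#' `sum over the class set of (1 - TI)^(1/gamma)`, averaged over the batch.
#' `gamma = 1` recovers [loss_tversky()]; the conventional `gamma = 4/3`
#' *enhances* the loss of easy examples (exponent < 1), maintaining gradient
#' signal as the Tversky index approaches 1 late in training.
#'
#' @inheritParams loss_tversky
#' @param gamma Focal parameter, `> 0`.
#' @export
loss_focal_tversky <- function(p, y, alpha = 0.3, beta = 0.7, gamma = 4 / 3,
                               class_set = c("all", "foreground"),
                               epsilon = 1e-6) {
  class_set <- match.arg(class_set)
  if (gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  prep <- .region_prep(p, y, epsilon)
  ti <- .ti_matrix(prep, alpha, beta)
  .region_assemble((1 - ti)^(1 / gamma), .class_set_idx(class_set, prep$C),
                   prep$B, "focal_tversky",
                   list(alpha = alpha, beta = beta, gamma = gamma,
                        class_set = class_set, epsilon = epsilon))
}

.grad_focal_tversky <- function(p, y, alpha = 0.3, beta = 0.7, gamma = 4 / 3,
                                class_set = "all", epsilon = 1e-6) {
  prep <- .region_prep(p, y, epsilon)
  cls <- .class_set_idx(class_set, prep$C)
  ti <- .ti_matrix(prep, alpha, beta)
  coef <- matrix(0, prep$B, prep$C)
  coef[, cls] <- .power_coef(ti, 1 / gamma)[, cls]
  .region_gradient(prep, coef, alpha, beta)
}

#' Modified Focal Tversky loss
#'
#' The Tversky component of the Unified Focal loss:
#' `sum over the class set of (1 - mTI)^(1 - gamma)` with the modified
#' Tversky index `mTI` (see [modified_tversky_index()]). At `gamma = 0` it
#' reduces to the Tversky(`delta`, `1 - delta`) loss, so
#' `gamma = 0, delta = 0.5` gives exactly [loss_dice()]; `gamma > 0`
#' enhances hard examples.
#'
#' @inheritParams modified_tversky_index
#' @inheritParams loss_dice
#' @param gamma Focal parameter in `[0, 1)`.
#' @param literal_exponents If `TRUE`, use the alternative printed exponent
#'   `gamma` instead of `1 - gamma` (compatibility mode, paired with the
#'   same flag of [loss_modified_focal()]).
#' @export
loss_modified_focal_tversky <- function(p, y, delta = 0.6, gamma = 0.5,
                                        class_set = c("all", "foreground"),
                                        epsilon = 1e-6,
                                        literal_exponents = FALSE) {
  class_set <- match.arg(class_set)
  if (gamma < 0 || gamma >= 1) stop("`gamma` must lie in [0, 1)", call. = FALSE)
  if (delta < 0 || delta > 1) stop("`delta` must lie in [0, 1]", call. = FALSE)
  q <- if (literal_exponents) gamma else 1 - gamma
  prep <- .region_prep(p, y, epsilon)
  ti <- .ti_matrix(prep, delta, 1 - delta)
  .region_assemble((1 - ti)^q, .class_set_idx(class_set, prep$C), prep$B,
                   "modified_focal_tversky",
                   list(delta = delta, gamma = gamma, class_set = class_set,
                        epsilon = epsilon))
}

.grad_modified_focal_tversky <- function(p, y, delta = 0.6, gamma = 0.5,
                                         class_set = "all", epsilon = 1e-6,
                                         literal_exponents = FALSE) {
  q <- if (literal_exponents) gamma else 1 - gamma
  prep <- .region_prep(p, y, epsilon)
  cls <- .class_set_idx(class_set, prep$C)
  ti <- .ti_matrix(prep, delta, 1 - delta)
  coef <- matrix(0, prep$B, prep$C)
  coef[, cls] <- .power_coef(ti, q)[, cls]
  .region_gradient(prep, coef, delta, 1 - delta)
}

#' Modified asymmetric Focal Tversky loss
#'
#' Asymmetric variant of [loss_modified_focal_tversky()]: the focal
#' enhancement exponent `(1 - gamma)` is applied only to the *rare* classes,
#' while every other class contributes its plain `(1 - mTI)` term — the
#' background is never enhanced.
#'
#' @inheritParams loss_modified_focal_tversky
#' @inheritParams loss_modified_asymmetric_focal
#' @export
loss_modified_asymmetric_focal_tversky <- function(p, y, delta = 0.6,
                                                   gamma = 0.5,
                                                   rare_classes = 1L,
                                                   class_set = c("all", "foreground"),
                                                   epsilon = 1e-6) {
  class_set <- match.arg(class_set)
  if (gamma < 0 || gamma >= 1) stop("`gamma` must lie in [0, 1)", call. = FALSE)
  prep <- .region_prep(p, y, epsilon)
  rc <- .check_rare_classes(rare_classes, prep$C)
  ti <- .ti_matrix(prep, delta, 1 - delta)
  qs <- ifelse((seq_len(prep$C) - 1L) %in% rc, 1 - gamma, 1)
  term <- sweep(1 - ti, 2, qs, "^")
  .region_assemble(term, .class_set_idx(class_set, prep$C), prep$B,
                   "modified_asymmetric_focal_tversky",
                   list(delta = delta, gamma = gamma, rare_classes = rc,
                        class_set = class_set, epsilon = epsilon))
}

.grad_modified_asymmetric_focal_tversky <- function(p, y, delta = 0.6,
                                                    gamma = 0.5,
                                                    rare_classes = 1L,
                                                    class_set = "all",
                                                    epsilon = 1e-6) {
  prep <- .region_prep(p, y, epsilon)
  rc <- .check_rare_classes(rare_classes, prep$C)
  cls <- .class_set_idx(class_set, prep$C)
  ti <- .ti_matrix(prep, delta, 1 - delta)
  qs <- ifelse((seq_len(prep$C) - 1L) %in% rc, 1 - gamma, 1)
  coef <- matrix(0, prep$B, prep$C)
  for (cl in cls) coef[, cl] <- .power_coef(ti[, cl, drop = FALSE], qs[cl])
  .region_gradient(prep, coef, delta, 1 - delta)
}
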