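#' @title Compound segmentation losses
#'
#' @description Weighted sums of a distribution-based and a region-based
#' loss: the Combo loss, the Hybrid Focal loss, and the symmetric and
#' asymmetric Unified Focal losses. The Unified Focal loss groups the
#' hyperparameters of its components into three: `lambda` (component
#' weighting), `delta` (output imbalance: false negatives vs false
#' positives) and `gamma` (focal modulation — suppression of easy examples
#' on the cross entropy side, enhancement of hard examples on the Tversky
#' side). Every other Dice- or cross entropy-based loss in the package is a
#' special case; [verify_reductions()] checks the edges numerically.
#'
#' @name compound-losses
NULL

# ---- Combo loss -------------------------------------------------------------

#' Combo loss
#'
#' `combo_alpha * mCE - (1 - combo_alpha) * DSC`, where `mCE` is a
#' class-weighted cross entropy (weight `beta` on foreground positions,
#' `1 - beta` on background; `beta > 0.5` penalises false negatives more)
#' and `DSC` is the soft *foreground* Dice score (mean over foreground
#' classes when C > 2). Because the Dice similarity is subtracted rather
#' than `1 - DSC` added, the loss is bounded below by
#' `-(1 - combo_alpha)`, attained at perfect prediction, and can be
#' negative.
#'
#' @inheritParams loss_cross_entropy
#' @param combo_alpha Mixing weight in `[0, 1]`: 1 gives the weighted cross
#'   entropy alone, 0 gives `-DSC`.
#' @param beta Foreground (false-negative) weight of the cross entropy term,
#'   in `[0, 1]`; `beta = 0.5` makes the term equal `0.5 * cross entropy`.
#' @export
loss_combo <- function(p, y, combo_alpha = 0.5, beta = 0.5, epsilon = 1e-6) {
  if (combo_alpha < 0 || combo_alpha > 1 || beta < 0 || beta > 1) {
    stop("`combo_alpha` and `beta` must lie in [0, 1]", call. = FALSE)
  }
  prep <- .ce_prep(p, y, epsilon)
  w <- .class_weight(prep, c(1 - beta, rep(beta, prep$C - 1L)))
  mce_item <- .per_item_mean(w * (-log(prep$pt)), prep$B)

  rprep <- .region_prep(p, y, epsilon)
  dsc <- .ti_matrix(rprep, 0.5, 0.5)
  fg <- seq(2L, rprep$C)
  dsc_item <- rowMeans(matrix(dsc[, fg], nrow = rprep$B))

  per_item <- combo_alpha * mce_item - (1 - combo_alpha) * dsc_item
  new_loss_value(mean(per_item), per_item, "combo",
                 list(combo_alpha = combo_alpha, beta = beta,
                      epsilon = epsilon))
}

.grad_combo <- function(p, y, combo_alpha = 0.5, beta = 0.5, epsilon = 1e-6) {
  prep <- .ce_prep(p, y, epsilon)
  w <- .class_weight(prep, c(1 - beta, rep(beta, prep$C - 1L)))
  g_mce <- .ce_gradient(prep, -w / prep$pt)

  rprep <- .region_prep(p, y, epsilon)
  fg <- seq(2L, rprep$C)
  coef <- matrix(0, rprep$B, rprep$C)
  coef[, fg] <- -(1 - combo_alpha) / length(fg)
  g_dsc <- .region_gradient(rprep, coef, 0.5, 0.5)

  combo_alpha * g_mce + g_dsc
}

# ---- Hybrid Focal loss ------------------------------------------------------

#' Hybrid Focal loss
#'
#' `lambda * Focal + (1 - lambda) * Focal Tversky`, each component with its
#' own hyperparameters (six in total) — the predecessor of the Unified
#' Focal loss, which collapses them to three.
#'
#' @inheritParams loss_cross_entropy
#' @param lambda Component weight in `[0, 1]`; 1 gives the Focal loss
#'   alone, 0 the Focal Tversky loss alone.
#' @param focal_alpha,focal_gamma Parameters of the [loss_focal()]
#'   component.
#' @param tversky_alpha,tversky_beta,tversky_gamma Parameters of the
#'   [loss_focal_tversky()] component.
#' @param class_set Class set of the Tversky component (see [loss_dice()]).
#' @export
loss_hybrid_focal <- function(p, y, lambda = 0.5,
                              focal_alpha = 0.25, focal_gamma = 2,
                              tversky_alpha = 0.3, tversky_beta = 0.7,
                              tversky_gamma = 4 / 3,
                              class_set = c("all", "foreground"),
                              epsilon = 1e-6) {
  class_set <- match.arg(class_set)
  if (lambda < 0 || lambda > 1) stop("`lambda` must lie in [0, 1]", call. = FALSE)
  a <- loss_focal(p, y, alpha = focal_alpha, gamma = focal_gamma,
                  epsilon = epsilon)
  b <- loss_focal_tversky(p, y, alpha = tversky_alpha, beta = tversky_beta,
                          gamma = tversky_gamma, class_set = class_set,
                          epsilon = epsilon)
  per_item <- lambda * a$per_item + (1 - lambda) * b$per_item
  new_loss_value(mean(per_item), per_item, "hybrid_focal",
                 list(lambda = lambda, focal_alpha = focal_alpha,
                      focal_gamma = focal_gamma,
                      tversky_alpha = tversky_alpha,
                      tversky_beta = tversky_beta,
                      tversky_gamma = tversky_gamma,
                      class_set = class_set, epsilon = epsilon))
}

.grad_hybrid_focal <- function(p, y, lambda = 0.5,
                               focal_alpha = 0.25, focal_gamma = 2,
                               tversky_alpha = 0.3, tversky_beta = 0.7,
                               tversky_gamma = 4 / 3, class_set = "all",
                               epsilon = 1e-6) {
  lambda * .grad_focal(p, y, alpha = focal_alpha, gamma = focal_gamma,
                       epsilon = epsilon) +
    (1 - lambda) * .grad_focal_tversky(p, y, alpha = tversky_alpha,
                                       beta = tversky_beta,
                                       gamma = tversky_gamma,
                                       class_set = class_set,
                                       epsilon = epsilon)
}

# ---- Unified Focal loss -----------------------------------------------------

#' Unified Focal loss
#'
#' `lambda * modified Focal + (1 - lambda) * modified Focal Tversky`, in a
#' symmetric variant (focal modulation applied to every class) and an
#' asymmetric variant (suppression confined to non-rare classes on the
#' cross entropy side, enhancement confined to rare classes on the Tversky
#' side). Recommended defaults: `lambda = 0.5` (equal component weight),
#' `delta = 0.6` (mildly recall-favouring), leaving `gamma` as the single
#' hyperparameter to tune.
#'
#' Special cases (`verify_reductions()` checks them numerically): with
#' `gamma = 0, delta = 0.5`, `lambda = 0` gives the Dice loss and
#' `lambda = 1` gives `0.5 *` cross entropy (the 0.5 is the `delta` class
#' weight); `lambda = 1` alone gives the modified (asymmetric) Focal loss,
#' `lambda = 0` the modified (asymmetric) Focal Tversky loss.
#'
#' @inheritParams loss_modified_focal
#' @inheritParams loss_modified_asymmetric_focal
#' @inheritParams loss_dice
#' @param lambda Component weight in `[0, 1]`.
#' @param variant `"symmetric"` or `"asymmetric"`.
#' @export
loss_unified_focal <- function(p, y, lambda = 0.5, delta = 0.6, gamma = 0.5,
                               variant = c("symmetric", "asymmetric"),
                               rare_classes = 1L,
                               class_set = c("all", "foreground"),
                               epsilon = 1e-6, literal_exponents = FALSE) {
  variant <- match.arg(variant)
  class_set <- match.arg(class_set)
  if (lambda < 0 || lambda > 1) stop("`lambda` must lie in [0, 1]", call. = FALSE)
  if (variant == "symmetric") {
    a <- loss_modified_focal(p, y, delta = delta, gamma = gamma,
                             epsilon = epsilon,
                             literal_exponents = literal_exponents)
    b <- loss_modified_focal_tversky(p, y, delta = delta, gamma = gamma,
                                     class_set = class_set, epsilon = epsilon,
                                     literal_exponents = literal_exponents)
  } else {
    a <- loss_modified_asymmetric_focal(p, y, delta = delta, gamma = gamma,
                                        rare_classes = rare_classes,
                                        epsilon = epsilon)
    b <- loss_modified_asymmetric_focal_tversky(p, y, delta = delta,
                                                gamma = gamma,
                                                rare_classes = rare_classes,
                                                class_set = class_set,
                                                epsilon = epsilon)
  }
  per_item <- lambda * a$per_item + (1 - lambda) * b$per_item
  new_loss_value(mean(per_item), per_item,
                 paste0("unified_focal_",
                        if (variant == "symmetric") "sym" else "asym"),
                 list(lambda = lambda, delta = delta, gamma = gamma,
                      variant = variant,
                      rare_classes = if (variant == "asymmetric") rare_classes,
                      class_set = class_set, epsilon = epsilon))
}

.grad_unified_focal <- function(p, y, lambda = 0.5, delta = 0.6, gamma = 0.5,
                                variant = "symmetric", rare_classes = 1L,
                                class_set = "all", epsilon = 1e-6,
                                literal_exponents = FALSE) {
  if (variant == "symmetric") {
    ga <- .grad_modified_focal(p, y, delta = delta, gamma = gamma,
                               epsilon = epsilon,
                               literal_exponents = literal_exponents)
    gb <- .grad_modified_focal_tversky(p, y, delta = delta, gamma = gamma,
                                       class_set = class_set,
                                       epsilon = epsilon,
                                       literal_exponents = literal_exponents)
  } else {
    ga <- .grad_modified_asymmetric_focal(p, y, delta = delta, gamma = gamma,
                                          rare_classes = rare_classes,
                                          epsilon = epsilon)
    gb <- .grad_modified_asymmetric_focal_tversky(p, y, delta = delta,
                                                  gamma = gamma,
                                                  rare_classes = rare_classes,
                                                  class_set = class_set,
                                                  epsilon = epsilon)
  }
  lambda * ga + (1 - lambda) * gb
}
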