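#' @title Distribution-based segmentation losses
#'
#' @description Cross entropy, Focal, modified Focal and modified asymmetric
#' Focal losses. All operate per spatial position on the predicted
#' probability of the true class, `p_t`, aggregate by averaging positions
#' within each batch item and then averaging over the batch, and clip
#' probabilities internally (see [clip_probabilities()]) so the logarithms
#' are always finite.
#'
#' @name distribution-losses
NULL

# ---- loss value container ---------------------------------------------------

new_loss_value <- function(value, per_item, name, settings) {
  structure(list(value = value, per_item = per_item,
                 name = name, settings = settings),
            class = "unifocal_loss")
}

#' @export
print.unifocal_loss <- function(x, ...) {
  cat(sprintf("<%s loss> value: %.6g over %d item(s)\n",
              x$name, x$value, length(x$per_item)))
  if (length(x$settings)) {
    cat("  settings:",
        paste(names(x$settings),
              vapply(x$settings, function(v) paste(format(v), collapse = ","),
                     character(1)),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.double.unifocal_loss <- function(x, ...) x$value

#' @rdname tidiers
#' @export
tidy.unifocal_loss <- function(x, ...) {
  tibble::tibble(item = seq_along(x$per_item), loss = x$name,
                 value = x$per_item)
}

# ---- shared scaffolding -----------------------------------------------------

# clip, flatten and precompute everything the CE-family needs
.ce_prep <- function(p, y, epsilon) {
  .check_prob_label_pair(p, y)
  B <- .n_batch(p); C <- .n_classes(p); Npos <- .n_positions(p)
  inside <- p > epsilon & p < 1 - epsilon   # clip pass-through mask for grads
  P <- .as_class_matrix(clip_probabilities(p, epsilon))
  G <- .as_class_matrix(y)
  pt <- rowSums(P * G)
  true_class <- max.col(G, ties.method = "first")  # 1-based channel index
  list(P = P, G = G, pt = pt, true_class = true_class,
       inside = inside, B = B, C = C, Npos = Npos, dim = dim(p))
}

# aggregate per-position terms and wrap; fprime is d(term)/d(p_t)
.ce_assemble <- function(prep, term, name, settings) {
  per_item <- .per_item_mean(term, prep$B)
  new_loss_value(mean(per_item), per_item, name, settings)
}

# gradient of a CE-family loss w.r.t. the (unclipped) probability array:
# only the true-class channel carries gradient, scaled by 1/(Npos * B)
.ce_gradient <- function(prep, fprime) {
  g <- prep$G * (fprime / (prep$Npos * prep$B))
  g <- g * .as_class_matrix(prep$inside)
  array(g, dim = prep$dim)
}

# per-position class weight vector from a length-C weight table
.class_weight <- function(prep, w_by_class) w_by_class[prep$true_class]

# resolve the focal alpha argument into a length-C class-weight vector
.alpha_weights <- function(alpha, C) {
  if (is.null(alpha)) return(rep(1, C))
  if (length(alpha) == 1L) return(c(1 - alpha, rep(alpha, C - 1L)))
  if (length(alpha) != C) {
    stop(sprintf("`alpha` must be NULL, a scalar, or length %d (one per class)", C),
         call. = FALSE)
  }
  as.numeric(alpha)
}

# ---- cross entropy ----------------------------------------------------------

#' Categorical cross entropy loss
#'
#' `-(1/N) * sum_i sum_c y_ic * log(p_ic)` per batch item, averaged over the
#' batch. For two-channel maps this is the familiar binary cross entropy.
#'
#' @param p Probability map `(batch, spatial..., class)`.
#' @param y One-hot labels of the same shape.
#' @param epsilon Clip margin applied before the logarithm.
#' @return A loss object with fields `value` (batch mean) and `per_item`.
#' @examples
#' y <- one_hot_encode(array(c(0, 1), dim = c(1, 2)), 2)
#' p <- array(c(0.5, 0.5, 0.5, 0.5), dim = c(1, 2, 2))
#' loss_cross_entropy(p, y)$value  # log(2)
#' @export
loss_cross_entropy <- function(p, y, epsilon = 1e-6) {
  prep <- .ce_prep(p, y, epsilon)
  .ce_assemble(prep, -log(prep$pt), "cross_entropy", list(epsilon = epsilon))
}

.grad_cross_entropy <- function(p, y, epsilon = 1e-6) {
  prep <- .ce_prep(p, y, epsilon)
  .ce_gradient(prep, -1 / prep$pt)
}

# ---- Focal loss -------------------------------------------------------------

#' Focal loss
#'
#' Adds the modulating factor `(1 - p_t)^gamma` to cross entropy,
#' down-weighting well-classified positions, with optional class weighting
#' `alpha`. With `gamma = 0` and `alpha = NULL` it equals
#' [loss_cross_entropy()] exactly.
#'
#' @inheritParams loss_cross_entropy
#' @param alpha `NULL` (no weighting), a scalar (weight `alpha` on every
#'   foreground class and `1 - alpha` on background), or a length-C vector
#'   of per-class weights. The conventional setting is `alpha = 0.25`.
#' @param gamma Focal exponent, `>= 0`. The conventional setting is 2.
#' @export
loss_focal <- function(p, y, alpha = NULL, gamma = 2, epsilon = 1e-6) {
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  prep <- .ce_prep(p, y, epsilon)
  w <- .class_weight(prep, .alpha_weights(alpha, prep$C))
  term <- w * (1 - prep$pt)^gamma * (-log(prep$pt))
  .ce_assemble(prep, term, "focal",
               list(alpha = alpha, gamma = gamma, epsilon = epsilon))
}

.grad_focal <- function(p, y, alpha = NULL, gamma = 2, epsilon = 1e-6) {
  prep <- .ce_prep(p, y, epsilon)
  w <- .class_weight(prep, .alpha_weights(alpha, prep$C))
  pt <- prep$pt
  fp <- if (gamma == 0) {
    -w / pt
  } else {
    w * (gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt)
  }
  .ce_gradient(prep, fp)
}

# ---- modified Focal loss ----------------------------------------------------

# shared weight table: delta on foreground classes, 1 - delta on background
.delta_weights <- function(delta, C) c(1 - delta, rep(delta, C - 1L))

# exponent convention: suppression grows with gamma, and gamma = 0 recovers
# the delta-weighted cross entropy; `literal_exponents` swaps in the 1 - gamma
# form for compatibility with the alternative printed convention
.mf_exponent <- function(gamma, literal_exponents) {
  if (literal_exponents) 1 - gamma else gamma
}

#' Modified Focal loss
#'
#' The cross entropy component of the Unified Focal loss: class weighting by
#' a single output-imbalance parameter `delta` (weight `delta` on foreground
#' classes, `1 - delta` on background) and focal suppression
#' `(1 - p_t)^gamma`. At `gamma = 0` it reduces to the `delta`-weighted
#' cross entropy, so `gamma = 0, delta = 0.5` gives exactly
#' `0.5 * loss_cross_entropy()`.
#'
#' @inheritParams loss_cross_entropy
#' @param delta Output-imbalance weight in `[0, 1]`; values above 0.5 weight
#'   foreground (false-negative) errors more heavily. Default 0.6.
#' @param gamma Focal parameter in `[0, 1)`.
#' @param literal_exponents If `TRUE`, use the alternative printed exponent
#'   `1 - gamma` instead of `gamma` (compatibility mode; under it `gamma = 1`
#'   rather than `gamma = 0` recovers weighted cross entropy).
#' @export
loss_modified_focal <- function(p, y, delta = 0.6, gamma = 0.5,
                                epsilon = 1e-6, literal_exponents = FALSE) {
  if (delta < 0 || delta > 1) stop("`delta` must lie in [0, 1]", call. = FALSE)
  if (gamma < 0 || gamma >= 1) {
    stop("`gamma` must lie in [0, 1) for the modified Focal loss", call. = FALSE)
  }
  e <- .mf_exponent(gamma, literal_exponents)
  prep <- .ce_prep(p, y, epsilon)
  w <- .class_weight(prep, .delta_weights(delta, prep$C))
  term <- w * (1 - prep$pt)^e * (-log(prep$pt))
  .ce_assemble(prep, term, "modified_focal",
               list(delta = delta, gamma = gamma, epsilon = epsilon))
}

.grad_modified_focal <- function(p, y, delta = 0.6, gamma = 0.5,
                                 epsilon = 1e-6, literal_exponents = FALSE) {
  e <- .mf_exponent(gamma, literal_exponents)
  prep <- .ce_prep(p, y, epsilon)
  w <- .class_weight(prep, .delta_weights(delta, prep$C))
  pt <- prep$pt
  fp <- if (e == 0) -w / pt else {
    w * (e * (1 - pt)^(e - 1) * log(pt) - (1 - pt)^e / pt)
  }
  .ce_gradient(prep, fp)
}

# ---- modified asymmetric Focal loss -----------------------------------------

#' Modified asymmetric Focal loss
#'
#' Asymmetric variant of [loss_modified_focal()]: positions belonging to a
#' *rare* (foreground) class contribute an unmodulated, `delta`-weighted
#' cross entropy term — their loss is never suppressed — while all other
#' positions keep the focal suppression factor `(1 - p_t)^gamma` with weight
#' `1 - delta`.
#'
#' @inheritParams loss_modified_focal
#' @param rare_classes Integer vector of rare class indices (1-based class
#'   labels, i.e. a subset of `1..C-1`; background 0 is not allowed).
#' @export
loss_modified_asymmetric_focal <- function(p, y, delta = 0.6, gamma = 0.5,
                                           rare_classes = 1L,
                                           epsilon = 1e-6) {
  if (gamma < 0 || gamma >= 1) stop("`gamma` must lie in [0, 1)", call. = FALSE)
  prep <- .ce_prep(p, y, epsilon)
  rc <- .check_rare_classes(rare_classes, prep$C)
  is_rare <- (prep$true_class - 1L) %in% rc
  pt <- prep$pt
  term <- ifelse(is_rare,
                 delta * (-log(pt)),
                 (1 - delta) * (1 - pt)^gamma * (-log(pt)))
  .ce_assemble(prep, term, "modified_asymmetric_focal",
               list(delta = delta, gamma = gamma, rare_classes = rc,
                    epsilon = epsilon))
}

.grad_modified_asymmetric_focal <- function(p, y, delta = 0.6, gamma = 0.5,
                                            rare_classes = 1L,
                                            epsilon = 1e-6) {
  prep <- .ce_prep(p, y, epsilon)
  rc <- .check_rare_classes(rare_classes, prep$C)
  is_rare <- (prep$true_class - 1L) %in% rc
  pt <- prep$pt
  fp_bg <- if (gamma == 0) -(1 - delta) / pt else {
    (1 - delta) * (gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt)
  }
  fp <- ifelse(is_rare, -delta / pt, fp_bg)
  .ce_gradient(prep, fp)
}
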