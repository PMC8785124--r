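#' Numerically verify the loss reduction hierarchy
#'
#' Every Dice- and cross entropy-based loss in the package is a special case
#' of the Unified Focal loss. This function checks each stated reduction
#' edge by evaluating both sides on seeded random probability/label batches
#' and recording the maximum absolute difference:
#'
#' * Focal(`gamma = 0`, no `alpha`) = cross entropy
#' * Focal Tversky(`gamma = 1`) = Tversky
#' * Tversky(0.5, 0.5) = Dice
#' * modified Tversky index(`delta`) = Tversky index(`delta`, `1 - delta`)
#' * modified Focal(`gamma = 0`, `delta = 0.5`) = 0.5 x cross entropy
#' * modified Focal Tversky(`gamma = 0`, `delta = 0.5`) = Dice
#' * Unified Focal sym(`lambda = 1`, `gamma = 0`, `delta = 0.5`) = 0.5 x CE
#' * Unified Focal sym(`lambda = 0`, `gamma = 0`, `delta = 0.5`) = Dice
#' * Unified Focal sym(`lambda = 1`) = modified Focal;
#'   (`lambda = 0`) = modified Focal Tversky
#' * Unified Focal asym(`lambda = 1`) = modified asymmetric Focal;
#'   (`lambda = 0`) = modified asymmetric Focal Tversky
#' * Hybrid Focal(`lambda = 1`) = Focal; (`lambda = 0`) = Focal Tversky
#'
#' @param trials Number of random batches per edge.
#' @param seed RNG seed.
#' @param tolerance Pass threshold on the max absolute difference.
#' @param batch_shape Spatial shape of the random batches.
#' @return A `reduction_report`: tibble with columns `edge`, `source`,
#'   `target`, `max_abs_diff`, `tolerance`, `pass`, plus attributes `trials`
#'   and `seed`. `tidy()` returns the tibble, `glance()` a one-row summary.
#' @examples
#' rep <- verify_reductions(trials = 5, seed = 1)
#' all(rep$pass)
#' @export
verify_reductions <- function(trials = 100, seed = 17, tolerance = 1e-6,
                              batch_shape = c(4, 4)) {
  stopifnot(trials >= 1)
  delta_probe <- 0.6   # probe value for the delta-parameterised edges
  edges <- list(
    list(edge = "focal_gamma0_to_ce",
         source = "focal(gamma=0, alpha=NULL)", target = "cross_entropy",
         f = function(p, y) loss_focal(p, y, alpha = NULL, gamma = 0)$value,
         g = function(p, y) loss_cross_entropy(p, y)$value),
    list(edge = "focal_tversky_gamma1_to_tversky",
         source = "focal_tversky(0.3, 0.7, gamma=1)", target = "tversky(0.3, 0.7)",
         f = function(p, y) loss_focal_tversky(p, y, 0.3, 0.7, gamma = 1)$value,
         g = function(p, y) loss_tversky(p, y, 0.3, 0.7)$value),
    list(edge = "tversky_half_to_dice",
         source = "tversky(0.5, 0.5)", target = "dice",
         f = function(p, y) loss_tversky(p, y, 0.5, 0.5)$value,
         g = function(p, y) loss_dice(p, y)$value),
    list(edge = "mti_to_ti",
         source = sprintf("modified_tversky_index(delta=%.1f)", delta_probe),
         target = sprintf("tversky_index(%.1f, %.1f)", delta_probe, 1 - delta_probe),
         f = function(p, y) modified_tversky_index(p, y, delta_probe)$score,
         g = function(p, y) tversky_index(p, y, delta_probe, 1 - delta_probe)$score),
    list(edge = "modified_focal_to_half_ce",
         source = "modified_focal(gamma=0, delta=0.5)", target = "0.5 * cross_entropy",
         f = function(p, y) loss_modified_focal(p, y, delta = 0.5, gamma = 0)$value,
         g = function(p, y) 0.5 * loss_cross_entropy(p, y)$value),
    list(edge = "modified_focal_tversky_to_dice",
         source = "modified_focal_tversky(gamma=0, delta=0.5)", target = "dice",
         f = function(p, y) loss_modified_focal_tversky(p, y, delta = 0.5, gamma = 0)$value,
         g = function(p, y) loss_dice(p, y)$value),
    list(edge = "uf_sym_lambda1_to_half_ce",
         source = "unified_focal(sym, lambda=1, gamma=0, delta=0.5)",
         target = "0.5 * cross_entropy",
         f = function(p, y) loss_unified_focal(p, y, lambda = 1, delta = 0.5,
                                               gamma = 0)$value,
         g = function(p, y) 0.5 * loss_cross_entropy(p, y)$value),
    list(edge = "uf_sym_lambda0_to_dice",
         source = "unified_focal(sym, lambda=0, gamma=0, delta=0.5)",
         target = "dice",
         f = function(p, y) loss_unified_focal(p, y, lambda = 0, delta = 0.5,
                                               gamma = 0)$value,
         g = function(p, y) loss_dice(p, y)$value),
    list(edge = "uf_sym_lambda1_to_modified_focal",
         source = "unified_focal(sym, lambda=1)", target = "modified_focal",
         f = function(p, y) loss_unified_focal(p, y, lambda = 1, delta = delta_probe,
                                               gamma = 0.5)$value,
         g = function(p, y) loss_modified_focal(p, y, delta = delta_probe,
                                                gamma = 0.5)$value),
    list(edge = "uf_sym_lambda0_to_modified_focal_tversky",
         source = "unified_focal(sym, lambda=0)", target = "modified_focal_tversky",
         f = function(p, y) loss_unified_focal(p, y, lambda = 0, delta = delta_probe,
                                               gamma = 0.5)$value,
         g = function(p, y) loss_modified_focal_tversky(p, y, delta = delta_probe,
                                                        gamma = 0.5)$value),
    list(edge = "uf_asym_lambda1_to_asymmetric_focal",
         source = "unified_focal(asym, lambda=1)",
         target = "modified_asymmetric_focal",
         f = function(p, y) loss_unified_focal(p, y, lambda = 1, delta = delta_probe,
                                               gamma = 0.5,
                                               variant = "asymmetric")$value,
         g = function(p, y) loss_modified_asymmetric_focal(p, y,
                                                           delta = delta_probe,
                                                           gamma = 0.5)$value),
    list(edge = "uf_asym_lambda0_to_asymmetric_focal_tversky",
         source = "unified_focal(asym, lambda=0)",
         target = "modified_asymmetric_focal_tversky",
         f = function(p, y) loss_unified_focal(p, y, lambda = 0, delta = delta_probe,
                                               gamma = 0.5,
                                               variant = "asymmetric")$value,
         g = function(p, y) loss_modified_asymmetric_focal_tversky(
               p, y, delta = delta_probe, gamma = 0.5)$value),
    list(edge = "hybrid_lambda1_to_focal",
         source = "hybrid_focal(lambda=1)", target = "focal(0.25, 2)",
         f = function(p, y) loss_hybrid_focal(p, y, lambda = 1)$value,
         g = function(p, y) loss_focal(p, y, alpha = 0.25, gamma = 2)$value),
    list(edge = "hybrid_lambda0_to_focal_tversky",
         source = "hybrid_focal(lambda=0)", target = "focal_tversky(0.3, 0.7, 4/3)",
         f = function(p, y) loss_hybrid_focal(p, y, lambda = 0)$value,
         g = function(p, y) loss_focal_tversky(p, y, 0.3, 0.7, 4 / 3)$value)
  )

  set.seed(seed)
  diffs <- numeric(length(edges))
  for (t in seq_len(trials)) {
    C <- if (t %% 2 == 0) 3L else 2L
    batch <- random_softmax_batch(n = 2L, shape = batch_shape, num_classes = C)
    for (k in seq_along(edges)) {
      d <- max(abs(edges[[k]]$f(batch$p, batch$y) -
                   edges[[k]]$g(batch$p, batch$y)))
      diffs[k] <- max(diffs[k], d)
    }
  }
  out <- tibble::tibble(
    edge = vapply(edges, `[[`, character(1), "edge"),
    source = vapply(edges, `[[`, character(1), "source"),
    target = vapply(edges, `[[`, character(1), "target"),
    max_abs_diff = diffs,
    tolerance = tolerance,
    pass = diffs < tolerance)
  structure(out, class = c("reduction_report", class(out)),
            trials = trials, seed = seed)
}

#' Random softmax probability batch with matching one-hot labels
#'
#' Draws logits from a standard normal, softmaxes over the class axis, and
#' samples labels uniformly. Used by [verify_reductions()] and throughout
#' the test suite; consumes the current RNG stream.
#'
#' @param n Batch size.
#' @param shape Spatial shape (length 2 or 3).
#' @param num_classes Number of classes.
#' @return List with probability array `p` and one-hot array `y`.
#' @export
random_softmax_batch <- function(n = 2L, shape = c(4, 4), num_classes = 2L) {
  d <- c(n, shape, num_classes)
  z <- array(stats::rnorm(prod(d)), dim = d)
  zm <- .as_class_matrix(z)
  ez <- exp(zm - apply(zm, 1, max))
  p <- array(ez / rowSums(ez), dim = d)
  labels <- array(sample.int(num_classes, prod(d[-length(d)]), replace = TRUE) - 1L,
                  dim = d[-length(d)])
  list(p = p, y = one_hot_encode(labels, num_classes))
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("Reduction hierarchy report: %d edges, %d trials, seed %d\n",
              nrow(x), attr(x, "trials"), attr(x, "seed")))
  NextMethod()
}

#' @rdname tidiers
#' @export
tidy.reduction_report <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidiers
#' @export
glance.reduction_report <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x), n_pass = sum(x$pass),
                 all_pass = all(x$pass),
                 worst_abs_diff = max(x$max_abs_diff),
                 trials = attr(x, "trials"), seed = attr(x, "seed"))
}
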