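#' Loss specifications by name
#'
#' A lightweight handle bundling a loss function's name and hyperparameters,
#' used wherever a loss is passed around as data — the benchmark harness,
#' the gamma sweep, the landscape export and the command-line interface.
#'
#' @param name One of `"cross_entropy"`, `"focal"`, `"modified_focal"`,
#'   `"modified_asymmetric_focal"`, `"dice"`, `"tversky"`,
#'   `"focal_tversky"`, `"modified_focal_tversky"`,
#'   `"modified_asymmetric_focal_tversky"`, `"combo"`, `"hybrid_focal"`,
#'   `"unified_focal"`.
#' @param ... Hyperparameters forwarded to the corresponding `loss_*()`
#'   function (e.g. `delta`, `gamma`, `lambda`, `variant`).
#' @param label Optional display label; defaults to `name` (plus the
#'   variant for the Unified Focal loss).
#' @return An object of class `seg_loss_spec`.
#' @examples
#' spec <- seg_loss("unified_focal", variant = "asymmetric",
#'                  lambda = 0.5, delta = 0.6, gamma = 0.5)
#' y <- one_hot_encode(array(c(0, 1), dim = c(1, 2)), 2)
#' p <- array(0.5, dim = c(1, 2, 2))
#' compute_loss(spec, p, y)$value
#' @export
seg_loss <- function(name, ..., label = NULL) {
  if (!name %in% names(.loss_registry)) {
    stop(sprintf("unknown loss '%s'; available: %s", name,
                 paste(names(.loss_registry), collapse = ", ")), call. = FALSE)
  }
  args <- list(...)
  if (is.null(label)) {
    label <- name
    if (name == "unified_focal" && !is.null(args$variant)) {
      label <- paste0("unified_focal_", substr(args$variant, 1, 4))
    }
  }
  structure(list(name = name, args = args, label = label),
            class = "seg_loss_spec")
}

#' @export
print.seg_loss_spec <- function(x, ...) {
  cat(sprintf("<seg_loss_spec> %s", x$label))
  if (length(x$args)) {
    cat("(", paste(names(x$args),
                   vapply(x$args, function(v) paste(format(v), collapse = ","),
                          character(1)),
                   sep = "=", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

.loss_registry <- list(
  cross_entropy = list(fn = function(...) loss_cross_entropy(...),
                       grad = function(...) .grad_cross_entropy(...)),
  focal = list(fn = function(...) loss_focal(...),
               grad = function(...) .grad_focal(...)),
  modified_focal = list(fn = function(...) loss_modified_focal(...),
                        grad = function(...) .grad_modified_focal(...)),
  modified_asymmetric_focal =
    list(fn = function(...) loss_modified_asymmetric_focal(...),
         grad = function(...) .grad_modified_asymmetric_focal(...)),
  dice = list(fn = function(...) loss_dice(...),
              grad = function(...) .grad_dice(...)),
  tversky = list(fn = function(...) loss_tversky(...),
                 grad = function(...) .grad_tversky(...)),
  focal_tversky = list(fn = function(...) loss_focal_tversky(...),
                       grad = function(...) .grad_focal_tversky(...)),
  modified_focal_tversky =
    list(fn = function(...) loss_modified_focal_tversky(...),
         grad = function(...) .grad_modified_focal_tversky(...)),
  modified_asymmetric_focal_tversky =
    list(fn = function(...) loss_modified_asymmetric_focal_tversky(...),
         grad = function(...) .grad_modified_asymmetric_focal_tversky(...)),
  combo = list(fn = function(...) loss_combo(...),
               grad = function(...) .grad_combo(...)),
  hybrid_focal = list(fn = function(...) loss_hybrid_focal(...),
                      grad = function(...) .grad_hybrid_focal(...)),
  unified_focal = list(fn = function(...) loss_unified_focal(...),
                       grad = function(...) .grad_unified_focal(...))
)

#' Evaluate a loss specification on a batch
#'
#' @param spec A [seg_loss()] specification.
#' @param p Probability map `(batch, spatial..., class)`.
#' @param y One-hot labels of the same shape.
#' @return For `compute_loss`, a loss object (see [loss_cross_entropy()]);
#'   for `loss_gradient`, the array `dL/dp` of the same shape as `p`.
#' @export
compute_loss <- function(spec, p, y) {
  stopifnot(inherits(spec, "seg_loss_spec"))
  do.call(.loss_registry[[spec$name]]$fn, c(list(p, y), spec$args))
}

#' @rdname compute_loss
#' @export
loss_gradient <- function(spec, p, y) {
  stopifnot(inherits(spec, "seg_loss_spec"))
  do.call(.loss_registry[[spec$name]]$grad, c(list(p, y), spec$args))
}

#' The conventional benchmark loss set
#'
#' Convenience list of [seg_loss()] specifications at their conventional
#' hyperparameter settings: cross entropy; Focal (`alpha` 0.25, `gamma` 2);
#' Dice; Tversky (0.3/0.7); Focal Tversky (0.3/0.7, `gamma` 4/3); Combo
#' (0.5/0.5); and the symmetric and asymmetric Unified Focal losses
#' (`lambda` 0.5, `delta` 0.6, `gamma` 0.5).
#'
#' @param gamma Focal parameter for the two Unified Focal entries.
#' @return Named list of `seg_loss_spec` objects.
#' @export
standard_losses <- function(gamma = 0.5) {
  list(
    cross_entropy = seg_loss("cross_entropy"),
    focal = seg_loss("focal", alpha = 0.25, gamma = 2),
    dice = seg_loss("dice"),
    tversky = seg_loss("tversky", alpha = 0.3, beta = 0.7),
    focal_tversky = seg_loss("focal_tversky", alpha = 0.3, beta = 0.7,
                             gamma = 4 / 3),
    combo = seg_loss("combo", combo_alpha = 0.5, beta = 0.5),
    unified_focal_sym = seg_loss("unified_focal", variant = "symmetric",
                                 lambda = 0.5, delta = 0.6, gamma = gamma),
    unified_focal_asym = seg_loss("unified_focal", variant = "asymmetric",
                                  lambda = 0.5, delta = 0.6, gamma = gamma)
  )
}
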