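#' Export per-position / per-class loss curves
#'
#' Tabulates, for each supplied loss, the scalar term its components
#' contribute as a function of the quantity they actually depend on: cross
#' entropy-family components are curves over `p_t` (the predicted
#' probability of the true class at one position); Tversky-family
#' components are curves over the (modified) Tversky index of one class.
#' Asymmetric and `delta`-weighted losses contribute separate foreground
#' (rare) and background curves. The grid excludes exact 0 and 1, matching
#' the clipped domain of the array losses.
#'
#' @param losses Named list of [seg_loss()] specifications (default
#'   [standard_losses()]).
#' @param grid_size Number of grid points (>= 10).
#' @return A `landscape_table` tibble: `loss`, `component`
#'   (`"foreground"`/`"background"`/`"all"`), `abscissa` (`"p_t"` or
#'   `"mTI"`), `x`, `value`.
#' @export
loss_landscape <- function(losses = standard_losses(), grid_size = 200) {
  stopifnot(grid_size >= 10)
  x <- seq_len(grid_size) / (grid_size + 1)
  ce_curve <- function(pt) -log(pt)
  rows <- purrr::imap(losses, function(spec, nm) {
    a <- spec$args
    g <- function(default) if (is.null(a$gamma)) default else a$gamma
    d <- function(default) if (is.null(a$delta)) default else a$delta
    lbl <- spec$label
    switch(spec$name,
      cross_entropy = tibble::tibble(loss = lbl, component = "all",
                                     abscissa = "p_t", x = x,
                                     value = ce_curve(x)),
      focal = {
        al <- if (is.null(a$alpha)) 1 else a$alpha[1]
        tibble::tibble(loss = lbl, component = "foreground", abscissa = "p_t",
                       x = x, value = al * (1 - x)^g(2) * ce_curve(x))
      },
      modified_focal = dplyr::bind_rows(
        tibble::tibble(loss = lbl, component = "foreground", abscissa = "p_t",
                       x = x, value = d(0.6) * (1 - x)^g(0.5) * ce_curve(x)),
        tibble::tibble(loss = lbl, component = "background", abscissa = "p_t",
                       x = x, value = (1 - d(0.6)) * (1 - x)^g(0.5) * ce_curve(x))),
      modified_asymmetric_focal = dplyr::bind_rows(
        tibble::tibble(loss = lbl, component = "foreground", abscissa = "p_t",
                       x = x, value = d(0.6) * ce_curve(x)),
        tibble::tibble(loss = lbl, component = "background", abscissa = "p_t",
                       x = x, value = (1 - d(0.6)) * (1 - x)^g(0.5) * ce_curve(x))),
      dice = tibble::tibble(loss = lbl, component = "all", abscissa = "mTI",
                            x = x, value = 1 - x),
      tversky = tibble::tibble(loss = lbl, component = "all", abscissa = "mTI",
                               x = x, value = 1 - x),
      focal_tversky = tibble::tibble(loss = lbl, component = "all",
                                     abscissa = "mTI", x = x,
                                     value = (1 - x)^(1 / g(4 / 3))),
      modified_focal_tversky = tibble::tibble(
        loss = lbl, component = "all", abscissa = "mTI", x = x,
        value = (1 - x)^(1 - g(0.5))),
      modified_asymmetric_focal_tversky = dplyr::bind_rows(
        tibble::tibble(loss = lbl, component = "foreground", abscissa = "mTI",
                       x = x, value = (1 - x)^(1 - g(0.5))),
        tibble::tibble(loss = lbl, component = "background", abscissa = "mTI",
                       x = x, value = 1 - x)),
      unified_focal = {
        variant <- if (is.null(a$variant)) "symmetric" else a$variant
        ce_fg <- if (variant == "asymmetric") d(0.6) * ce_curve(x) else
          d(0.6) * (1 - x)^g(0.5) * ce_curve(x)
        dplyr::bind_rows(
          tibble::tibble(loss = lbl, component = "foreground",
                         abscissa = "p_t", x = x, value = ce_fg),
          tibble::tibble(loss = lbl, component = "background",
                         abscissa = "p_t", x = x,
                         value = (1 - d(0.6)) * (1 - x)^g(0.5) * ce_curve(x)),
          tibble::tibble(loss = lbl, component = "foreground",
                         abscissa = "mTI", x = x,
                         value = (1 - x)^(1 - g(0.5))),
          tibble::tibble(loss = lbl, component = "background",
                         abscissa = "mTI", x = x,
                         value = if (variant == "asymmetric") 1 - x else
                           (1 - x)^(1 - g(0.5))))
      },
      {
        # compound losses without a single-abscissa curve (combo, hybrid):
        # export their CE-side component only
        tibble::tibble(loss = lbl, component = "all", abscissa = "p_t",
                       x = x, value = ce_curve(x))
      })
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("landscape_table", class(out)))
}

# ---- benchmark --------------------------------------------------------------

#' Benchmark a set of losses on a synthetic task
#'
#' For every (loss, seed) pair: initialises and trains the tiny segmenter
#' on the task's training split (validation-loss early stopping), predicts
#' the test split, and records the four hard metrics per class plus the
#' training-curve summary. A run whose loss turns non-finite is flagged
#' `diverged` and reported with the best parameters reached — it never
#' aborts the benchmark.
#'
#' @param losses Named list of [seg_loss()] specifications.
#' @param splits A [split_task()] result (list with `train`, `val`, `test`).
#' @param seeds Integer vector of training seeds.
#' @param spec Optional [tiny_segmenter()] specification.
#' @param ... Passed to [train_segmenter()] (`epochs`, `lr`, ...).
#' @return A `benchmark_result` tibble: one row per (loss, seed, class)
#'   with `dsc`, `iou`, `recall`, `precision`, `epochs_run`, `diverged`,
#'   `best_val_loss`, `wall_time`. `glance()` summarises per loss on the
#'   rarest class.
#' @export
run_benchmark <- function(losses, splits, seeds = 1:3, spec = NULL, ...) {
  stopifnot(is.list(losses), length(losses) >= 1)
  if (is.null(names(losses))) {
    names(losses) <- vapply(losses, `[[`, character(1), "label")
  }
  rows <- list()
  for (nm in names(losses)) {
    for (sd in seeds) {
      t0 <- proc.time()[["elapsed"]]
      fit <- train_segmenter(splits$train, splits$val, losses[[nm]],
                             spec = spec, seed = sd, ...)
      pred <- predict(fit, splits$test$images)
      rep <- evaluate_segmentation(pred, splits$test$masks,
                                   num_classes = splits$test$num_classes)
      wall <- proc.time()[["elapsed"]] - t0
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        rep$summary, loss = nm, seed = sd, epochs_run = fit$epochs_run,
        diverged = fit$diverged, best_val_loss = fit$best_val_loss,
        wall_time = wall, .before = 1)
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("benchmark_result", class(out)))
}

#' @rdname tidiers
#' @export
tidy.benchmark_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidiers
#' @export
glance.benchmark_result <- function(x, ...) {
  rare <- max(x$class)
  dplyr::summarise(
    dplyr::group_by(dplyr::filter(tibble::as_tibble(x), .data$class == rare),
                    .data$loss),
    dsc = mean(.data$dsc, na.rm = TRUE),
    iou = mean(.data$iou, na.rm = TRUE),
    recall = mean(.data$recall, na.rm = TRUE),
    precision = mean(.data$precision, na.rm = TRUE),
    n_seeds = dplyr::n(), n_diverged = sum(.data$diverged),
    .groups = "drop")
}

#' Stability sweep over the Unified Focal focal parameter
#'
#' Trains the tiny segmenter with the Unified Focal loss for every
#' combination of `gamma`, variant and seed, and reports test-split metrics
#' — a desk-scale analogue of sweeping the single remaining hyperparameter
#' over `[0.1, 0.9]` to check that performance is stable in `gamma`.
#'
#' @param gammas Numeric vector of focal parameters in `[0, 1)`. An empty
#'   vector returns an empty result.
#' @param splits A [split_task()] result.
#' @param variants Subset of `c("symmetric", "asymmetric")`.
#' @param seeds Integer vector of training seeds.
#' @param lambda,delta Unified Focal mixing and imbalance weights.
#' @inheritParams run_benchmark
#' @return A `gamma_sweep` tibble: `benchmark_result` columns plus `gamma`
#'   and `variant`.
#' @export
gamma_sweep <- function(gammas = seq(0.1, 0.9, by = 0.1), splits,
                        variants = c("symmetric", "asymmetric"), seeds = 1L,
                        lambda = 0.5, delta = 0.6, spec = NULL, ...) {
  variants <- match.arg(variants, several.ok = TRUE)
  if (length(gammas) == 0) {
    out <- tibble::tibble(gamma = numeric(), variant = character())
    return(structure(out, class = c("gamma_sweep", class(out))))
  }
  if (any(gammas < 0 | gammas >= 1)) {
    stop("all `gammas` must lie in [0, 1)", call. = FALSE)
  }
  grid <- expand.grid(gamma = gammas, variant = variants,
                      stringsAsFactors = FALSE)
  losses <- purrr::pmap(grid, function(gamma, variant) {
    seg_loss("unified_focal", variant = variant, lambda = lambda,
             delta = delta, gamma = gamma,
             label = sprintf("uf_%s_g%.2f", substr(variant, 1, 4), gamma))
  })
  names(losses) <- vapply(losses, `[[`, character(1), "label")
  res <- run_benchmark(losses, splits, seeds = seeds, spec = spec, ...)
  key <- tibble::tibble(loss = names(losses), gamma = grid$gamma,
                        variant = grid$variant)
  out <- dplyr::left_join(tibble::as_tibble(res), key, by = "loss")
  structure(out, class = c("gamma_sweep", "benchmark_result", class(out)))
}
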