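#' Generate a synthetic class-imbalanced segmentation task
#'
#' Produces a seeded batch of image/mask pairs whose foreground prevalence
#' is controlled to a target fraction, emulating the degrees of class
#' imbalance seen in medical segmentation benchmarks (from ~10% foreground
#' for polyps or kidneys down to 0.2% for enhancing brain tumour). The
#' generator places random soft-edged elliptical (2D) or ellipsoidal (3D)
#' blobs, builds a smooth radial field from them, and thresholds the field
#' at the per-image quantile matching `target_fraction`, so the realized
#' prevalence tracks the target closely while the blob boundary remains
#' soft and irregular. Images are the mask plus class-dependent intensity
#' contrast and Gaussian noise, clamped to `[0, 1]`.
#'
#' With `num_classes = 3` the inner (highest-field) part of the foreground
#' is labelled class 2 — a nested rare-inside-rare structure mimicking
#' kidney/tumour style tasks; every class-2 position lies inside the
#' foreground support by construction.
#'
#' @param n_images Number of images.
#' @param shape Spatial shape, length 2 (e.g. `c(64, 64)`) or 3.
#' @param target_fraction Target foreground prevalence in `(0, 0.5)`
#'   (foreground = all classes > 0).
#' @param num_classes 2 (binary) or 3 (nested multiclass).
#' @param seed RNG seed; the same call with the same seed is bit-identical.
#' @param noise_sd Standard deviation of the additive Gaussian image noise.
#' @param contrast Intensity offset of foreground over background (class 2
#'   receives an extra `0.5 * contrast`).
#' @param blob_count Integer range (length 2) of blobs per image.
#' @param nested_fraction For `num_classes = 3`: share of the foreground
#'   assigned to the inner class 2.
#' @return A `synthetic_task`: list with `images` (array
#'   `(n, spatial..., 1)`), `masks` (integer array `(n, spatial...)`),
#'   `target_fraction`, `realized_fraction` (batch mean),
#'   `per_image_fraction`, `seed`, `num_classes` and `spec` (the generation
#'   parameters).
#' @examples
#' task <- generate_task(4, shape = c(32, 32), target_fraction = 0.05, seed = 1)
#' task$realized_fraction
#' @export
generate_task <- function(n_images, shape = c(64, 64), target_fraction = 0.05,
                          num_classes = 2, seed = 1, noise_sd = 0.2,
                          contrast = 0.5, blob_count = c(1L, 3L),
                          nested_fraction = 0.2) {
  if (target_fraction <= 0 || target_fraction >= 0.5) {
    stop("`target_fraction` must lie in (0, 0.5)", call. = FALSE)
  }
  if (!length(shape) %in% 2:3) stop("`shape` must be 2D or 3D", call. = FALSE)
  if (!num_classes %in% 2:3) stop("`num_classes` must be 2 or 3", call. = FALSE)
  npos <- prod(shape)
  if (target_fraction * npos < 1) {
    stop(sprintf(
      "unreachable target_fraction: %.4g of %d positions is below one pixel",
      target_fraction, npos), call. = FALSE)
  }
  set.seed(seed)
  nd <- length(shape)
  masks <- array(0L, dim = c(n_images, shape))
  coords <- .grid_coords(shape)
  for (b in seq_len(n_images)) {
    field <- .blob_field(coords, shape, target_fraction, blob_count)
    thr <- stats::quantile(field, 1 - target_fraction, names = FALSE)
    m <- as.integer(field >= thr)
    if (num_classes == 3) {
      thr2 <- stats::quantile(field, 1 - nested_fraction * target_fraction,
                              names = FALSE)
      m <- m + as.integer(field >= thr2)
    }
    if (nd == 2) masks[b, , ] <- m else masks[b, , , ] <- m
  }
  fg <- apply(masks > 0, 1, mean)
  intensity <- 0.25 + contrast * pmin(masks, 1) + 0.5 * contrast * (masks == 2)
  images <- intensity + stats::rnorm(length(masks), sd = noise_sd)
  images <- array(pmin(pmax(images, 0), 1), dim = c(n_images, shape, 1L))
  structure(list(
    images = images, masks = masks,
    target_fraction = target_fraction,
    realized_fraction = mean(fg), per_image_fraction = fg,
    seed = seed, num_classes = as.integer(num_classes),
    spec = list(shape = shape, noise_sd = noise_sd, contrast = contrast,
                blob_count = blob_count, nested_fraction = nested_fraction)),
    class = "synthetic_task")
}

# per-axis coordinate matrices for a 2D/3D grid, as an npos x ndim matrix
.grid_coords <- function(shape) {
  idx <- as.matrix(expand.grid(lapply(shape, seq_len)))
  # expand.grid varies the first factor fastest, matching column-major order
  unname(idx)
}

# smooth max-of-Gaussians field from randomly placed, randomly oriented
# elliptical blobs whose nominal areas sum to the target area
.blob_field <- function(coords, shape, target_fraction, blob_count) {
  nd <- length(shape)
  k <- sample(seq(blob_count[1], blob_count[2]), 1L)
  area <- target_fraction * prod(shape)
  share <- stats::runif(k, 0.5, 1.5)
  share <- share / sum(share)
  field <- rep(0, nrow(coords))
  for (j in seq_len(k)) {
    r <- if (nd == 2) sqrt(share[j] * area / pi) else
      (3 * share[j] * area / (4 * pi))^(1 / 3)
    ecc <- stats::runif(1, 1, 2)            # axis ratio
    axes <- r * c(ecc, 1 / ecc, 1)[seq_len(nd)]
    centre <- vapply(shape, function(s) stats::runif(1, 0.15 * s, 0.85 * s),
                     numeric(1))
    d <- sweep(coords, 2, centre)
    if (nd == 2) {                           # random rotation in-plane
      th <- stats::runif(1, 0, pi)
      rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      d <- d %*% rot
    }
    m <- rowSums(sweep(d, 2, axes, "/")^2)
    field <- pmax(field, exp(-0.5 * m))
  }
  field
}

#' @export
print.synthetic_task <- function(x, ...) {
  cat(sprintf(
    "<synthetic_task> %d image(s) %s, %d classes, target foreground %.4g, realized %.4g (seed %d)\n",
    dim(x$masks)[1], paste(x$spec$shape, collapse = "x"), x$num_classes,
    x$target_fraction, x$realized_fraction, x$seed))
  invisible(x)
}

# subset the batch axis of an array, keeping all other axes
.subset_batch <- function(a, idx) {
  nd <- length(dim(a))
  do.call(`[`, c(list(a, idx), rep(list(quote(expr = )), nd - 1L),
                 list(drop = FALSE)))
}

.subset_task <- function(task, idx) {
  out <- task
  out$images <- .subset_batch(task$images, idx)
  out$masks <- .subset_batch(task$masks, idx)
  out$per_image_fraction <- task$per_image_fraction[idx]
  out$realized_fraction <- mean(out$per_image_fraction)
  out
}

#' Split a synthetic task into train/validation/test subsets
#'
#' Randomly partitions the images into three disjoint, exhaustive subsets
#' (the conventional 80% development / 20% test layout corresponds to
#' `fractions = c(0.64, 0.16, 0.20)`).
#'
#' @param task A [generate_task()] result.
#' @param fractions Length-3 positive vector summing to 1:
#'   (train, validation, test).
#' @param seed RNG seed for the permutation.
#' @return Named list of three `synthetic_task` objects: `train`, `val`,
#'   `test`.
#' @export
split_task <- function(task, fractions = c(0.64, 0.16, 0.20), seed = 1) {
  stopifnot(inherits(task, "synthetic_task"))
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three positive numbers summing to 1",
         call. = FALSE)
  }
  n <- dim(task$masks)[1]
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- diff(round(cumsum(c(0, fractions)) * n))
  ends <- cumsum(sizes)
  list(train = .subset_task(task, sort(perm[seq_len(ends[1])])),
       val = .subset_task(task, sort(perm[seq(ends[1] + 1, ends[2])])),
       test = .subset_task(task, sort(perm[seq(ends[2] + 1, ends[3])])))
}

#' Benchmark-style class-imbalance regimes
#'
#' The foreground prevalences of five widely used class-imbalanced medical
#' segmentation datasets, as targets for [generate_task()]: colorectal
#' polyp (9.3%), retinal vessel (8.7%), breast tumour (4.8%), enhancing
#' brain tumour (0.2%) and nested kidney/kidney-tumour (10.8% / 0.2%).
#'
#' @return Tibble with columns `regime`, `foreground_pct`,
#'   `target_fraction`, `num_classes`, `nested_fraction`.
#' @export
imbalance_presets <- function() {
  tibble::tibble(
    regime = c("polyp", "retinal_vessel", "breast_tumour",
               "enhancing_brain_tumour", "kidney_with_tumour"),
    foreground_pct = c(9.3, 8.7, 4.8, 0.2, 11.0),
    target_fraction = c(0.093, 0.087, 0.048, 0.002, 0.110),
    num_classes = c(2L, 2L, 2L, 2L, 3L),
    nested_fraction = c(NA, NA, NA, NA, 0.2 / 11))
}

#' Export a synthetic task to image files
#'
#' Writes 2D tasks as paired grayscale PNG files (`image_0001.png`,
#' `mask_0001.png`, masks scaled to full intensity range) and 3D tasks as
#' NIfTI volumes, together with a CSV manifest
#' (`image`, `mask`, `realized_fraction`, `seed`).
#'
#' @param task A `synthetic_task`.
#' @param dir Output directory (created if missing).
#' @param format `"png"` (2D only) or `"nifti"`.
#' @return The manifest tibble, invisibly.
#' @export
export_task <- function(task, dir, format = c("png", "nifti")) {
  stopifnot(inherits(task, "synthetic_task"))
  format <- match.arg(format)
  nd <- length(task$spec$shape)
  if (format == "png" && nd != 2) {
    stop("PNG export is only available for 2D tasks; use format = \"nifti\"",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(task$masks)[1]
  scale <- max(1L, task$num_classes - 1L)
  rows <- lapply(seq_len(n), function(b) {
    if (format == "png") {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("the 'png' package is required for PNG export", call. = FALSE)
      }
      fi <- file.path(dir, sprintf("image_%04d.png", b))
      fm <- file.path(dir, sprintf("mask_%04d.png", b))
      png::writePNG(task$images[b, , , 1], fi)
      png::writePNG(task$masks[b, , ] / scale, fm)
    } else {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        stop("the 'RNifti' package is required for NIfTI export", call. = FALSE)
      }
      fi <- file.path(dir, sprintf("image_%04d.nii.gz", b))
      fm <- file.path(dir, sprintf("mask_%04d.nii.gz", b))
      img <- .subset_batch(task$images, b)
      img <- array(img, dim = dim(img)[2:(nd + 1)])
      msk <- .subset_batch(task$masks, b)
      msk <- array(msk, dim = dim(msk)[2:(nd + 1)])
      RNifti::writeNifti(RNifti::asNifti(img), fi)
      RNifti::writeNifti(RNifti::asNifti(msk), fm)
    }
    tibble::tibble(image = fi, mask = fm,
                   realized_fraction = task$per_image_fraction[b],
                   seed = task$seed)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
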