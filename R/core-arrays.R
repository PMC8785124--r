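#' Core array contracts for probability maps and label masks
#'
#' All losses and metrics in unifocal operate on dense arrays with the
#' layout `(batch, spatial..., class)`: the batch axis first, then one or
#' more spatial axes (2D or 3D), and the class axis last. Background is
#' always class 0 (channel 1 in R's 1-based indexing). Binary problems are
#' represented as two-channel softmax maps, never single-channel sigmoid
#' maps, so every loss is defined once for general C.
#'
#' A *probability map* holds per-position class probabilities (softmax
#' output): entries in \[0,1\] summing to 1 over the class axis at each
#' position. *One-hot labels* share the same shape with exactly one active
#' channel per position.
#'
#' @name core-arrays
#' @keywords internal
NULL

# ---- internal shape helpers -------------------------------------------------

# number of classes = extent of the last axis
.n_classes <- function(x) dim(x)[length(dim(x))]

# number of batch items = extent of the first axis
.n_batch <- function(x) dim(x)[1L]

# number of spatial positions per item
.n_positions <- function(x) {
  d <- dim(x)
  prod(d[-c(1L, length(d))])
}

# flatten (B, S..., C) to a (B*Npos) x C matrix; rows are ordered with the
# batch index fastest, which matches R's column-major layout exactly
.as_class_matrix <- function(x) {
  matrix(x, ncol = .n_classes(x))
}

# collapse a length B*Npos position vector to per-item means / sums
.per_item_mean <- function(v, n_batch) rowMeans(matrix(v, nrow = n_batch))
.per_item_sum  <- function(v, n_batch) rowSums(matrix(v, nrow = n_batch))

.check_prob_label_pair <- function(p, y) {
  if (is.null(dim(p)) || is.null(dim(y))) {
    stop("`p` and `y` must be arrays with layout (batch, spatial..., class)",
         call. = FALSE)
  }
  if (!identical(dim(p), dim(y))) {
    stop(sprintf(
      "shape mismatch: probability map is (%s) but labels are (%s)",
      paste(dim(p), collapse = " x "), paste(dim(y), collapse = " x ")),
      call. = FALSE)
  }
  if (length(dim(p)) < 3L) {
    stop("arrays need at least (batch, one spatial axis, class)", call. = FALSE)
  }
  if (.n_classes(p) < 2L) {
    stop("the class axis must have at least 2 channels (background = class 0)",
         call. = FALSE)
  }
  invisible(TRUE)
}

.check_rare_classes <- function(rare_classes, num_classes) {
  if (length(rare_classes) == 0L) {
    stop("`rare_classes` must contain at least one foreground class index",
         call. = FALSE)
  }
  rc <- as.integer(rare_classes)
  if (any(rc == 0L)) {
    stop("`rare_classes` must not contain the background class 0", call. = FALSE)
  }
  if (any(rc < 1L | rc > num_classes - 1L)) {
    stop(sprintf("`rare_classes` must be a subset of {1..%d}", num_classes - 1L),
         call. = FALSE)
  }
  rc
}

# ---- one-hot encoding -------------------------------------------------------

#' One-hot encode an integer label mask
#'
#' Converts an integer label mask of shape `(batch, spatial...)` into its
#' one-hot representation of shape `(batch, spatial..., num_classes)`, with
#' class labels running from 0 (background) to `num_classes - 1`.
#'
#' @param labels Integer array of shape `(batch, spatial...)`, or a plain
#'   matrix/array for a single image (a batch axis of 1 is added).
#' @param num_classes Number of classes C (>= 2).
#' @return A 0/1 array of shape `(batch, spatial..., num_classes)`; at every
#'   position exactly one class channel is 1.
#' @examples
#' y <- one_hot_encode(array(c(0, 1, 2, 1), dim = c(1, 2, 2)), num_classes = 3)
#' dim(y)
#' @export
one_hot_encode <- function(labels, num_classes) {
  if (num_classes < 2) {
    stop("`num_classes` must be at least 2", call. = FALSE)
  }
  if (is.null(dim(labels))) {
    labels <- array(labels, dim = c(1L, length(labels)))
  }
  lv <- as.integer(round(as.vector(labels)))
  bad <- lv < 0L | lv > num_classes - 1L
  if (any(bad)) {
    stop(sprintf("invalid label %d: labels must lie in [0, %d]",
                 lv[which(bad)[1L]], num_classes - 1L), call. = FALSE)
  }
  out <- vapply(seq_len(num_classes) - 1L,
                function(cl) as.double(lv == cl),
                numeric(length(lv)))
  array(out, dim = c(dim(labels), num_classes))
}

# inverse of one_hot_encode: argmax over the class axis, ties broken toward
# the lower class index (deterministic hard binarization)
.argmax_labels <- function(p) {
  pm <- .as_class_matrix(p)
  lab <- max.col(pm, ties.method = "first") - 1L
  array(lab, dim = dim(p)[-length(dim(p))])
}

# ---- probability clipping ---------------------------------------------------

#' Clip probabilities away from 0 and 1
#'
#' Clamps every entry of a probability map into `[epsilon, 1 - epsilon]`.
#' Applied internally by every loss before taking logarithms, so that empty
#' or perfectly predicted classes cannot produce `log(0)` or unstable
#' ratio-score gradients. After clipping, class probabilities are no longer
#' guaranteed to sum to exactly 1 at each position.
#'
#' Idempotent: clipping twice with the same `epsilon` changes nothing.
#'
#' @param p Numeric array of probabilities.
#' @param epsilon Clip margin, strictly between 0 and 0.5. Default `1e-6`.
#' @return Array of the same shape with entries in `[epsilon, 1 - epsilon]`.
#' @export
clip_probabilities <- function(p, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 0.5) {
    stop("`epsilon` must be a single number in (0, 0.5)", call. = FALSE)
  }
  pmin(pmax(p, epsilon), 1 - epsilon)
}

# ---- confusion counting -----------------------------------------------------

#' Per-class confusion counts for a probability map against one-hot labels
#'
#' Computes per-class, per-batch-item true positives, false positives, false
#' negatives and true negatives. In `"soft"` mode the counts are
#' probability-weighted sums (`tp = sum(p * g)` over positions, etc.) — the
#' differentiable quantities that enter the Tversky index. In `"hard"` mode
#' the map is first binarized by argmax over the class axis (ties toward the
#' lower class index) and the counts are integers summing to the number of
#' spatial positions.
#'
#' @param p Probability map, shape `(batch, spatial..., class)`.
#' @param y One-hot labels of the same shape (see [one_hot_encode()]).
#' @param mode `"soft"` or `"hard"`.
#' @return A tibble with columns `item`, `class` (0-based), `tp`, `fp`,
#'   `fn`, `tn`, `mode`.
#' @examples
#' y <- one_hot_encode(array(c(0, 1, 1, 0), dim = c(1, 2, 2)), 2)
#' p <- array(0.5, dim = dim(y))
#' confusion_counts(p, y, mode = "soft")
#' @export
confusion_counts <- function(p, y, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  .check_prob_label_pair(p, y)
  cc <- .soft_counts(if (mode == "hard") one_hot_encode(.argmax_labels(p), .n_classes(p)) else p, y)
  B <- .n_batch(p); C <- .n_classes(p)
  tibble::tibble(
    item  = rep(seq_len(B), times = C),
    class = rep(seq_len(C) - 1L, each = B),
    tp = as.vector(cc$tp), fp = as.vector(cc$fp),
    fn = as.vector(cc$fn), tn = as.vector(cc$tn),
    mode = mode)
}

# internal: B x C matrices of soft counts; `p` may be a hard one-hot map in
# which case these are the hard counts
.soft_counts <- function(p, y) {
  B <- .n_batch(p); C <- .n_classes(p)
  P <- .as_class_matrix(p)
  G <- .as_class_matrix(y)
  per_class <- function(m) {
    vapply(seq_len(C), function(cl) .per_item_sum(m[, cl], B), numeric(B))
  }
  tp <- per_class(P * G)
  fp <- per_class(P * (1 - G))
  fn <- per_class((1 - P) * G)
  tn <- per_class((1 - P) * (1 - G))
  # vapply drops to a vector when B = 1
  fix <- function(m) matrix(m, nrow = B, ncol = C)
  list(tp = fix(tp), fp = fix(fp), fn = fix(fn), tn = fix(tn))
}
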