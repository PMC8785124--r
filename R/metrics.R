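#' Hard segmentation evaluation metrics
#'
#' Computes the four standard overlap metrics from thresholded (integer
#' label) predictions, per class and per image:
#' DSC `= 2TP/(2TP+FP+FN)`, IoU `= TP/(TP+FP+FN)`,
#' recall `= TP/(TP+FN)` and precision `= TP/(TP+FP)`.
#' Metrics are computed per image and then averaged over the collection
#' (macro averaging, matching per-image reporting conventions); a pooled
#' micro-averaged mode is available. Classes with a zero denominator (e.g.
#' recall of a class absent from the ground truth) are reported as `NA` and
#' excluded from the summary means with a warning — never silently scored 0.
#'
#' @param pred_labels Integer label mask, shape `(batch, spatial...)` (a
#'   single image without a batch axis is also accepted).
#' @param true_labels Integer label mask of the same shape.
#' @param num_classes Number of classes C.
#' @param average `"macro"` (per image, then mean; default) or `"micro"`
#'   (counts pooled over all images before computing metrics).
#' @return A `metric_report`: list with `per_image` (tibble: `image`,
#'   `class`, `tp`, `fp`, `fn`, `tn`, `dsc`, `iou`, `recall`, `precision`)
#'   and `summary` (tibble: `class`, mean metrics, `n_images`). `tidy()`
#'   returns `per_image`, `glance()` the summary.
#' @examples
#' pred <- array(c(1, 1, 1, 0, 0, 0), dim = c(1, 2, 3))
#' truth <- array(c(1, 1, 0, 1, 0, 0), dim = c(1, 2, 3))
#' evaluate_segmentation(pred, truth, num_classes = 2)$summary
#' @export
evaluate_segmentation <- function(pred_labels, true_labels, num_classes,
                                  average = c("macro", "micro")) {
  average <- match.arg(average)
  if (is.null(dim(pred_labels))) pred_labels <- array(pred_labels, c(1L, length(pred_labels)))
  if (is.null(dim(true_labels))) true_labels <- array(true_labels, c(1L, length(true_labels)))
  if (!identical(dim(pred_labels), dim(true_labels))) {
    stop(sprintf("shape mismatch: predictions are (%s) but ground truth is (%s)",
                 paste(dim(pred_labels), collapse = " x "),
                 paste(dim(true_labels), collapse = " x ")), call. = FALSE)
  }
  yp <- one_hot_encode(pred_labels, num_classes)
  yt <- one_hot_encode(true_labels, num_classes)
  cc <- .soft_counts(yp, yt)   # one-hot in, so these are exact hard counts
  B <- dim(yp)[1L]

  per_image <- tibble::tibble(
    image = rep(seq_len(B), times = num_classes),
    class = rep(seq_len(num_classes) - 1L, each = B),
    tp = as.vector(cc$tp), fp = as.vector(cc$fp),
    fn = as.vector(cc$fn), tn = as.vector(cc$tn))
  per_image <- dplyr::mutate(per_image,
    dsc = .safe_ratio(2 * .data$tp, 2 * .data$tp + .data$fp + .data$fn),
    iou = .safe_ratio(.data$tp, .data$tp + .data$fp + .data$fn),
    recall = .safe_ratio(.data$tp, .data$tp + .data$fn),
    precision = .safe_ratio(.data$tp, .data$tp + .data$fp))

  if (average == "macro") {
    if (anyNA(per_image[c("dsc", "iou", "recall", "precision")])) {
      warning("classes with zero denominator excluded from summary means",
              call. = FALSE)
    }
    summary <- dplyr::summarise(
      dplyr::group_by(per_image, .data$class),
      n_images = sum(!is.na(.data$dsc)),
      dsc = mean(.data$dsc, na.rm = TRUE),
      iou = mean(.data$iou, na.rm = TRUE),
      recall = mean(.data$recall, na.rm = TRUE),
      precision = mean(.data$precision, na.rm = TRUE),
      .groups = "drop")
    summary <- dplyr::relocate(summary, "n_images", .after = "precision")
  } else {
    summary <- dplyr::summarise(
      dplyr::group_by(per_image, .data$class),
      tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
      n_images = dplyr::n(), .groups = "drop")
    summary <- dplyr::transmute(summary,
      class = .data$class,
      dsc = .safe_ratio(2 * .data$tp, 2 * .data$tp + .data$fp + .data$fn),
      iou = .safe_ratio(.data$tp, .data$tp + .data$fp + .data$fn),
      recall = .safe_ratio(.data$tp, .data$tp + .data$fn),
      precision = .safe_ratio(.data$tp, .data$tp + .data$fp),
      n_images = .data$n_images)
  }
  structure(list(per_image = per_image, summary = summary,
                 average = average, num_classes = num_classes),
            class = "metric_report")
}

.safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Segmentation metric report (%s-averaged, %d image(s), %d classes)\n",
              x$average, max(x$per_image$image), x$num_classes))
  print(x$summary)
  invisible(x)
}

#' Tidiers for unifocal result objects
#'
#' [generics::tidy()] returns the per-unit tibble (per-image metrics, per
#' reduction edge, per benchmark run); [generics::glance()] a one-row (or
#' per-class) summary.
#'
#' @param x A result object from this package.
#' @param ... Unused.
#' @name tidiers
#' @export
tidy.metric_report <- function(x, ...) x$per_image

#' @rdname tidiers
#' @export
glance.metric_report <- function(x, ...) x$summary

#' Write a metric report to CSV or JSON
#'
#' Serialises the per-image table with stable column names
#' (`image`, `class`, `dsc`, `iou`, `recall`, `precision`, ...), plus the
#' per-class summary on the JSON side.
#'
#' @param x A `metric_report`.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(x, path) {
  stopifnot(inherits(x, "metric_report"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(x$per_image, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(summary = x$summary, per_image = x$per_image),
                         path, dataframe = "rows", digits = NA, pretty = TRUE)
  } else {
    stop("`path` must end in .csv or .json", call. = FALSE)
  }
  invisible(path)
}
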