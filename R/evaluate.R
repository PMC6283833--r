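# Pixel-by-pixel accuracy statistic, per-class tables, paired-t comparison
# of augmentation modes, and tiled whole-image quantification.
#
# The accuracy of a classifier over N_ROI test patches of N_x x N_y pixels
# is the fraction of pixels classified into the correct class, times 100:
# Accuracy = 100 / (N_x N_y N_ROI) * sum_ijk [pred_ijk == true_ijk].

as_label_list <- function(x) {
  if (is.matrix(x)) list(x) else x
}

#' Pixel-by-pixel classification accuracy (%)
#'
#' @param predicted,truth Integer label matrices, or lists of matrices of
#'   matching shapes (one per test patch).
#' @return Percentage of pixels whose predicted class equals the reference
#'   class, in `[0, 100]`.
#' @export
pixel_accuracy <- function(predicted, truth) {
  p <- as_label_list(predicted)
  t <- as_label_list(truth)
  if (length(p) != length(t)) stop("prediction/truth counts differ", call. = FALSE)
  correct <- 0
  total <- 0
  for (i in seq_along(p)) {
    if (!identical(dim(p[[i]]), dim(t[[i]]))) {
      stop(sprintf("shape mismatch at patch %d", i), call. = FALSE)
    }
    correct <- correct + sum(p[[i]] == t[[i]])
    total <- total + length(t[[i]])
  }
  100 * correct / total
}

#' Per-class pixel accuracy table
#'
#' Class c's accuracy is computed over all pixels whose true label is c; the
#' mean is over all pixels. A class absent from the truth is reported as
#' `NA` (undefined), never as 0. The per-patch accuracies allow paired
#' comparisons between classifiers on identical test patches.
#'
#' @param predictions,truths Lists of integer label matrices (one per test
#'   patch), matching shapes.
#' @return An object of class `evaluation_report`: `per_roi_accuracy`,
#'   `per_class_accuracy` (named, `NA` = undefined), `mean_accuracy`,
#'   `n_rois`, `patch_dims`.
#' @export
per_class_table <- function(predictions, truths) {
  p <- as_label_list(predictions)
  t <- as_label_list(truths)
  if (length(p) != length(t) || length(p) == 0L) {
    stop("predictions and truths must be non-empty lists of equal length", call. = FALSE)
  }
  per_roi <- vapply(seq_along(p), function(i) pixel_accuracy(p[[i]], t[[i]]), numeric(1L))
  pv <- unlist(lapply(p, as.vector))
  tv <- unlist(lapply(t, as.vector))
  cls <- ptex_classes()
  per_class <- vapply(cls, function(code) {
    sel <- tv == code
    if (!any(sel)) NA_real_ else 100 * mean(pv[sel] == tv[sel])
  }, numeric(1L))
  structure(list(per_roi_accuracy = per_roi,
                 per_class_accuracy = per_class,
                 mean_accuracy = 100 * mean(pv == tv),
                 n_rois = length(p),
                 patch_dims = dim(p[[1L]])),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d ROIs of %d x %d\n",
              x$n_rois, x$patch_dims[1L], x$patch_dims[2L]))
  for (nm in names(x$per_class_accuracy)) {
    v <- x$per_class_accuracy[[nm]]
    cat(sprintf("  %-14s %s\n", nm, if (is.na(v)) "undefined" else sprintf("%5.1f%%", v)))
  }
  cat(sprintf("  %-14s %5.1f%%\n", "mean", x$mean_accuracy))
  invisible(x)
}

#' Paired t-test on per-patch accuracies of two classifiers
#'
#' Standard paired t statistic and two-sided p-value on the per-patch
#' accuracy differences (pairing by identical test patch). Degenerate cases
#' are flagged rather than crashing: all-zero differences give t = 0,
#' p = 1; nonzero constant differences give an infinite t with p = 0.
#'
#' @param acc_a,acc_b Equal-length (>= 2) numeric vectors of per-patch
#'   accuracies.
#' @return An object of class `paired_comparison`: `t_statistic`, `p_value`,
#'   `df`, `mean_difference`, `degenerate` flag, and the inputs.
#' @export
paired_t <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("paired lists must have equal length", call. = FALSE)
  n <- length(acc_a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- acc_a - acc_b
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    if (all(d == 0)) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(accuracies_a = acc_a, accuracies_b = acc_b,
                 t_statistic = t_stat, p_value = p, df = n - 1L,
                 mean_difference = mean(d), degenerate = degenerate),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> n = %d pairs, mean difference %.3f\n",
              length(x$accuracies_a), x$mean_difference))
  cat(sprintf("  t = %.4g, df = %d, p = %.4g%s\n", x$t_statistic, x$df, x$p_value,
              if (x$degenerate) " (degenerate: zero-variance differences)" else ""))
  invisible(x)
}

#' Tiled whole-image quantification
#'
#' Slides a `tile` x `tile` window over the image with the given stride
#' (windows are clamped so the full image is covered), predicts per-pixel
#' class probabilities for every window, sums the softmax probabilities of
#' overlapping windows at each pixel and takes the argmax. Pixels outside
#' `foreground_mask` are labeled `NA` ("ignore") and must be excluded from
#' any accuracy computation.
#'
#' `model` can be any object for which `predict_patch(model, matrix)` (or
#' `predict(model, matrix)`) returns a list with a `probs` array.
#'
#' @param model A `ptex_model`/`ptex_fit`, or any classifier exposing the
#'   predict contract above.
#' @param image Numeric intensity matrix.
#' @param foreground_mask Logical matrix of the image's shape; at least one
#'   `TRUE` pixel.
#' @param tile Window side length (default 20), at most the image dims.
#' @param stride Window step (default `tile / 2`, floored, at least 1).
#' @return Integer label matrix with `NA` outside the foreground.
#' @export
tile_quantify <- function(model, image, foreground_mask, tile = 20L,
                          stride = max(1L, tile %/% 2L)) {
  image <- as.matrix(image)
  H <- nrow(image); W <- ncol(image)
  if (!identical(dim(foreground_mask), dim(image))) {
    stop("foreground_mask must match the image shape", call. = FALSE)
  }
  if (!any(foreground_mask)) stop("foreground_mask is empty", call. = FALSE)
  if (tile > H || tile > W) stop("tile exceeds image dimensions", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  starts <- function(n) unique(pmin(seq(1L, n, by = stride), n - tile + 1L))
  pred_fun <- if (inherits(model, "ptex_fit")) {
    function(m) predict(model, m)
  } else if (inherits(model, "ptex_model")) {
    function(m) predict_patch(model, m)
  } else {
    function(m) stats::predict(model, m)
  }
  n_classes <- NULL
  votes <- NULL
  for (r0 in starts(H)) for (c0 in starts(W)) {
    win <- image[r0:(r0 + tile - 1L), c0:(c0 + tile - 1L)]
    pr <- pred_fun(win)$probs
    if (is.null(votes)) {
      n_classes <- dim(pr)[3L]
      votes <- array(0, c(H, W, n_classes))
    }
    votes[r0:(r0 + tile - 1L), c0:(c0 + tile - 1L), ] <-
      votes[r0:(r0 + tile - 1L), c0:(c0 + tile - 1L), , drop = FALSE] + pr
  }
  flat <- matrix(votes, H * W, n_classes)
  labels <- matrix(max.col(flat, ties.method = "first") - 1L, H, W)
  labels[!foreground_mask] <- NA_integer_
  labels
}
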