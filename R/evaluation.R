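#' Evaluate link predictions against labels
#'
#' Computes the benchmark metrics for thresholded link predictions:
#' overall accuracy, F1 on the positive class, the false-positive ratio
#' among the top-scoring fraction of predictions (default top 10%), and the
#' distribution of true/false predictions over the five fixed score ranges
#' `[0,0.2) [0.2,0.4) [0.4,0.6) [0.6,0.8) [0.8,1]` (half-open bins, the last
#' closed). Unscorable pairs are excluded from every denominator and counted
#' separately. Accuracy on sampled-negative benchmarks can be underestimated
#' when unrevealed true links lurk among the negatives; no correction is
#' applied.
#'
#' @param predictions Tibble from [predict_links()] with a `label` column.
#' @param top_fraction Fraction of highest-scoring predictions for the
#'   false-positive ratio (default 0.10). Ties at the cutoff are broken by
#'   score descending, then `tf_id`, `target_id`.
#' @return A `pixlink_eval` list: `accuracy`, `f1`, `precision`, `recall`,
#'   `top_fraction_fp_ratio`, `top_fraction`, `histogram` tibble
#'   (`bin`, `n_true`, `n_false`), `n_scorable`, `n_unscorable`, `notes`.
#' @export
evaluate_predictions <- function(predictions, top_fraction = 0.10) {
  stopifnot("label" %in% names(predictions))
  p <- dplyr::filter(predictions, .data$scorable)
  if (nrow(p) == 0) stop("no scorable predictions to evaluate")
  notes <- character(0)

  correct <- p$decision == (p$label == 1)
  accuracy <- mean(correct)
  tp <- sum(p$decision & p$label == 1)
  fp <- sum(p$decision & p$label == 0)
  fn <- sum(!p$decision & p$label == 1)
  if (tp + fp == 0) {
    precision <- 0
    f1 <- 0
    notes <- c(notes, "no predicted positives; F1 defined as 0")
  } else {
    precision <- tp / (tp + fp)
    f1 <- if (tp == 0) 0 else 2 * precision * (tp / (tp + fn)) /
      (precision + tp / (tp + fn))
  }
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)

  n_top <- ceiling(top_fraction * nrow(p))
  ord <- order(-p$score, p$tf_id, p$target_id)
  top <- p[ord[seq_len(n_top)], ]
  top_fp_ratio <- mean(top$label == 0)

  breaks <- c(0, 0.2, 0.4, 0.6, 0.8, 1.0)
  bin_of <- findInterval(p$score, breaks, rightmost.closed = TRUE)
  bin_labels <- c("[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)",
                  "[0.8,1]")
  n_true <- vapply(1:5, function(b) sum(bin_of == b & correct), integer(1))
  n_false <- vapply(1:5, function(b) sum(bin_of == b & !correct), integer(1))
  histogram <- tibble::tibble(bin = bin_labels, n_true = n_true,
                              n_false = n_false)

  structure(list(
    accuracy = accuracy, f1 = f1, precision = precision, recall = recall,
    top_fraction_fp_ratio = top_fp_ratio, top_fraction = top_fraction,
    n_top = n_top,
    histogram = histogram,
    n_scorable = nrow(p),
    n_unscorable = sum(!predictions$scorable),
    notes = notes
  ), class = "pixlink_eval")
}

#' @export
print.pixlink_eval <- function(x, ...) {
  cat(sprintf(
    "<pixlink_eval> accuracy %.3f, F1 %.3f, top-%d%% FP ratio %.3f (%d scorable, %d unscorable)\n",
    x$accuracy, x$f1, round(100 * x$top_fraction), x$top_fraction_fp_ratio,
    x$n_scorable, x$n_unscorable))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x A `pixlink_eval`.
#' @param ... Unused.
#' @export
glance.pixlink_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, f1 = x$f1, precision = x$precision,
                 recall = x$recall,
                 top_fraction_fp_ratio = x$top_fraction_fp_ratio,
                 n_scorable = x$n_scorable, n_unscorable = x$n_unscorable)
}

#' @rdname evaluate_predictions
#' @export
tidy.pixlink_eval <- function(x, ...) x$histogram

#' Plot the true/false prediction distribution over score ranges
#'
#' @param object A `pixlink_eval`.
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @export
autoplot.pixlink_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$histogram, c("n_true", "n_false"),
                              names_to = "outcome", values_to = "n")
  long$outcome <- ifelse(long$outcome == "n_true", "true", "false")
  long$bin <- factor(long$bin, levels = object$histogram$bin)
  ggplot2::ggplot(long, ggplot2::aes(.data$bin, .data$n,
                                     fill = .data$outcome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "output range", y = "predictions", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Hit ratio on an all-positive link set
#'
#' For an independent link set in which every pair is a true link (e.g. a
#' partial-evidence network used as external validation), the hit ratio is
#' the fraction of scorable links the classifier decides positive. The
#' breakdown reports, among the hits, the fractions whose scores exceed 0.8
#' and 0.6 (strict inequalities).
#'
#' @param predictions Prediction tibble from [predict_links()].
#' @return List: `hit_ratio`, `n_hits`, `n_scorable`, `frac_hits_gt_0.8`,
#'   `frac_hits_gt_0.6`.
#' @export
hit_ratio <- function(predictions) {
  p <- dplyr::filter(predictions, .data$scorable)
  if (nrow(p) == 0) stop("no scorable predictions")
  hits <- p[p$decision, ]
  list(
    hit_ratio = nrow(hits) / nrow(p),
    n_hits = nrow(hits),
    n_scorable = nrow(p),
    frac_hits_gt_0.8 = if (nrow(hits)) mean(hits$score > 0.8) else NA_real_,
    frac_hits_gt_0.6 = if (nrow(hits)) mean(hits$score > 0.6) else NA_real_
  )
}
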