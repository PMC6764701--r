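#' Aggregate instance scores into a link score
#'
#' The link score for a TF-target pair is the arithmetic mean of the
#' classifier probabilities over *all* enumerated image-pair instances,
#' pooled across the three orientations — the numerator sums every instance
#' probability and the denominator is the total instance count
#' `sum over orientations of |X_tf,o| * |X_target,o|`. The decision applies
#' the threshold with a `>=` convention, so a score exactly at the threshold
#' is called positive.
#'
#' @param instance_scores Numeric vector of per-instance probabilities in
#'   `[0, 1]` (any orientation order; the mean is permutation invariant).
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble: `score`, `decision`, `n_instances`, `scorable`,
#'   `threshold_used`. An empty score vector yields `scorable = FALSE` with
#'   `NA` score and decision — never a silent 0.
#' @export
aggregate_scores <- function(instance_scores, threshold = 0.5) {
  if (length(instance_scores) == 0) {
    return(tibble::tibble(score = NA_real_, decision = NA,
                          n_instances = 0L, scorable = FALSE,
                          threshold_used = threshold))
  }
  if (any(instance_scores < 0 | instance_scores > 1))
    stop("instance scores must lie in [0, 1]")
  s <- mean(instance_scores)
  tibble::tibble(score = s, decision = s >= threshold,
                 n_instances = length(instance_scores), scorable = TRUE,
                 threshold_used = threshold)
}

#' Predict regulatory links for labelled gene pairs
#'
#' Scores every orientation-matched image-pair instance of each gene pair in
#' evaluation mode and averages them into one link probability per pair.
#' Pairs whose genes share no non-empty orientation are returned with
#' `scorable = FALSE` and excluded from metric denominators downstream.
#'
#' @param model A trained `pixlink_model`.
#' @param pairs Labelled pair tibble (columns `tf_id`, `target_id`, and
#'   optionally `label`, `split`).
#' @param images Image tibble covering every gene in `pairs`.
#' @param threshold Decision threshold (default 0.5).
#' @return Tibble with one row per pair: `tf_id`, `target_id`, `label` (if
#'   supplied), `score`, `decision`, `n_instances`, `scorable`,
#'   `threshold_used`.
#' @export
predict_links <- function(model, pairs, images, threshold = 0.5) {
  known <- unique(images$gene_id)
  missing <- setdiff(unique(c(pairs$tf_id, pairs$target_id)), known)
  if (length(missing))
    stop("pair references gene(s) with no images: ",
         paste(missing, collapse = ", "))
  inst <- enumerate_instances(pairs, images)
  scored <- if (nrow(inst)) score_instances(model, inst, images) else
    dplyr::mutate(inst, score = numeric(0))
  agg <- lapply(seq_len(nrow(pairs)), function(i)
    aggregate_scores(scored$score[scored$pair_id == i], threshold))
  out <- dplyr::bind_cols(pairs, dplyr::bind_rows(agg))
  class(out) <- c("pixlink_predictions", class(out))
  out
}

#' Write / read link predictions as TSV
#'
#' @param predictions Prediction tibble from [predict_links()].
#' @param path TSV destination.
#' @return `write_predictions()`: the path invisibly; `read_predictions()`:
#'   the tibble.
#' @export
write_predictions <- function(predictions, path) {
  df <- as.data.frame(predictions)
  df$score <- sprintf("%.17g", df$score)  # round-trip exact
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
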