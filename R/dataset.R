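#' Load an image corpus from disk
#'
#' Reads the manifest written by [write_corpus()] (or assembled by hand for
#' user-prepared corpora) and loads every referenced PNG/JPEG-style image as a
#' grayscale matrix. Images are grouped per gene and orientation in manifest
#' order; all images must share one frame size.
#'
#' @param dir Corpus directory containing the manifest and image files.
#' @param manifest Manifest path; default `<dir>/manifest.json`. A JSON array
#'   of rows with fields `file`, `gene_id`, `orientation`.
#' @return Tibble with columns `gene_id`, `orientation`, `replicate`, `image`
#'   (list-column of matrices in `[0, 1]`).
#' @export
load_corpus <- function(dir, manifest = file.path(dir, "manifest.json")) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  rows <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (length(rows) == 0 || nrow(rows) == 0) {
    return(tibble::tibble(gene_id = character(), orientation = character(),
                          replicate = integer(), image = list()))
  }
  bad_o <- setdiff(unique(rows$orientation), px_orientations)
  if (length(bad_o)) {
    i <- which(rows$orientation %in% bad_o)[1]
    stop(sprintf("manifest row %d: unknown orientation '%s'", i,
                 rows$orientation[i]))
  }
  imgs <- vector("list", nrow(rows))
  dims <- NULL
  for (i in seq_len(nrow(rows))) {
    path <- file.path(dir, rows$file[i])
    if (!file.exists(path))
      stop(sprintf("manifest row %d: missing file %s", i, path))
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]  # grayscale channel
    if (is.null(dims)) dims <- dim(img)
    if (!identical(dim(img), dims))
      stop(sprintf("manifest row %d: image dimensions %s differ from %s", i,
                   paste(dim(img), collapse = "x"),
                   paste(dims, collapse = "x")))
    imgs[[i]] <- img
  }
  out <- tibble::tibble(
    gene_id = rows$gene_id, orientation = rows$orientation, image = imgs)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$gene_id, .data$orientation),
    replicate = dplyr::row_number())
  dplyr::select(dplyr::ungroup(out), "gene_id", "orientation", "replicate",
                "image")
}

#' Summarise per-gene image sets
#'
#' @param images Image tibble from [load_corpus()] or a corpus's `$images`.
#' @return Tibble with one row per gene: `gene_id`, `n_lateral`, `n_ventral`,
#'   `n_dorsal`, `n_total`.
#' @export
gene_image_sets <- function(images) {
  counts <- dplyr::count(images, .data$gene_id, .data$orientation)
  wide <- tidyr::pivot_wider(counts, names_from = "orientation",
                             values_from = "n", values_fill = 0L)
  for (o in px_orientations) if (!o %in% names(wide)) wide[[o]] <- 0L
  dplyr::transmute(wide, gene_id = .data$gene_id,
                   n_lateral = .data$lateral, n_ventral = .data$ventral,
                   n_dorsal = .data$dorsal,
                   n_total = .data$lateral + .data$ventral + .data$dorsal)
}

#' Read a TSV edge list
#'
#' @param path TSV file with header columns `tf_id` and `target_id`.
#' @return Tibble of `tf_id`, `target_id`.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf_id", "target_id") %in% names(df)))
    stop("edge list must have columns tf_id and target_id: ", path)
  tibble::as_tibble(df[, c("tf_id", "target_id")])
}

#' Sample negative TF-target pairs
#'
#' Draws negatives uniformly without replacement from the TF x gene universe,
#' excluding the positive edges, an exclusion network (e.g. links with
#' partial evidence, which must not be labelled negative), and self pairs.
#' The customary design is a 1:1 positive-to-negative ratio.
#'
#' @param tf_universe Character vector of TF ids.
#' @param gene_universe Character vector of candidate target ids.
#' @param positives Tibble of `tf_id`, `target_id` positive links.
#' @param exclusion Tibble of pairs that may be neither positive nor
#'   negative; default empty.
#' @param ratio Negatives per positive (default 1).
#' @param seed Sampling seed.
#' @return Tibble of `tf_id`, `target_id`, `label = 0`,
#'   `provenance = "sampled_negative"`.
#' @export
sample_negatives <- function(tf_universe, gene_universe, positives,
                             exclusion = NULL, ratio = 1, seed = 1L) {
  n_wanted <- ceiling(ratio * nrow(positives))
  if (n_wanted == 0)
    return(tibble::tibble(tf_id = character(), target_id = character(),
                          label = integer(), provenance = character()))
  pool <- tidyr::expand_grid(tf_id = tf_universe, target_id = gene_universe)
  pool <- dplyr::filter(pool, .data$tf_id != .data$target_id)
  pool <- dplyr::anti_join(pool, positives, by = c("tf_id", "target_id"))
  if (!is.null(exclusion) && nrow(exclusion) > 0)
    pool <- dplyr::anti_join(pool, exclusion, by = c("tf_id", "target_id"))
  if (nrow(pool) < n_wanted)
    stop(sprintf(
      "cannot sample %d negatives: only %d non-excluded pairs available",
      n_wanted, nrow(pool)))
  withr::with_seed(seed, {
    picked <- pool[sample.int(nrow(pool), n_wanted), ]
  })
  dplyr::mutate(dplyr::arrange(picked, .data$tf_id, .data$target_id),
                label = 0L, provenance = "sampled_negative")
}

#' Assemble labelled gene pairs from positive and negative edge sets
#'
#' @param positives Tibble of `tf_id`, `target_id`.
#' @param negatives Tibble as returned by [sample_negatives()].
#' @param provenance_pos Provenance tag for positives.
#' @return Tibble of `tf_id`, `target_id`, `label`, `provenance`.
#' @export
make_pairs <- function(positives, negatives,
                       provenance_pos = "high_confidence") {
  pos <- dplyr::mutate(positives[, c("tf_id", "target_id")],
                       label = 1L, provenance = provenance_pos)
  dplyr::bind_rows(pos, negatives)
}

#' Split labelled pairs at gene level
#'
#' The gene universe (TFs and targets together) is partitioned into
#' train-genes and test-genes, so that images of one gene can never appear on
#' both sides. A pair is a training pair iff both endpoints are train-genes
#' and a test pair iff both are test-genes; mixed pairs are dropped and
#' counted. Because pairs have two endpoints, the gene-level fraction is set
#' to `sqrt(r) / (sqrt(r) + sqrt(1 - r))` so the expected *pair-level*
#' training fraction equals `train_frac`; partitions are re-drawn until the
#' achieved pair fraction is within `tol` of the request. Validation pairs
#' are then split off the training pairs at pair level (their genes stay on
#' the training side).
#'
#' @param pairs Labelled pair tibble from [make_pairs()].
#' @param train_frac Desired pair-level training(+validation) fraction
#'   (default 0.8, i.e. a 4:1 train:test ratio).
#' @param val_frac_of_train Fraction of training pairs held out for
#'   validation (default 0.1).
#' @param seed Split seed.
#' @param tol Tolerance on the achieved pair-level training fraction.
#' @param max_tries Partition re-draws before giving up.
#' @return A `pixlink_split`: list with tibbles `train_pairs`, `val_pairs`,
#'   `test_pairs` (each with a `split` column), `train_genes`, `test_genes`,
#'   `dropped_pairs` count, `achieved` fractions, and the seed.
#' @export
split_by_gene <- function(pairs, train_frac = 0.8, val_frac_of_train = 0.1,
                          seed = 1L, tol = 0.06, max_tries = 200L) {
  stopifnot(train_frac > 0, train_frac < 1)
  genes <- sort(unique(c(pairs$tf_id, pairs$target_id)))
  r <- train_frac
  gene_frac <- sqrt(r) / (sqrt(r) + sqrt(1 - r))
  n_train_genes <- max(1L, min(length(genes) - 1L,
                               round(gene_frac * length(genes))))
  best <- NULL
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      train_genes <- sort(sample(genes, n_train_genes))
      test_genes <- setdiff(genes, train_genes)
      side_tf <- pairs$tf_id %in% train_genes
      side_tg <- pairs$target_id %in% train_genes
      is_train <- side_tf & side_tg
      is_test <- (!side_tf) & (!side_tg)
      n_kept <- sum(is_train) + sum(is_test)
      if (n_kept == 0) next
      frac <- sum(is_train) / n_kept
      cand <- list(train_genes = train_genes, test_genes = test_genes,
                   is_train = is_train, is_test = is_test, frac = frac)
      if (is.null(best) || abs(frac - train_frac) < abs(best$frac - train_frac))
        best <- cand
      if (abs(frac - train_frac) <= tol) break
    }
    if (is.null(best) || abs(best$frac - train_frac) > tol)
      stop(sprintf(paste(
        "gene-level split failed: best achieved pair-level train fraction",
        "%.3f vs requested %.3f (tol %.3f) after %d tries"),
        if (is.null(best)) NA_real_ else best$frac, train_frac, tol,
        max_tries))
    train_all <- pairs[best$is_train, ]
    test_pairs <- pairs[best$is_test, ]
    n_val <- round(val_frac_of_train * nrow(train_all))
    val_idx <- if (n_val > 0) sample.int(nrow(train_all), n_val) else integer(0)
  })
  val_pairs <- train_all[sort(val_idx), ]
  train_pairs <- train_all[setdiff(seq_len(nrow(train_all)), val_idx), ]
  structure(list(
    train_pairs = dplyr::mutate(train_pairs, split = "train"),
    val_pairs = dplyr::mutate(val_pairs, split = "val"),
    test_pairs = dplyr::mutate(test_pairs, split = "test"),
    train_genes = best$train_genes, test_genes = best$test_genes,
    dropped_pairs = nrow(pairs) - nrow(train_all) - nrow(test_pairs),
    achieved = list(
      pair_train_frac = best$frac,
      val_frac_of_train = if (nrow(train_all)) length(val_idx) /
        nrow(train_all) else 0),
    seed = as.integer(seed)
  ), class = "pixlink_split")
}

#' @export
print.pixlink_split <- function(x, ...) {
  cat(sprintf(
    "<pixlink_split> train %d / val %d / test %d pairs (dropped %d mixed);\n",
    nrow(x$train_pairs), nrow(x$val_pairs), nrow(x$test_pairs),
    x$dropped_pairs))
  cat(sprintf("  pair-level train fraction %.3f, val fraction %.3f, seed %d\n",
              x$achieved$pair_train_frac, x$achieved$val_frac_of_train,
              x$seed))
  invisible(x)
}

#' Split report as a list ready for JSON serialisation
#' @param split A `pixlink_split`.
#' @return List of counts, achieved fractions, gene partition and seed.
#' @export
split_report <- function(split) {
  list(
    n_train_pairs = nrow(split$train_pairs),
    n_val_pairs = nrow(split$val_pairs),
    n_test_pairs = nrow(split$test_pairs),
    dropped_pairs = split$dropped_pairs,
    pair_train_frac = split$achieved$pair_train_frac,
    val_frac_of_train = split$achieved$val_frac_of_train,
    train_genes = split$train_genes,
    test_genes = split$test_genes,
    seed = split$seed
  )
}

#' Enumerate orientation-matched image-pair instances
#'
#' Reduces each labelled gene pair (two variable-size image sets) to
#' single-image instances: the full cross product of the TF's and the
#' target's images within each orientation. Every instance inherits the
#' pair's label. The number of instances for a pair is therefore
#' `sum over orientations of |X_tf,o| * |X_target,o|`; pairs with no shared
#' non-empty orientation yield zero instances and are flagged unscorable
#' downstream. The TF image is by contract the *first* (top) element of every
#' instance — classifier inputs are order-sensitive.
#'
#' @param pairs Labelled pair tibble (columns `tf_id`, `target_id`, `label`,
#'   optionally `split`).
#' @param images Image tibble (from [load_corpus()] or a corpus's `$images`).
#' @return Instance tibble: `pair_id`, `tf_id`, `target_id`, `orientation`,
#'   `tf_row`, `target_row` (row indices into `images`), `label` and any
#'   carried pair columns.
#' @export
enumerate_instances <- function(pairs, images) {
  img_idx <- dplyr::mutate(images[, c("gene_id", "orientation")],
                           row = dplyr::row_number())
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    tf_rows <- img_idx[img_idx$gene_id == p$tf_id, ]
    tg_rows <- img_idx[img_idx$gene_id == p$target_id, ]
    inst <- NULL
    for (o in px_orientations) {
      a <- tf_rows$row[tf_rows$orientation == o]
      b <- tg_rows$row[tg_rows$orientation == o]
      if (length(a) == 0 || length(b) == 0) next
      grid <- tidyr::expand_grid(tf_row = a, target_row = b)
      grid$orientation <- o
      inst <- dplyr::bind_rows(inst, grid)
    }
    if (is.null(inst)) next
    inst$pair_id <- i
    inst$tf_id <- p$tf_id
    inst$target_id <- p$target_id
    inst$label <- p$label
    if ("split" %in% names(p)) inst$split <- p$split
    out[[i]] <- inst
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(pair_id = integer(), tf_id = character(),
                          target_id = character(), orientation = character(),
                          tf_row = integer(), target_row = integer(),
                          label = integer()))
  }
  cols <- c("pair_id", "tf_id", "target_id", "orientation", "tf_row",
            "target_row", "label")
  dplyr::select(res, dplyr::all_of(cols), dplyr::everything())
}

#' Expected instance count per pair
#'
#' The identity `n_instances = sum over orientations of
#' |X_tf,o| * |X_target,o|`, computed from image counts alone (used as the
#' denominator of the link-score mean and as a cross-check on
#' [enumerate_instances()]).
#'
#' @inheritParams enumerate_instances
#' @return `pairs` with an `n_instances` column appended.
#' @export
expected_instance_counts <- function(pairs, images) {
  sets <- gene_image_sets(images)
  lut <- function(ids, col) {
    v <- sets[[col]][match(ids, sets$gene_id)]
    dplyr::coalesce(v, 0L)
  }
  n <- lut(pairs$tf_id, "n_lateral") * lut(pairs$target_id, "n_lateral") +
    lut(pairs$tf_id, "n_ventral") * lut(pairs$target_id, "n_ventral") +
    lut(pairs$tf_id, "n_dorsal") * lut(pairs$target_id, "n_dorsal")
  dplyr::mutate(pairs, n_instances = as.integer(n))
}
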