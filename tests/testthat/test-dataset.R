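write_mini_manifest <- function(dir, rows) {
  dir.create(file.path(dir, "images"), showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(rows))) {
    png::writePNG(matrix(runif(32 * 16), 16, 32),
                  file.path(dir, rows$file[i]))
  }
  jsonlite::write_json(rows, file.path(dir, "manifest.json"),
                       dataframe = "rows")
  invisible(dir)
}

test_that("load_corpus groups images per gene and orientation", {
  dir <- withr::local_tempdir()
  rows <- tibble::tibble(
    file = file.path("images", sprintf("img%d.png", 1:3)),
    gene_id = "A",
    orientation = c("lateral", "lateral", "dorsal"))
  write_mini_manifest(dir, rows)
  images <- load_corpus(dir)
  counts <- gene_image_sets(images)
  expect_identical(counts$n_lateral, 2L)
  expect_identical(counts$n_ventral, 0L)
  expect_identical(counts$n_dorsal, 1L)
})

test_that("load_corpus rejects bad manifests with the offending row", {
  dir <- withr::local_tempdir()
  rows <- tibble::tibble(file = file.path("images", "a.png"),
                         gene_id = "A", orientation = "frontal")
  write_mini_manifest(dir, rows)
  expect_error(load_corpus(dir), "unknown orientation 'frontal'")

  dir2 <- withr::local_tempdir()
  rows2 <- tibble::tibble(file = file.path("images", "b.png"),
                          gene_id = "A", orientation = "lateral")
  jsonlite::write_json(rows2, file.path(dir2, "manifest.json"),
                       dataframe = "rows")
  expect_error(load_corpus(dir2), "missing file")
})

test_that("negative sampling honours ratio, exclusions and determinism", {
  tfs <- sprintf("TF%02d", 1:3)
  genes <- sprintf("G%03d", 1:10)
  positives <- tibble::tibble(tf_id = rep(tfs, c(4, 3, 3)),
                              target_id = genes)
  exclusion <- tibble::tibble(tf_id = "TF01", target_id = c("G005", "G006"))
  negs <- sample_negatives(tfs, genes, positives, exclusion,
                           ratio = 1, seed = 42)
  expect_identical(nrow(negs), 10L)
  expect_identical(nrow(dplyr::inner_join(negs, positives,
                                          by = c("tf_id", "target_id"))), 0L)
  expect_identical(nrow(dplyr::inner_join(negs, exclusion,
                                          by = c("tf_id", "target_id"))), 0L)
  expect_true(all(negs$tf_id != negs$target_id))
  expect_identical(negs,
                   sample_negatives(tfs, genes, positives, exclusion,
                                    ratio = 1, seed = 42))
  expect_identical(nrow(sample_negatives(tfs, genes, positives,
                                         ratio = 0, seed = 1)), 0L)
})

test_that("infeasible negative requests report the pool size", {
  tfs <- "TF01"
  genes <- sprintf("G%03d", 1:6)
  positives <- tibble::tibble(tf_id = "TF01", target_id = genes[1:5])
  # pool has 1 free pair, 5 requested
  expect_error(sample_negatives(tfs, genes, positives, ratio = 1, seed = 1),
               "only 1 non-excluded")
})

test_that("gene-level split is deterministic and leakage-free", {
  corpus <- tiny_corpus(seed = 7)
  pairs <- corpus_pairs(corpus, seed = 7)
  split <- split_by_gene(pairs, seed = 9)
  split2 <- split_by_gene(pairs, seed = 9)
  expect_identical(split_report(split), split_report(split2))

  # pair-level disjointness and accounting of dropped mixed pairs
  key <- function(p) paste(p$tf_id, p$target_id)
  expect_length(intersect(key(split$train_pairs), key(split$test_pairs)), 0)
  expect_length(intersect(key(split$val_pairs), key(split$test_pairs)), 0)
  expect_identical(
    nrow(split$train_pairs) + nrow(split$val_pairs) +
      nrow(split$test_pairs) + split$dropped_pairs,
    nrow(pairs))

  # exhaustive leakage scan: genes whose images feed training/validation
  # instances never appear in a test pair
  inst_tr <- enumerate_instances(
    dplyr::bind_rows(split$train_pairs, split$val_pairs), corpus$images)
  train_img_genes <- unique(corpus$images$gene_id[
    c(inst_tr$tf_row, inst_tr$target_row)])
  test_genes <- unique(c(split$test_pairs$tf_id, split$test_pairs$target_id))
  expect_length(intersect(train_img_genes, test_genes), 0)

  # achieved fractions near the 4:1 / 90:10 design
  expect_lt(abs(split$achieved$pair_train_frac - 0.8), 0.06 + 1e-9)
  expect_lt(abs(split$achieved$val_frac_of_train - 0.1), 0.05 + 1e-9)
})

test_that("instance enumeration is the orientation-wise cross product", {
  images <- tibble::tibble(
    gene_id = c(rep("A", 3), rep("B", 5)),
    orientation = c("lateral", "lateral", "ventral",
                    "lateral", "lateral", "lateral", "dorsal", "dorsal"),
    replicate = c(1, 2, 1, 1, 2, 3, 1, 2),
    image = replicate(8, matrix(0, 4, 4), simplify = FALSE))
  pair <- tibble::tibble(tf_id = "A", target_id = "B", label = 1L)
  inst <- enumerate_instances(pair, images)
  # (2 lateral x 3 lateral) + (1 ventral x 0) + (0 dorsal x 2) = 6
  expect_identical(nrow(inst), 6L)
  expect_true(all(inst$label == 1L))
  expect_true(all(images$orientation[inst$tf_row] ==
                    images$orientation[inst$target_row]))

  one <- tibble::tibble(
    gene_id = c("A", "B"), orientation = "lateral", replicate = 1,
    image = replicate(2, matrix(0, 4, 4), simplify = FALSE))
  expect_identical(nrow(enumerate_instances(pair, one)), 1L)

  disjoint <- tibble::tibble(
    gene_id = c("A", "B"), orientation = c("lateral", "dorsal"),
    replicate = 1,
    image = replicate(2, matrix(0, 4, 4), simplify = FALSE))
  expect_identical(nrow(enumerate_instances(pair, disjoint)), 0L)
})

test_that("instance counts equal the orientation product identity corpus-wide", {
  corpus <- tiny_corpus(seed = 7)
  pairs <- corpus_pairs(corpus, seed = 3)
  inst <- enumerate_instances(pairs, corpus$images)
  expected <- expected_instance_counts(pairs, corpus$images)
  observed <- vapply(seq_len(nrow(pairs)),
                     function(i) sum(inst$pair_id == i), integer(1))
  expect_identical(observed, expected$n_instances)
  # label inheritance across all instances
  expect_identical(inst$label, pairs$label[inst$pair_id])
})
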