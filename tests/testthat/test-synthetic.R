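test_that("generation is deterministic under a fixed seed", {
  spec <- tiny_spec(seed = 7, n_targets = 6)
  a <- generate_corpus(spec)
  b <- generate_corpus(spec)
  expect_identical(a$truth_edges, b$truth_edges)
  expect_identical(a$region_assignments, b$region_assignments)
  expect_identical(a$images$image, b$images$image)
})

test_that("image count range and frame size are honoured", {
  spec <- tiny_spec(seed = 3, n_targets = 6, images_per_gene = c(1, 1))
  corpus <- generate_corpus(spec)
  counts <- gene_image_sets(corpus$images)
  # one image per orientation forced by the degenerate range
  expect_true(all(counts$n_total == 3))
  dims <- vapply(corpus$images$image, dim, integer(2))
  expect_true(all(dims[1, ] == spec$img_height))
  expect_true(all(dims[2, ] == spec$img_width))
  expect_true(all(vapply(corpus$images$image, min, numeric(1)) >= 0))
  expect_true(all(vapply(corpus$images$image, max, numeric(1)) <= 1))
})

test_that("planted edge count matches the interaction density and edges share regions", {
  spec <- tiny_spec(seed = 11, n_tfs = 5, n_targets = 20,
                    interaction_density = 0.2)
  corpus <- generate_corpus(spec)
  expect_identical(nrow(corpus$truth_edges), as.integer(round(0.2 * 5 * 20)))
  regions <- setNames(corpus$region_assignments$regions,
                      corpus$region_assignments$gene_id)
  shared_pos <- mapply(function(a, b)
    length(intersect(regions[[a]], regions[[b]])),
    corpus$truth_edges$tf_id, corpus$truth_edges$target_id)
  expect_true(all(shared_pos >= 1))
  shared_neg <- mapply(function(a, b)
    length(intersect(regions[[a]], regions[[b]])),
    corpus$negative_pool$tf_id, corpus$negative_pool$target_id)
  expect_true(all(shared_neg == 0))
})

test_that("an infeasible edge request names the shared-region constraint", {
  spec <- tiny_spec(seed = 1, n_tfs = 3, n_targets = 5, n_regions = 100,
                    regions_per_gene = c(1, 1), interaction_density = 0.9)
  expect_error(generate_corpus(spec), "share an active region")
})

test_that("spec invariants are enforced", {
  expect_error(tiny_spec(n_regions = 1), "n_regions")
  expect_error(tiny_spec(interaction_density = 0), "interaction_density")
  expect_error(tiny_spec(interaction_density = 1), "interaction_density")
  expect_error(tiny_spec(images_per_gene = c(2, 1)), "images_per_gene")
  expect_error(tiny_spec(regions_per_gene = c(0, 2)), "regions_per_gene")
})

test_that("truth pairs co-express locally while negatives do not", {
  corpus <- tiny_corpus(seed = 5)
  spec <- corpus$spec
  regions <- setNames(corpus$region_assignments$regions,
                      corpus$region_assignments$gene_id)
  # mean pixel correlation within the TF's active-region boxes, using one
  # lateral (or first available) image of each gene
  first_img <- function(g) {
    rows <- corpus$images[corpus$images$gene_id == g, ]
    list(img = rows$image[[1]], orientation = rows$orientation[1])
  }
  pair_cor <- function(tf, tg) {
    a <- first_img(tf)
    rows <- corpus$images[corpus$images$gene_id == tg &
                            corpus$images$orientation == a$orientation, ]
    if (nrow(rows) == 0) return(NA_real_)
    b <- rows$image[[1]]
    px <- unlist(lapply(regions[[tf]], function(r) {
      bb <- region_bbox(spec, r, a$orientation)
      list(as.vector(a$img[bb$y0:bb$y1, bb$x0:bb$x1]),
           as.vector(b[bb$y0:bb$y1, bb$x0:bb$x1]))
    }), recursive = FALSE)
    va <- unlist(px[seq(1, length(px), by = 2)])
    vb <- unlist(px[seq(2, length(px), by = 2)])
    stats::cor(va, vb)
  }
  pos_cor <- mapply(pair_cor, corpus$truth_edges$tf_id,
                    corpus$truth_edges$target_id)
  neg <- corpus$negative_pool[seq_len(min(30, nrow(corpus$negative_pool))), ]
  neg_cor <- mapply(pair_cor, neg$tf_id, neg$target_id)
  expect_gt(mean(pos_cor, na.rm = TRUE), mean(neg_cor, na.rm = TRUE))
})

test_that("global intensity is decoupled from the local pattern", {
  corpus <- tiny_corpus(seed = 5, global_scale_range = c(0.5, 2))
  mean_int <- function(g) {
    mean(vapply(corpus$images$image[corpus$images$gene_id == g],
                mean, numeric(1)))
  }
  pos_diff <- mapply(function(a, b) abs(mean_int(a) - mean_int(b)),
                     corpus$truth_edges$tf_id, corpus$truth_edges$target_id)
  neg <- corpus$negative_pool[seq_len(min(30, nrow(corpus$negative_pool))), ]
  neg_diff <- mapply(function(a, b) abs(mean_int(a) - mean_int(b)),
                     neg$tf_id, neg$target_id)
  # some interacting pair looks globally more different than some non-pair
  expect_true(max(pos_diff) > min(neg_diff))
})

test_that("write_corpus emits a complete manifest and round-trips", {
  corpus <- tiny_corpus(seed = 7)
  out <- withr::local_tempdir()
  manifest <- write_corpus(corpus, out)
  expect_identical(nrow(manifest), nrow(corpus$images))
  expect_true(file.exists(file.path(out, "truth_edges.tsv")))
  expect_identical(read_edges(file.path(out, "truth_edges.tsv")),
                   corpus$truth_edges)
  loaded <- load_corpus(out)
  expect_identical(gene_image_sets(loaded), gene_image_sets(corpus$images))
})

test_that("an empty corpus writes a valid empty manifest", {
  corpus <- tiny_corpus(seed = 7)
  empty <- corpus
  empty$images <- corpus$images[0, ]
  out <- withr::local_tempdir()
  manifest <- write_corpus(empty, out)
  expect_identical(nrow(manifest), 0L)
  expect_identical(nrow(load_corpus(out)), 0L)
})
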