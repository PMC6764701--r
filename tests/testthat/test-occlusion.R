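# A model that provably ignores a pixel region: identity backbone (flatten)
# with first-layer FC weights zeroed over the region's positions.
masked_model <- function(input_height = 16, input_width = 32,
                         mask_rows, mask_cols) {
  model <- build_model(model_config(
    "small_cnn", input_height = input_height, input_width = input_width,
    head_dropout = 0, head_batchnorm = FALSE, input_norm = "dataset",
    seed = 4))
  h2 <- 2L * input_height
  n_px <- h2 * input_width
  fc <- ly_fc(n_px, 8L)
  mask <- matrix(FALSE, h2, input_width)
  mask[mask_rows, mask_cols] <- TRUE
  fc$W[as.vector(mask), ] <- 0
  model$layers <- list(ly_flatten(), fc, ly_tanh(), ly_fc(8L, 1L),
                       ly_sigmoid())
  model$backbone_len <- 1L
  model
}

test_that("the occlusion grid has the declared geometry", {
  model <- stub_model(0.5, 16, 32)
  tf <- matrix(runif(16 * 32), 16, 32)
  tg <- matrix(runif(16 * 32), 16, 32)
  for (k in list(c(4L, 4L, 2L), c(6L, 3L, 3L), c(8L, 8L, 8L),
                 c(5L, 7L, 2L))) {
    map <- occlusion_map(model, tf, tg,
                         occlusion_config(k[1], k[2], stride = k[3]))
    expect_identical(nrow(map$values), (32L - k[1]) %/% k[3] + 1L)
    expect_identical(ncol(map$values), (32L - k[2]) %/% k[3] + 1L)
  }
  expect_error(
    occlusion_map(model, tf, tg, occlusion_config(64, 8)),
    "exceeds input")
})

test_that("a constant stub model yields an all-zero map", {
  model <- stub_model(0.7, 16, 32)
  tf <- matrix(runif(16 * 32), 16, 32)
  tg <- matrix(runif(16 * 32), 16, 32)
  map <- occlusion_map(model, tf, tg, occlusion_config(8, 8, stride = 8))
  expect_true(all(map$values == 0))
  expect_equal(map$baseline_score, 0.7, tolerance = 1e-12)
})

test_that("occluding with identical content changes nothing", {
  corpus <- tiny_corpus(seed = 7)
  model <- tiny_model(corpus, seed = 5)
  tf <- matrix(0.95, 32, 64)
  tf[20:28, 10:30] <- 0.2
  tg <- corpus$images$image[[1]]
  # patch (1:8, 1:8) of the TF half is uniform background = fill value
  map <- occlusion_map(model, tf, tg,
                       occlusion_config(8, 8, stride = 8,
                                        fill_value = 0.95))
  expect_equal(map$values[1, 1], 0, tolerance = 1e-12)
})

test_that("positions inside an ignored region have exactly zero impact", {
  model <- masked_model(16, 32, mask_rows = 1:16, mask_cols = 1:16)
  tf <- matrix(runif(16 * 32), 16, 32)
  tg <- matrix(runif(16 * 32), 16, 32)
  map <- occlusion_map(model, tf, tg,
                       occlusion_config(8, 8, stride = 8, fill_value = 0))
  # patches at rows 1-16 x cols 1-16 live wholly inside the masked block
  expect_true(all(map$values[1:2, 1:2] == 0))
  expect_true(any(map$values[, 3:4] != 0) || any(map$values[3:4, ] != 0))
})

test_that("occlusion localizes the planted interaction region", {
  fix <- tiny_trained()
  corpus <- fix$corpus
  spec <- corpus$spec
  regions <- setNames(corpus$region_assignments$regions,
                      corpus$region_assignments$gene_id)
  pos <- fix$split$test_pairs[fix$split$test_pairs$label == 1, ]
  if (nrow(pos) == 0) pos <- fix$split$train_pairs[
    fix$split$train_pairs$label == 1, ][1, ]
  inst <- enumerate_instances(pos[1, ], corpus$images)[1, ]
  tf_img <- corpus$images$image[[inst$tf_row]]
  tg_img <- corpus$images$image[[inst$target_row]]
  map <- occlusion_map(fix$model, tf_img, tg_img,
                       occlusion_config(12, 12, stride = 4))
  peak <- occlusion_peak(map)
  shared <- intersect(regions[[inst$tf_id]], regions[[inst$target_id]])
  in_any <- any(vapply(shared, function(r) {
    bb <- region_bbox(spec, r, inst$orientation)
    col_ok <- peak$col >= bb$x0 && peak$col <= bb$x1
    row_top <- peak$row >= bb$y0 && peak$row <= bb$y1
    row_bot <- peak$row >= bb$y0 + spec$img_height &&
      peak$row <= bb$y1 + spec$img_height
    col_ok && (row_top || row_bot)
  }, logical(1)))
  expect_true(in_any)
})

test_that("overlay rendering is geometry-preserving and deterministic", {
  model <- stub_model(0.5, 16, 32)
  tf <- matrix(runif(16 * 32), 16, 32)
  tg <- matrix(runif(16 * 32), 16, 32)
  map <- occlusion_map(model, tf, tg, occlusion_config(8, 8, stride = 8))
  expect_message(out <- render_overlay(map, tf, tg), "uniform")
  expect_identical(dim(out), c(32L, 32L, 3L))
  # all-zero map renders the plain input
  expect_equal(out[, , 1], rbind(tf, tg), tolerance = 1e-12)

  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  suppressMessages({
    render_overlay(map, tf, tg, path = p1)
    render_overlay(map, tf, tg, path = p2)
  })
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  expect_error(render_overlay(map, tf[1:8, ], tg[1:8, ]), "do not match")
})

test_that("occlusion maps serialise with their configuration", {
  model <- stub_model(0.5, 16, 32)
  map <- occlusion_map(model, matrix(0.5, 16, 32), matrix(0.5, 16, 32),
                       occlusion_config(8, 8, stride = 8))
  prefix <- tempfile()
  write_occlusion_map(map, prefix)
  grid <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  expect_identical(dim(grid), dim(map$values))
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(side$baseline_score, map$baseline_score, tolerance = 1e-12)
  expect_identical(side$config$stride, 8L)
  unlink(paste0(prefix, c(".tsv", ".json")))
})
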