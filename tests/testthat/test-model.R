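test_that("residual backbone reproduces the declared stage geometry", {
  model <- build_model(model_config("resnet50_style", input_height = 128,
                                    input_width = 320, seed = 1))
  s <- model_summary(model)
  expect_identical(s$stage, c("conv1", "conv2_x", "conv3_x", "conv4_x",
                              "conv5_x", "pooling", "fc_sigmoid"))
  expect_identical(s$out_height, c(128L, 64L, 32L, 16L, 8L, 1L, 1L))
  expect_identical(s$out_width, c(160L, 80L, 40L, 20L, 10L, 1L, 1L))
  expect_identical(s$channels, c(64L, 256L, 512L, 1024L, 2048L, 2048L, 1L))
})

test_that("incompatible input geometry fails with the offending stage", {
  expect_error(build_model(model_config("small_cnn", input_height = 30,
                                        input_width = 64)),
               "average pooling")
})

test_that("scores are probabilities and evaluation mode is deterministic", {
  corpus <- tiny_corpus(seed = 7)
  model <- tiny_model(corpus, seed = 2, head_dropout = 0.3)
  tf_img <- corpus$images$image[[1]]
  tg_img <- corpus$images$image[[2]]
  s1 <- score_instance(model, tf_img, tg_img)
  s2 <- score_instance(model, tf_img, tg_img)
  expect_identical(s1, s2)  # dropout disabled in eval mode
  expect_gt(s1, 0)
  expect_lt(s1, 1)
  # the concatenation is ordered: TF on top, so swapping roles may change
  # the score; the harness can measure this order sensitivity
  s_rev <- score_instance(model, tg_img, tf_img)
  expect_false(identical(s1, s_rev))
  expect_error(score_instance(model, tf_img[1:10, 1:10], tg_img),
               "dimensions")
})

test_that("a constant-weight stub scores every instance identically", {
  model <- stub_model(0.7)
  imgs <- replicate(4, matrix(runif(32 * 64), 32, 64), simplify = FALSE)
  scores <- c(score_instance(model, imgs[[1]], imgs[[2]]),
              score_instance(model, imgs[[3]], imgs[[4]]),
              score_instance(model, imgs[[2]], imgs[[3]]))
  expect_equal(scores, rep(0.7, 3), tolerance = 1e-12)
})

test_that("training updates weights, records history, and validates inputs", {
  corpus <- tiny_corpus(seed = 7)
  pairs <- corpus_pairs(corpus, seed = 7)
  split <- split_by_gene(pairs, seed = 7)
  inst_tr <- enumerate_instances(split$train_pairs, corpus$images)
  inst_val <- enumerate_instances(split$val_pairs, corpus$images)
  model <- tiny_model(corpus, seed = 2)
  cfg1 <- train_config(learning_rate = 0.05, epochs = 1, batch_size = 16,
                       seed = 1)
  w_before <- model$layers[[2]]$W
  trained <- train_model(model, inst_tr, inst_val, corpus$images, cfg1)
  expect_identical(nrow(trained$history), 1L)
  expect_false(identical(w_before, trained$layers[[2]]$W))

  expect_error(train_model(tiny_model(corpus), inst_tr[0, ], inst_val,
                           corpus$images, cfg1),
               "empty")
  one_class <- inst_tr[inst_tr$label == 1, ]
  expect_error(train_model(tiny_model(corpus), one_class, inst_val,
                           corpus$images, cfg1),
               "single class")
})

test_that("freezing the backbone trains only the head", {
  corpus <- tiny_corpus(seed = 7)
  pairs <- corpus_pairs(corpus, seed = 7)
  split <- split_by_gene(pairs, seed = 7)
  inst_tr <- enumerate_instances(split$train_pairs, corpus$images)
  model <- tiny_model(corpus, seed = 2, freeze_backbone = TRUE)
  conv_w <- model$layers[[2]]$W
  head_fc <- model$layers[[model$backbone_len + 1L]]
  head_w <- head_fc$W
  trained <- train_model(model, inst_tr, inst_tr[0, ], corpus$images,
                         train_config(learning_rate = 0.05, epochs = 1,
                                      batch_size = 16, seed = 1))
  expect_identical(conv_w, trained$layers[[2]]$W)
  expect_false(identical(head_w, head_fc$W))
})

test_that("the planted signal is recovered and shrinks with noise", {
  accs <- vapply(c(0.02, 0.35, 1.2), function(noise) {
    corpus <- tiny_corpus(seed = 13, noise_sd = noise)
    pairs <- corpus_pairs(corpus, seed = 13)
    split <- split_by_gene(pairs, seed = 13)
    inst_tr <- enumerate_instances(split$train_pairs, corpus$images)
    inst_val <- enumerate_instances(split$val_pairs, corpus$images)
    model <- tiny_model(corpus, seed = 13)
    model <- train_model(model, inst_tr, inst_val, corpus$images,
                         train_config(learning_rate = 0.05, epochs = 8,
                                      batch_size = 16, seed = 13))
    ev <- evaluate_predictions(
      predict_links(model, split$test_pairs, corpus$images))
    ev$accuracy
  }, numeric(1))
  expect_gte(accs[1], accs[2] - 0.05)
  expect_gte(accs[2], accs[3] - 0.05)
  expect_gt(accs[1], accs[3])
  expect_gte(accs[1], 0.9)
})

test_that("model parameters survive a save/load round trip", {
  fix <- tiny_trained()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fix$model, path)
  loaded <- load_model(path)
  img1 <- fix$corpus$images$image[[1]]
  img2 <- fix$corpus$images$image[[2]]
  expect_identical(score_instance(fix$model, img1, img2),
                   score_instance(loaded, img1, img2))
  expect_identical(tidy(loaded), tidy(fix$model))
})

test_that("tidy/glance/autoplot summarise a fitted classifier", {
  fix <- tiny_trained()
  h <- tidy(fix$model)
  expect_identical(names(h), c("epoch", "train_loss", "train_acc",
                               "val_loss", "val_acc"))
  g <- glance(fix$model)
  expect_identical(g$backbone, "small_cnn")
  expect_identical(g$epochs, nrow(h))
  expect_s3_class(autoplot(fix$model), "ggplot")
})

test_that("a missing pretrained weight file is reported", {
  expect_error(
    build_model(model_config("small_cnn", input_height = 32,
                             input_width = 64,
                             pretrained_init = "/no/such/weights.rds")),
    "missing parameter file")
})
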