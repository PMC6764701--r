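# Shared fixtures. Small-frame corpora (32 x 64 px) keep unit tests fast;
# the acceptance suite builds its own full-frame corpus. Heavyweight
# artifacts are built lazily and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[key]]
}

tiny_spec <- function(seed = 7, ...) {
  args <- utils::modifyList(list(
    n_tfs = 4, n_targets = 16, img_width = 64, img_height = 32,
    images_per_gene = c(1, 2), interaction_density = 0.2,
    noise_sd = 0.02, seed = seed), list(...))
  do.call(corpus_spec, args)
}

tiny_corpus <- function(seed = 7, ...) {
  key <- paste0("corpus_", seed, "_", paste(unlist(list(...)), collapse = "_"))
  cached(key, generate_corpus(tiny_spec(seed = seed, ...)))
}

# Labelled pairs for a corpus, with region-sharing non-edges excluded from
# the negative pool (they carry the planted signal without the label).
corpus_pairs <- function(corpus, ratio = 1, seed = 1) {
  all_p <- tidyr::expand_grid(tf_id = corpus$tf_ids,
                              target_id = corpus$target_ids)
  exclusion <- dplyr::anti_join(
    dplyr::anti_join(all_p, corpus$truth_edges, by = c("tf_id", "target_id")),
    corpus$negative_pool, by = c("tf_id", "target_id"))
  negs <- sample_negatives(corpus$tf_ids, corpus$target_ids,
                           corpus$truth_edges, exclusion = exclusion,
                           ratio = ratio, seed = seed)
  make_pairs(corpus$truth_edges, negs)
}

tiny_model <- function(corpus, seed = 3, ...) {
  args <- utils::modifyList(list(
    backbone = "small_cnn",
    input_height = corpus$spec$img_height,
    input_width = corpus$spec$img_width,
    head_dropout = 0, head_batchnorm = FALSE, seed = seed), list(...))
  build_model(do.call(model_config, args))
}

# Constant-output stub: a real classifier whose final layer weights are
# zeroed so every input scores exactly `value`. Downstream modules treat it
# as an opaque model.
stub_model <- function(value, input_height = 32, input_width = 64) {
  model <- build_model(model_config(
    "small_cnn", input_height = input_height, input_width = input_width,
    head_dropout = 0, head_batchnorm = FALSE, seed = 1))
  fc_out <- model$layers[[length(model$layers) - 1L]]
  stopifnot(fc_out$type == "fc")
  fc_out$W[] <- 0
  fc_out$b[] <- stats::qlogis(value)
  model
}

# Quickly trained small model on the tiny corpus; cached for reuse.
tiny_trained <- function() {
  cached("tiny_trained", {
    corpus <- tiny_corpus(seed = 7)
    pairs <- corpus_pairs(corpus, seed = 7)
    split <- split_by_gene(pairs, seed = 7)
    inst_tr <- enumerate_instances(split$train_pairs, corpus$images)
    inst_val <- enumerate_instances(split$val_pairs, corpus$images)
    model <- tiny_model(corpus, seed = 7, head_dropout = 0.1)
    model <- train_model(model, inst_tr, inst_val, corpus$images,
                         train_config(learning_rate = 0.05, epochs = 8,
                                      batch_size = 16, seed = 7))
    list(corpus = corpus, split = split, model = model)
  })
}

random_predictions <- function(n, seed) {
  withr::with_seed(seed, {
    p <- tibble::tibble(
      tf_id = sprintf("TF%02d", sample.int(9, n, replace = TRUE)),
      target_id = sprintf("G%03d", seq_len(n)),
      label = sample(0:1, n, replace = TRUE),
      score = stats::runif(n))
  })
  p$decision <- p$score >= 0.5
  p$n_instances <- 1L
  p$scorable <- TRUE
  p$threshold_used <- 0.5
  class(p) <- c("pixlink_predictions", class(p))
  p
}
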