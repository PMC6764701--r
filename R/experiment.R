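#' Run the full pipeline from one configuration
#'
#' Executes, in order: `simulate` (synthetic corpus generation, skipped when
#' an existing corpus directory is given), `prepare` (negative sampling and
#' gene-level splitting), `train`, `predict`, `evaluate`, and `hubs`. Every
#' stage writes its artifact under `out_dir` and is recorded in the run
#' manifest together with its seed, so a rerun with the same configuration
#' reproduces all deterministic outputs byte for byte.
#'
#' The configuration is a YAML file (or equivalent nested list) with
#' sections:
#' \describe{
#'   \item{simulate}{arguments of [corpus_spec()], or `corpus_dir:` pointing
#'     at a written corpus.}
#'   \item{prepare}{`negative_ratio`, `train_frac`, `val_frac_of_train`,
#'     `seed`.}
#'   \item{model}{arguments of [model_config()].}
#'   \item{train}{arguments of [train_config()].}
#'   \item{predict}{`threshold`.}
#'   \item{hubs}{`k`, `min_degree`.}
#' }
#'
#' @param config Path to a YAML configuration or a nested list.
#' @param out_dir Output directory.
#' @return A `pixlink_manifest` list: config snapshot, seeds, package
#'   version, input checksums, per-stage output paths, and timestamps.
#'   Stage results are attached as attribute `"results"`.
#' @export
run_experiment <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  check_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = cfg,
    package_version = as.character(utils::packageVersion("pixlink")),
    r_version = R.version.string,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = list(), paths = list(), checksums = list())
  results <- list()

  # -- simulate / load ----------------------------------------------------
  if (!is.null(cfg$simulate$corpus_dir)) {
    corpus_dir <- cfg$simulate$corpus_dir
    images <- load_corpus(corpus_dir)
    positives <- read_edges(file.path(corpus_dir, "truth_edges.tsv"))
    neg_pool_path <- file.path(corpus_dir, "certified_negatives.tsv")
    negative_pool <- if (file.exists(neg_pool_path)) read_edges(neg_pool_path)
    tf_ids <- sort(unique(positives$tf_id))
    target_ids <- sort(setdiff(unique(c(positives$target_id,
                                        negative_pool$target_id)),
                               tf_ids))
    spec <- NULL
  } else {
    spec <- do.call(corpus_spec, cfg$simulate)
    corpus <- generate_corpus(spec)
    corpus_dir <- file.path(out_dir, "corpus")
    write_corpus(corpus, corpus_dir)
    images <- corpus$images
    positives <- corpus$truth_edges
    negative_pool <- corpus$negative_pool
    tf_ids <- corpus$tf_ids
    target_ids <- corpus$target_ids
    manifest$seeds$simulate <- spec$seed
  }
  manifest$paths$corpus <- corpus_dir
  manifest$checksums$truth_edges <-
    unname(tools::md5sum(file.path(corpus_dir, "truth_edges.tsv")))

  # -- prepare ------------------------------------------------------------
  prep <- cfg$prepare
  seed_prep <- prep$seed %||% 1L
  negatives <- sample_negatives(
    tf_universe = tf_ids, gene_universe = target_ids,
    positives = positives,
    exclusion = if (is.null(negative_pool)) NULL else
      dplyr::anti_join(
        tidyr::expand_grid(tf_id = tf_ids, target_id = target_ids),
        dplyr::bind_rows(negative_pool[, c("tf_id", "target_id")],
                         positives[, c("tf_id", "target_id")]),
        by = c("tf_id", "target_id")),
    ratio = prep$negative_ratio %||% 1,
    seed = seed_prep)
  pairs <- make_pairs(positives, negatives)
  split <- split_by_gene(pairs,
                         train_frac = prep$train_frac %||% 0.8,
                         val_frac_of_train = prep$val_frac_of_train %||% 0.1,
                         seed = seed_prep,
                         tol = prep$split_tol %||% 0.06)
  split_path <- file.path(out_dir, "split_report.json")
  jsonlite::write_json(split_report(split), split_path, auto_unbox = TRUE,
                       digits = NA)
  manifest$seeds$prepare <- seed_prep
  manifest$paths$split_report <- split_path
  results$split <- split

  # -- train --------------------------------------------------------------
  mcfg <- do.call(model_config, c(
    cfg$model %||% list(),
    if (is.null(cfg$model$input_height))
      list(input_height = nrow(images$image[[1]]),
           input_width = ncol(images$image[[1]]))))
  tcfg <- do.call(train_config, cfg$train %||% list())
  model <- build_model(mcfg)
  inst_train <- enumerate_instances(split$train_pairs, images)
  inst_val <- enumerate_instances(split$val_pairs, images)
  inst_test <- enumerate_instances(split$test_pairs, images)
  img_id <- sprintf("%s__%s__%02d", images$gene_id, images$orientation,
                    images$replicate)
  for (part in c("train", "val", "test")) {
    inst <- get(paste0("inst_", part))
    path <- file.path(out_dir, sprintf("instances_%s.tsv", part))
    utils::write.table(
      data.frame(tf_image = img_id[inst$tf_row],
                 target_image = img_id[inst$target_row],
                 orientation = inst$orientation, label = inst$label),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$paths[[paste0("instances_", part)]] <- path
  }
  model <- train_model(model, inst_train, inst_val, images, tcfg)
  hist_path <- file.path(out_dir, "history.csv")
  utils::write.csv(model$history, hist_path, row.names = FALSE)
  model_path <- file.path(out_dir, "model.rds")
  save_model(model, model_path)
  manifest$seeds$model_init <- mcfg$seed
  manifest$seeds$train <- tcfg$seed
  manifest$paths$history <- hist_path
  manifest$paths$model <- model_path
  results$model <- model

  # -- predict ------------------------------------------------------------
  threshold <- cfg$predict$threshold %||% 0.5
  preds <- predict_links(model, split$test_pairs, images,
                         threshold = threshold)
  pred_path <- file.path(out_dir, "predictions.tsv")
  write_predictions(preds, pred_path)
  manifest$paths$predictions <- pred_path
  results$predictions <- preds

  # -- evaluate -----------------------------------------------------------
  ev <- evaluate_predictions(preds)
  eval_path <- file.path(out_dir, "eval.json")
  jsonlite::write_json(
    list(accuracy = ev$accuracy, f1 = ev$f1,
         top_fraction_fp_ratio = ev$top_fraction_fp_ratio,
         n_scorable = ev$n_scorable, n_unscorable = ev$n_unscorable,
         notes = c(ev$notes, paste(
           "accuracy on sampled-negative benchmarks may be underestimated:",
           "unrevealed true links may exist among the negatives"))),
    eval_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(ev$histogram, file.path(out_dir, "histogram.csv"),
                   row.names = FALSE)
  manifest$paths$eval <- eval_path
  results$eval <- ev

  # -- hubs ---------------------------------------------------------------
  hub_cfg <- cfg$hubs %||% list()
  k <- hub_cfg$k %||% min(50L, ev$n_scorable)
  net <- top_k_edges(preds, k)
  hubs <- extract_hubs(net, min_degree = hub_cfg$min_degree %||% 2)
  net_path <- file.path(out_dir, "top_edges.tsv")
  export_network(net, "TSV", net_path)
  hubs_path <- file.path(out_dir, "hub_degrees.tsv")
  utils::write.table(hubs$degree_table, hubs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$paths$top_edges <- net_path
  manifest$paths$hub_degrees <- hubs_path
  results$network <- net
  results$hubs <- hubs

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest$paths$manifest <- manifest_path
  structure(manifest, class = "pixlink_manifest", results = results)
}

check_config <- function(cfg) {
  bad <- character(0)
  if (!is.list(cfg)) stop("configuration must be a list or YAML file")
  known <- c("simulate", "prepare", "model", "train", "predict", "hubs")
  bad <- c(bad, setdiff(names(cfg), known))
  if (is.null(cfg$simulate))
    bad <- c(bad, "simulate (need corpus parameters or corpus_dir)")
  if (!is.null(cfg$simulate$corpus_dir) &&
      !dir.exists(cfg$simulate$corpus_dir))
    bad <- c(bad, sprintf("simulate.corpus_dir (missing: %s)",
                          cfg$simulate$corpus_dir))
  if (length(bad))
    stop("configuration problems: ", paste(bad, collapse = "; "))
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pixlink_manifest <- function(x, ...) {
  cat("<pixlink_manifest>\n")
  cat("  started: ", x$started, "\n", sep = "")
  cat("  outputs:\n")
  for (nm in names(x$paths)) cat(sprintf("    %-12s %s\n", nm, x$paths[[nm]]))
  invisible(x)
}
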