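#' Classifier configuration
#'
#' Two backbones are available. `resnet50_style` follows the 50-layer
#' residual architecture adapted to the vertically concatenated image pair:
#' a 7x7/64 stride-2 stem, 3x3 stride-2 max pooling, four bottleneck stages
#' of 3, 4, 6 and 3 units (256, 512, 1024, 2048 output channels), and global
#' average pooling. `small_cnn` is a shallow convolutional stack sized for
#' CPU-scale experiments: input average pooling, two strided convolutions,
#' and a fold step that stacks the TF-half and target-half feature maps
#' channel-wise so 1x1 convolutions can detect co-located expression.
#'
#' Both backbones share the head contract: a fully connected layer with
#' `head_hidden_dim` tanh units (optionally batch-normalised and dropped
#' out), then a single sigmoid unit giving the interaction probability.
#'
#' @param backbone `"small_cnn"` or `"resnet50_style"`.
#' @param input_height,input_width Size of *one* image; the classifier input
#'   is the vertical concatenation, `2 * input_height` rows.
#' @param head_hidden_dim Width of the penultimate fully connected layer.
#' @param head_activation Currently `"tanh"`.
#' @param head_dropout Dropout fraction applied after the hidden layer.
#' @param head_batchnorm Apply batch normalisation in the head.
#' @param input_norm Input normalisation: `"per_image"` (default)
#'   standardises each image by its own mean and standard deviation, making
#'   the classifier invariant to overall staining intensity so only the
#'   spatial pattern matters; `"dataset"` applies corpus-wide constants
#'   estimated from the training images.
#' @param freeze_backbone Train only the head; backbone weights stay fixed
#'   (the fixed-feature-extractor variant of transfer learning).
#' @param pretrained_init Optional path to a saved backbone parameter file
#'   (see [save_model()]); `NULL` (default) draws random initial weights.
#' @param seed Weight-initialisation seed.
#' @return A `pixlink_model_config` list.
#' @export
model_config <- function(backbone = c("small_cnn", "resnet50_style"),
                         input_height = 128, input_width = 320,
                         head_hidden_dim = 128,
                         head_activation = "tanh",
                         head_dropout = 0.3,
                         head_batchnorm = TRUE,
                         input_norm = c("per_image", "dataset"),
                         freeze_backbone = FALSE,
                         pretrained_init = NULL,
                         seed = 1L) {
  backbone <- match.arg(backbone)
  stopifnot(head_hidden_dim >= 1, head_dropout >= 0, head_dropout < 1,
            identical(head_activation, "tanh"))
  structure(list(
    backbone = backbone,
    input_height = as.integer(input_height),
    input_width = as.integer(input_width),
    channels = if (backbone == "resnet50_style") 3L else 1L,
    head_hidden_dim = as.integer(head_hidden_dim),
    head_activation = head_activation,
    head_dropout = head_dropout,
    head_batchnorm = isTRUE(head_batchnorm),
    input_norm = match.arg(input_norm),
    freeze_backbone = isTRUE(freeze_backbone),
    pretrained_init = pretrained_init,
    seed = as.integer(seed)
  ), class = "pixlink_model_config")
}

#' Training configuration
#'
#' Defaults follow the standard recipe for this classifier: plain SGD,
#' learning rate 0.001, 60 epochs, decision threshold 0.5. For the compact
#' `small_cnn` trained from scratch a larger learning rate and fewer epochs
#' are appropriate (see the methods vignette).
#'
#' @param optimizer Only `"sgd"` is implemented.
#' @param learning_rate Positive step size.
#' @param epochs Number of passes over the training instances.
#' @param batch_size Minibatch size.
#' @param seed Seed for shuffling and dropout.
#' @param checkpoint_policy `"best_val"` restores the epoch with the highest
#'   validation accuracy; `"last"` keeps the final weights.
#' @return A `pixlink_train_config` list.
#' @export
train_config <- function(optimizer = "sgd", learning_rate = 0.001,
                         epochs = 60, batch_size = 32, seed = 1L,
                         checkpoint_policy = c("best_val", "last")) {
  stopifnot(identical(optimizer, "sgd"), learning_rate > 0, epochs >= 1)
  structure(list(
    optimizer = optimizer, learning_rate = learning_rate,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed),
    checkpoint_policy = match.arg(checkpoint_policy)
  ), class = "pixlink_train_config")
}

build_head <- function(d_in, cfg) {
  head <- list(ly_fc(d_in, cfg$head_hidden_dim, init = "xavier"))
  if (cfg$head_batchnorm) head <- c(head, list(ly_bn(cfg$head_hidden_dim)))
  head <- c(head, list(ly_tanh()))
  if (cfg$head_dropout > 0) head <- c(head, list(ly_dropout(cfg$head_dropout)))
  c(head, list(ly_fc(cfg$head_hidden_dim, 1L, init = "xavier"), ly_sigmoid()))
}

bottleneck <- function(c_in, c_mid, c_out, stride = 1L) {
  branch <- list(
    ly_conv(1L, 1L, c_in, c_mid, stride = 1L, pad = 0L), ly_bn(c_mid),
    ly_relu(),
    ly_conv(3L, 3L, c_mid, c_mid, stride = stride, pad = 1L), ly_bn(c_mid),
    ly_relu(),
    ly_conv(1L, 1L, c_mid, c_out, stride = 1L, pad = 0L), ly_bn(c_out))
  shortcut <- if (c_in != c_out || stride != 1L) {
    list(ly_conv(1L, 1L, c_in, c_out, stride = stride, pad = 0L),
         ly_bn(c_out))
  }
  ly_residual(branch, shortcut)
}

resnet_stage <- function(c_in, c_mid, c_out, n_units, first_stride) {
  blocks <- list(bottleneck(c_in, c_mid, c_out, stride = first_stride))
  for (i in seq_len(n_units - 1L))
    blocks <- c(blocks, list(bottleneck(c_out, c_mid, c_out, stride = 1L)))
  blocks
}

#' Build an image-pair classifier
#'
#' Constructs the network for inputs of `2 * input_height` rows by
#' `input_width` columns (TF image stacked above the target image). The
#' declared downsampling schedule must divide the input geometry; for the
#' default 128 x 320 frame the residual backbone produces the stage map
#' sizes 128x160, 64x80, 32x40, 16x20 and 8x10 before global pooling.
#'
#' @param cfg A [model_config()].
#' @return A `pixlink_model`: layers plus input geometry and stage table.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "pixlink_model_config"))
  H2 <- 2L * cfg$input_height
  W <- cfg$input_width
  in_shape <- c(H2, W, cfg$channels)
  withr::with_seed(cfg$seed, {
    if (cfg$backbone == "resnet50_style") {
      backbone <- c(
        list(ly_conv(7L, 7L, cfg$channels, 64L, stride = 2L, pad = 3L),
             ly_bn(64L), ly_relu()),
        list(ly_maxpool(3L, stride = 2L, pad = 1L)),
        resnet_stage(64L, 64L, 256L, 3L, first_stride = 1L),
        resnet_stage(256L, 128L, 512L, 4L, first_stride = 2L),
        resnet_stage(512L, 256L, 1024L, 6L, first_stride = 2L),
        resnet_stage(1024L, 512L, 2048L, 3L, first_stride = 2L),
        list(ly_gap()))
      stage_ends <- c(conv1 = 3L, conv2_x = 4L + 3L, conv3_x = 7L + 4L,
                      conv4_x = 11L + 6L, conv5_x = 17L + 3L,
                      pooling = 21L)
    } else {
      if (H2 %% 16L != 0L || W %% 16L != 0L)
        stop(sprintf(paste(
          "small_cnn downsamples by 16; concatenated input %dx%d is not",
          "divisible by 16 (first failing stage: input average pooling)"),
          H2, W))
      backbone <- list(
        ly_avgpool(4L),
        ly_conv(5L, 5L, 1L, 8L, stride = 2L, pad = 2L), ly_relu(),
        ly_conv(3L, 3L, 8L, 16L, stride = 2L, pad = 1L), ly_relu(),
        ly_fold(),
        ly_conv(1L, 1L, 48L, 32L, stride = 1L, pad = 0L), ly_relu(),
        ly_gap())
      stage_ends <- c(pool_in = 1L, conv1 = 3L, conv2 = 5L, fold = 6L,
                      conv3 = 8L, pooling = 9L)
    }
    feat_shape <- nn_out_shape(backbone, in_shape)
    feat_dim <- prod(feat_shape)
    pre_head <- if (length(feat_shape) > 1) list(ly_flatten()) else list()
    head <- build_head(feat_dim, cfg)
    layers <- c(backbone, pre_head, head)
  })
  model <- structure(list(
    config = cfg,
    layers = layers,
    backbone_len = length(backbone) + length(pre_head),
    stage_ends = stage_ends,
    input_shape = in_shape,
    normalize = c(mean = 0.8, sd = 0.2),
    trained = FALSE
  ), class = "pixlink_model")
  if (!is.null(cfg$pretrained_init)) {
    if (!file.exists(cfg$pretrained_init))
      stop("pretrained_init points to a missing parameter file: ",
           cfg$pretrained_init,
           " (pretrained backbone weights must be supplied externally)")
    snap <- readRDS(cfg$pretrained_init)
    restore_params(model$layers, snap)
  }
  model
}

#' @export
print.pixlink_model <- function(x, ...) {
  cat(sprintf("<pixlink_model> backbone=%s input=%dx%dx%d %s\n",
              x$config$backbone, x$input_shape[1], x$input_shape[2],
              x$input_shape[3],
              if (x$trained) "(trained)" else "(untrained)"))
  invisible(x)
}

#' Per-stage output geometry of a classifier
#'
#' Propagates the input geometry through the network analytically and
#' reports the feature-map size after each named stage, plus the head.
#'
#' @param model A `pixlink_model`.
#' @return Tibble with `stage`, `out_height`, `out_width`, `channels`.
#' @export
model_summary <- function(model) {
  shape <- model$input_shape
  rows <- list()
  prev <- 0L
  for (s in seq_along(model$stage_ends)) {
    end <- model$stage_ends[[s]]
    for (i in (prev + 1L):end)
      shape <- layer_out_shape(model$layers[[i]], shape)
    prev <- end
    dims <- if (length(shape) == 3) shape else c(1L, 1L, shape)
    rows[[s]] <- tibble::tibble(
      stage = names(model$stage_ends)[s],
      out_height = dims[1], out_width = dims[2], channels = dims[3])
  }
  shape_fc <- nn_out_shape(
    model$layers[(prev + 1L):length(model$layers)],
    shape)
  dplyr::bind_rows(
    rows,
    tibble::tibble(stage = "fc_sigmoid", out_height = 1L, out_width = 1L,
                   channels = as.integer(shape_fc)))
}

# Build the normalised concatenated input for one instance; the TF image is
# the top half by contract.
concat_input <- function(model, tf_img, target_img) {
  d_exp <- c(model$config$input_height, model$config$input_width)
  if (!identical(dim(tf_img), as.integer(d_exp)) ||
      !identical(dim(target_img), as.integer(d_exp)))
    stop(sprintf("image dimensions must be %dx%d (got %s and %s)",
                 d_exp[1], d_exp[2],
                 paste(dim(tf_img), collapse = "x"),
                 paste(dim(target_img), collapse = "x")))
  if (identical(model$config$input_norm, "per_image")) {
    tf_img <- (tf_img - mean(tf_img)) / max(stats::sd(tf_img), 1e-6)
    target_img <- (target_img - mean(target_img)) /
      max(stats::sd(target_img), 1e-6)
    x <- rbind(tf_img, target_img)
  } else {
    x <- rbind(tf_img, target_img)
    x <- (x - model$normalize[["mean"]]) / model$normalize[["sd"]]
  }
  array(rep(x, model$config$channels),
        c(dim(x), model$config$channels))
}

#' Score one image-pair instance
#'
#' Runs the classifier in evaluation mode (dropout off, batch statistics
#' frozen) on the concatenated pair; deterministic given fixed weights.
#'
#' @param model A `pixlink_model`.
#' @param tf_img,target_img Grayscale matrices (`input_height` x
#'   `input_width`, intensities in `[0, 1]`).
#' @return Probability in (0, 1) that the TF regulates the target, as
#'   evidenced by this image pair.
#' @export
score_instance <- function(model, tf_img, target_img) {
  x <- concat_input(model, tf_img, target_img)
  as.numeric(nn_forward(model$layers, x, training = FALSE)$out)
}

#' Score a table of instances
#'
#' @param model A `pixlink_model`.
#' @param instances Instance tibble from [enumerate_instances()].
#' @param images The image tibble the instance rows index into.
#' @return `instances` with a `score` column appended.
#' @export
score_instances <- function(model, instances, images) {
  scores <- vapply(seq_len(nrow(instances)), function(i) {
    score_instance(model,
                   images$image[[instances$tf_row[i]]],
                   images$image[[instances$target_row[i]]])
  }, numeric(1))
  dplyr::mutate(instances, score = scores)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

instance_inputs <- function(model, instances, images) {
  lapply(seq_len(nrow(instances)), function(i)
    concat_input(model, images$image[[instances$tf_row[i]]],
                 images$image[[instances$target_row[i]]]))
}

#' Train the classifier on labelled image-pair instances
#'
#' Minibatch stochastic gradient descent on binary cross-entropy. With
#' `freeze_backbone` the backbone acts as a fixed feature extractor:
#' per-instance features are computed once and only the head is updated.
#' Normalisation constants are set from the training images' mean and
#' standard deviation before the first epoch. The model's layer parameters
#' are updated in place; the returned object additionally carries the
#' per-epoch history.
#'
#' @param model A `pixlink_model` from [build_model()].
#' @param train_instances,val_instances Instance tibbles (columns `tf_row`,
#'   `target_row`, `label`); `val_instances` may have zero rows.
#' @param images Image tibble indexed by the instance rows.
#' @param cfg A [train_config()].
#' @return The trained `pixlink_model` with `$history` (tibble of `epoch`,
#'   `train_loss`, `train_acc`, `val_loss`, `val_acc`) and `$train_config`.
#' @export
train_model <- function(model, train_instances, val_instances, images, cfg) {
  stopifnot(inherits(cfg, "pixlink_train_config"))
  if (nrow(train_instances) == 0) stop("training set is empty")
  y <- train_instances$label
  if (length(unique(y)) < 2)
    stop("training set contains a single class; the binary problem is ",
         "degenerate")

  if (identical(model$config$input_norm, "dataset")) {
    train_imgs <- unique(c(train_instances$tf_row,
                           train_instances$target_row))
    px <- unlist(lapply(images$image[train_imgs], as.vector))
    model$normalize <- c(mean = mean(px), sd = max(stats::sd(px), 1e-6))
  }

  frozen <- model$config$freeze_backbone
  n_layers <- length(model$layers)
  bl <- model$backbone_len
  if (frozen) {
    feats_tr <- lapply(instance_inputs(model, train_instances, images),
      function(x) nn_forward(model$layers[seq_len(bl)], x,
                             training = FALSE)$out)
    feats_val <- lapply(instance_inputs(model, val_instances, images),
      function(x) nn_forward(model$layers[seq_len(bl)], x,
                             training = FALSE)$out)
    active <- model$layers[(bl + 1L):n_layers]
  } else {
    active <- model$layers
  }

  eval_set <- function(instances, feats = NULL) {
    if (nrow(instances) == 0) return(c(loss = NA_real_, acc = NA_real_))
    p <- if (frozen) {
      vapply(feats, function(f)
        as.numeric(nn_forward(active, f, training = FALSE)$out), numeric(1))
    } else {
      score_instances(model, instances, images)$score
    }
    c(loss = bce_loss(p, instances$label),
      acc = mean((p >= 0.5) == (instances$label == 1)))
  }

  n <- nrow(train_instances)
  history <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, loss = Inf, snap = NULL)
  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(n)
      correct <- logical(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1L, n)]
        clear_grads(active)
        for (i in batch) {
          x <- if (frozen) feats_tr[[i]] else
            concat_input(model, images$image[[train_instances$tf_row[i]]],
                         images$image[[train_instances$target_row[i]]])
          fwd <- nn_forward(active, x, training = TRUE)
          p <- as.numeric(fwd$out)
          yi <- y[i]
          losses[i] <- bce_loss(p, yi)
          correct[i] <- (p >= 0.5) == (yi == 1)
          # after the final sigmoid layer this backpropagates p - y
          dout <- (p - yi) / max(p * (1 - p), 1e-12)
          nn_backward(active, fwd$caches, dout)
        }
        sgd_step(active, cfg$learning_rate, scale = 1 / length(batch))
      }
      val <- eval_set(val_instances, if (frozen) feats_val)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(losses), train_acc = mean(correct),
        val_loss = val[["loss"]], val_acc = val[["acc"]])
      # ties in validation accuracy resolve to the lower validation loss
      if (cfg$checkpoint_policy == "best_val" && !is.na(val[["acc"]]) &&
          (val[["acc"]] > best$acc ||
             (val[["acc"]] == best$acc && val[["loss"]] < best$loss))) {
        best <- list(acc = val[["acc"]], loss = val[["loss"]],
                     snap = collect_params(model$layers))
      }
    }
  })
  if (!is.null(best$snap)) restore_params(model$layers, best$snap)
  model$history <- dplyr::bind_rows(history)
  model$train_config <- cfg
  model$trained <- TRUE
  model
}

#' Save / load classifier parameters
#'
#' Parameters (weights, biases, batch-norm statistics) are serialised with
#' the model and training configuration; [load_model()] rebuilds the network
#' and restores them.
#'
#' @param model A `pixlink_model`.
#' @param path Destination `.rds` path.
#' @return `save_model()`: the path, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  obj <- list(config = model$config, params = collect_params(model$layers),
              normalize = model$normalize, history = model$history,
              train_config = model$train_config, trained = model$trained)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$config)
  restore_params(model$layers, obj$params)
  model$normalize <- obj$normalize
  model$history <- obj$history
  model$train_config <- obj$train_config
  model$trained <- isTRUE(obj$trained)
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted classifier
#'
#' @param x A trained `pixlink_model`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.pixlink_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  x$history
}

#' One-row summary of a fitted classifier
#'
#' @param x A trained `pixlink_model`.
#' @param ... Unused.
#' @return Tibble with backbone, epochs, final/best metrics.
#' @export
glance.pixlink_model <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(
    backbone = x$config$backbone,
    epochs = nrow(h),
    train_loss = h$train_loss[nrow(h)],
    train_acc = h$train_acc[nrow(h)],
    best_val_acc = if (all(is.na(h$val_acc))) NA_real_ else
      max(h$val_acc, na.rm = TRUE))
}

#' Plot training history
#'
#' @param object A trained `pixlink_model`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracy per epoch.
#' @export
autoplot.pixlink_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
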