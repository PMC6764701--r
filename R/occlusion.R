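#' Occlusion test configuration
#'
#' The occlusion test slides a rectangular occluding patch across the full
#' concatenated input (both the TF half and the target half are probed) and
#' records how much the output probability drops when the patch is replaced
#' by a constant fill. Defaults: a 32x32 patch moved with stride 16, filled
#' with the light-background intensity of standardized embryo images (0.95)
#' so the occluder resembles unstained tissue rather than an
#' out-of-distribution black square.
#'
#' @param kernel_height,kernel_width Patch size in pixels.
#' @param stride Step between patch positions, in pixels.
#' @param fill_value Intensity written into the occluded patch, on the raw
#'   `[0, 1]` image scale.
#' @return A `pixlink_occlusion_config` list.
#' @export
occlusion_config <- function(kernel_height = 32, kernel_width = 32,
                             stride = 16, fill_value = 0.95) {
  stopifnot(kernel_height >= 1, kernel_width >= 1, stride >= 1)
  structure(list(
    kernel_height = as.integer(kernel_height),
    kernel_width = as.integer(kernel_width),
    stride = as.integer(stride), fill_value = fill_value
  ), class = "pixlink_occlusion_config")
}

#' Occlusion sensitivity map for one image-pair instance
#'
#' For every patch position on the concatenated input, the patch is replaced
#' by `fill_value`, the occluded input is re-scored in evaluation mode, and
#' the map records `baseline - occluded` output probability. Positive values
#' mark regions the model relies on; zero means no impact; negative values
#' (occlusion raising the score) are retained.
#'
#' @param model A trained `pixlink_model`.
#' @param tf_img,target_img The instance's images (raw `[0, 1]` matrices).
#' @param cfg An [occlusion_config()].
#' @return A `pixlink_occlusion_map`: list with `values` (matrix of
#'   probability decreases, rows indexing vertical patch positions),
#'   `baseline_score`, `config`, `input_dim`, and `row_px`/`col_px` (pixel
#'   offsets of each grid position's patch top-left corner).
#' @export
occlusion_map <- function(model, tf_img, target_img,
                          cfg = occlusion_config()) {
  x_raw <- rbind(tf_img, target_img)
  d <- dim(x_raw)
  if (cfg$kernel_height > d[1] || cfg$kernel_width > d[2])
    stop(sprintf("occlusion kernel %dx%d exceeds input %dx%d",
                 cfg$kernel_height, cfg$kernel_width, d[1], d[2]))
  baseline <- score_instance(model, tf_img, target_img)
  n_r <- (d[1] - cfg$kernel_height) %/% cfg$stride + 1L
  n_c <- (d[2] - cfg$kernel_width) %/% cfg$stride + 1L
  values <- matrix(0, n_r, n_c)
  h <- nrow(tf_img)
  for (i in seq_len(n_r)) {
    r0 <- (i - 1L) * cfg$stride + 1L
    rows <- r0:(r0 + cfg$kernel_height - 1L)
    for (j in seq_len(n_c)) {
      c0 <- (j - 1L) * cfg$stride + 1L
      cols <- c0:(c0 + cfg$kernel_width - 1L)
      occ <- x_raw
      occ[rows, cols] <- cfg$fill_value
      score <- score_instance(model, occ[seq_len(h), , drop = FALSE],
                              occ[h + seq_len(h), , drop = FALSE])
      values[i, j] <- baseline - score
    }
  }
  structure(list(
    values = values, baseline_score = baseline, config = cfg,
    input_dim = d,
    row_px = (seq_len(n_r) - 1L) * cfg$stride + 1L,
    col_px = (seq_len(n_c) - 1L) * cfg$stride + 1L
  ), class = "pixlink_occlusion_map")
}

#' @export
print.pixlink_occlusion_map <- function(x, ...) {
  cat(sprintf(
    "<pixlink_occlusion_map> %dx%d grid, baseline %.4f, max decrease %.4f\n",
    nrow(x$values), ncol(x$values), x$baseline_score, max(x$values)))
  invisible(x)
}

#' Pixel location of the strongest occlusion response
#'
#' Centre (row, column) of the patch whose occlusion decreased the output
#' most, in concatenated-input pixel coordinates; ties resolve to the first
#' position in column-major order.
#'
#' @param map A `pixlink_occlusion_map`.
#' @return Named list `row`, `col`, `value`.
#' @export
occlusion_peak <- function(map) {
  i <- which.max(map$values)
  r <- (i - 1L) %% nrow(map$values) + 1L
  c <- (i - 1L) %/% nrow(map$values) + 1L
  list(row = map$row_px[r] + map$config$kernel_height / 2,
       col = map$col_px[c] + map$config$kernel_width / 2,
       value = map$values[r, c])
}

# Nearest-neighbour upsampling of the occlusion grid to input size, with
# each grid value spread over its patch footprint (overlaps averaged).
upsample_map <- function(map) {
  d <- map$input_dim
  acc <- matrix(0, d[1], d[2])
  n <- matrix(0, d[1], d[2])
  for (i in seq_len(nrow(map$values))) {
    rows <- map$row_px[i]:(map$row_px[i] + map$config$kernel_height - 1L)
    for (j in seq_len(ncol(map$values))) {
      cols <- map$col_px[j]:(map$col_px[j] + map$config$kernel_width - 1L)
      acc[rows, cols] <- acc[rows, cols] + map$values[i, j]
      n[rows, cols] <- n[rows, cols] + 1
    }
  }
  out <- acc
  out[n > 0] <- acc[n > 0] / n[n > 0]
  out
}

#' Render an occlusion overlay
#'
#' Clips the map at zero (only decreases are rendered), min-max normalises
#' it, upsamples to input size, and alpha-blends a red heat layer over the
#' grayscale concatenated input. Written as PNG when `path` is given.
#'
#' @param map A `pixlink_occlusion_map`.
#' @param tf_img,target_img The instance's images (must match the map).
#' @param alpha Overlay opacity in `[0, 1]`.
#' @param path Optional PNG destination.
#' @return The blended RGB array (H x W x 3), invisibly if written.
#' @export
render_overlay <- function(map, tf_img, target_img, alpha = 0.5,
                           path = NULL) {
  x <- rbind(tf_img, target_img)
  if (!identical(dim(x), map$input_dim))
    stop("instance dimensions do not match the occlusion map")
  up <- upsample_map(map)
  up[up < 0] <- 0
  rng <- range(up)
  if (diff(rng) == 0) {
    message("occlusion map is uniform; rendering a flat overlay")
    heat <- matrix(0, nrow(up), ncol(up))
  } else {
    heat <- (up - rng[1]) / diff(rng)
  }
  out <- array(0, c(dim(x), 3))
  out[, , 1] <- (1 - alpha * heat) * x + alpha * heat        # red
  out[, , 2] <- (1 - alpha * heat) * x
  out[, , 3] <- (1 - alpha * heat) * x
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}

#' Plot an occlusion map
#'
#' @param object A `pixlink_occlusion_map`.
#' @param ... Unused.
#' @return A ggplot raster of probability decreases over patch positions.
#' @export
autoplot.pixlink_occlusion_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$values)),
                           col = seq_len(ncol(object$values)))
  df$decrease <- as.vector(object$values)[
    (df$col - 1L) * nrow(object$values) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$decrease)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "patch column", y = "patch row",
                  fill = "p decrease") +
    ggplot2::theme_minimal()
}

#' Save an occlusion map as plain-text matrix plus JSON sidecar
#'
#' @param map A `pixlink_occlusion_map`.
#' @param prefix Path prefix; writes `<prefix>.tsv` (the grid) and
#'   `<prefix>.json` (config + baseline score).
#' @return The prefix, invisibly.
#' @export
write_occlusion_map <- function(map, prefix) {
  utils::write.table(map$values, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(baseline_score = map$baseline_score,
         config = unclass(map$config), input_dim = map$input_dim),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
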