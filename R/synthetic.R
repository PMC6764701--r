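#' Specify a synthetic spatial-expression image corpus
#'
#' Defines the study conditions for a simulated in situ hybridization (ISH)
#' style corpus: a universe of transcription factors (TFs) and target genes,
#' each expressed in a small set of spatial "anatomical" regions of an
#' elliptical embryo. A TF regulates a target exactly when the two genes share
#' at least one active region, so regulatory signal lives in *local*
#' co-expression. Each gene additionally receives a global intensity scale, so
#' whole-image brightness is decoupled from the local pattern — two
#' interacting genes can look very different at the whole-embryo scale while
#' agreeing locally.
#'
#' Images follow the standardized embryo-image convention: dark staining on a
#' light background, a fixed frame of `img_width` x `img_height` pixels, and
#' one of three viewing orientations (lateral, ventral, dorsal). The same
#' region index maps to different coordinates in different orientations, so
#' image pairs are only comparable within an orientation.
#'
#' @param n_tfs Number of transcription factors.
#' @param n_targets Number of target genes.
#' @param n_regions Number of spatial expression regions per orientation
#'   (at least 2).
#' @param img_width,img_height Image frame in pixels.
#' @param images_per_gene Inclusive integer range `c(lo, hi)` for the number
#'   of images per gene per orientation; `lo` may be 0, but every gene is
#'   guaranteed at least one image overall.
#' @param regions_per_gene Inclusive integer range for the number of active
#'   regions per gene.
#' @param interaction_density Fraction of all TF x target pairs planted as
#'   true regulatory edges, in (0, 1).
#' @param noise_sd Standard deviation of per-pixel Gaussian noise, on the
#'   [0, 1] intensity scale.
#' @param region_radius_frac Gaussian radius of a region's expression blob,
#'   as a fraction of the image width. The default keeps neighbouring
#'   regions spatially separate (centre spacing of several radii), so pairs
#'   certified as sharing no region also share no stained territory.
#' @param global_scale_range Multiplicative range `c(lo, hi)` for the
#'   per-gene global staining intensity.
#' @param seed Master seed; all stochastic draws flow from it.
#' @return A `pixlink_spec` list.
#' @seealso [generate_corpus()]
#' @export
corpus_spec <- function(n_tfs = 6, n_targets = 24, n_regions = 6,
                        img_width = 320, img_height = 128,
                        images_per_gene = c(1, 3),
                        regions_per_gene = c(1, 2),
                        interaction_density = 0.15,
                        noise_sd = 0.03,
                        region_radius_frac = 0.06,
                        global_scale_range = c(0.5, 2),
                        seed = 1L) {
  spec <- list(
    n_tfs = as.integer(n_tfs), n_targets = as.integer(n_targets),
    n_regions = as.integer(n_regions),
    img_width = as.integer(img_width), img_height = as.integer(img_height),
    images_per_gene = as.integer(images_per_gene),
    regions_per_gene = as.integer(regions_per_gene),
    interaction_density = interaction_density,
    noise_sd = noise_sd,
    region_radius_frac = region_radius_frac,
    global_scale_range = global_scale_range,
    seed = as.integer(seed)
  )
  validate_corpus_spec(spec)
  structure(spec, class = "pixlink_spec")
}

validate_corpus_spec <- function(spec) {
  if (spec$n_regions < 2)
    stop("n_regions must be >= 2 so shared and disjoint region sets exist")
  if (length(spec$images_per_gene) != 2 || spec$images_per_gene[1] < 0 ||
      spec$images_per_gene[1] > spec$images_per_gene[2])
    stop("images_per_gene must be an increasing non-negative range c(lo, hi)")
  if (spec$interaction_density <= 0 || spec$interaction_density >= 1)
    stop("interaction_density must lie strictly inside (0, 1)")
  if (spec$regions_per_gene[1] < 1 ||
      spec$regions_per_gene[2] > spec$n_regions)
    stop("regions_per_gene must lie within [1, n_regions]")
  if (spec$global_scale_range[1] <= 0)
    stop("global_scale_range must be positive")
  invisible(spec)
}

px_orientations <- c("lateral", "ventral", "dorsal")

# Region centres in unit embryo coordinates (x along the major axis,
# y along the minor axis). The same region index lands at different
# coordinates per orientation: the layout is shifted and reflected, which
# mimics how an anatomical structure projects differently per viewing axis.
region_centers <- function(n_regions, orientation) {
  xs <- seq(0.15, 0.85, length.out = n_regions)
  ys <- rep(c(0.3, 0.7), length.out = n_regions)
  switch(orientation,
    lateral = cbind(x = xs, y = ys),
    ventral = cbind(x = rev(xs), y = 0.5 + 0.6 * (ys - 0.5)),
    dorsal  = cbind(x = xs, y = 1 - ys)
  )
}

embryo_mask <- function(h, w) {
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  rx <- 0.47 * w
  ry <- 0.42 * h
  col_idx <- matrix(seq_len(w), h, w, byrow = TRUE)
  row_idx <- matrix(seq_len(h), h, w)
  ((col_idx - cx) / rx)^2 + ((row_idx - cy) / ry)^2 <= 1
}

# Smooth expression blob: darkness added around a region centre.
region_blob <- function(h, w, center, radius_frac = 0.06) {
  cx <- center[["x"]] * w
  cy <- center[["y"]] * h
  r <- radius_frac * w
  col_idx <- matrix(seq_len(w), h, w, byrow = TRUE)
  row_idx <- matrix(seq_len(h), h, w)
  d2 <- (col_idx - cx)^2 + (row_idx - cy)^2
  exp(-d2 / (2 * r^2))
}

render_gene_image <- function(spec, regions, orientation, scale, rng_noise) {
  h <- spec$img_height
  w <- spec$img_width
  mask <- embryo_mask(h, w)
  centers <- region_centers(spec$n_regions, orientation)
  darkness <- matrix(0, h, w)
  for (r in regions) {
    darkness <- darkness +
      0.9 * region_blob(h, w, centers[r, ], spec$region_radius_frac)
  }
  img <- 0.95 - 0.1 * mask - pmin(scale * darkness, 1) * mask * 0.8
  img <- img + rng_noise(h * w) * spec$noise_sd
  img[img < 0] <- 0
  img[img > 1] <- 1
  matrix(img, h, w)
}

#' Generate a synthetic corpus with a planted regulatory network
#'
#' Draws active-region assignments per gene, plants TF-to-target truth edges
#' among pairs that share at least one active region, certifies a pool of
#' negatives among pairs that share none, and renders every image. All
#' randomness derives from `spec$seed`, so the same spec reproduces the same
#' corpus byte for byte.
#'
#' @param spec A [corpus_spec()].
#' @return A `pixlink_corpus`: list with `images` (tibble of `gene_id`,
#'   `orientation`, `image` list-column of `img_height` x `img_width`
#'   matrices in `[0, 1]`), `truth_edges` and `negative_pool` (tibbles of
#'   `tf_id`, `target_id`), `region_assignments` (tibble of `gene_id`,
#'   `regions` list-column), `gene_scales`, and the `spec`.
#' @examples
#' corpus <- generate_corpus(corpus_spec(n_tfs = 2, n_targets = 4,
#'                                       img_width = 64, img_height = 32,
#'                                       seed = 7))
#' nrow(corpus$truth_edges)
#' @export
generate_corpus <- function(spec) {
  validate_corpus_spec(spec)
  withr::with_seed(spec$seed, {
    tf_ids <- sprintf("TF%02d", seq_len(spec$n_tfs))
    target_ids <- sprintf("G%03d", seq_len(spec$n_targets))
    genes <- c(tf_ids, target_ids)

    n_reg <- sample(seq(spec$regions_per_gene[1], spec$regions_per_gene[2]),
                    length(genes), replace = TRUE)
    regions <- lapply(n_reg, function(k) sort(sample.int(spec$n_regions, k)))
    names(regions) <- genes

    all_pairs <- tidyr::expand_grid(tf_id = tf_ids, target_id = target_ids)
    shared <- purrr::map2_int(all_pairs$tf_id, all_pairs$target_id,
      function(a, b) length(intersect(regions[[a]], regions[[b]])))
    n_edges <- round(spec$interaction_density * nrow(all_pairs))
    candidates <- which(shared > 0)
    if (length(candidates) < n_edges) {
      stop(sprintf(paste(
        "cannot plant %d edges: only %d TF-target pairs share an active",
        "region; raise regions_per_gene or lower interaction_density"),
        n_edges, length(candidates)))
    }
    edge_idx <- sort(sample(candidates, n_edges))
    truth_edges <- all_pairs[edge_idx, ]
    negative_pool <- all_pairs[shared == 0, ]

    n_img <- matrix(
      sample(seq(spec$images_per_gene[1], spec$images_per_gene[2]),
             length(genes) * 3, replace = TRUE),
      nrow = length(genes), dimnames = list(genes, px_orientations))
    # every gene must be imaged at least once
    for (g in seq_len(length(genes))) {
      if (sum(n_img[g, ]) == 0) n_img[g, sample.int(3, 1)] <- 1L
    }

    scales <- stats::runif(length(genes), spec$global_scale_range[1],
                           spec$global_scale_range[2])
    names(scales) <- genes

    rows <- list()
    for (g in genes) {
      for (o in px_orientations) {
        k <- n_img[g, o]
        if (k == 0) next
        for (i in seq_len(k)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            gene_id = g, orientation = o, replicate = i,
            image = list(render_gene_image(spec, regions[[g]], o,
                                           scales[[g]], stats::rnorm)))
        }
      }
    }
    images <- dplyr::bind_rows(rows)

    structure(list(
      images = images,
      truth_edges = tibble::as_tibble(truth_edges),
      negative_pool = tibble::as_tibble(negative_pool),
      region_assignments = tibble::tibble(
        gene_id = genes, regions = unname(regions)),
      gene_scales = tibble::tibble(gene_id = genes, scale = unname(scales)),
      tf_ids = tf_ids, target_ids = target_ids,
      spec = spec
    ), class = "pixlink_corpus")
  })
}

#' @export
print.pixlink_corpus <- function(x, ...) {
  cat(sprintf(
    "<pixlink_corpus> %d genes (%d TFs), %d images (%dx%d), %d truth edges\n",
    length(x$tf_ids) + length(x$target_ids), length(x$tf_ids),
    nrow(x$images), x$spec$img_height, x$spec$img_width,
    nrow(x$truth_edges)))
  invisible(x)
}

#' Region bounding box in pixel coordinates
#'
#' Utility for interpretability checks: the axis-aligned box covering the
#' bulk of a planted region's expression blob in a given orientation.
#'
#' @param spec A [corpus_spec()].
#' @param region Region index.
#' @param orientation One of `"lateral"`, `"ventral"`, `"dorsal"`.
#' @param radius_mult Half-width of the box in units of the blob radius.
#' @return Named list `x0, x1, y0, y1` (columns / rows, 1-based, clipped to
#'   the frame).
#' @export
region_bbox <- function(spec, region, orientation, radius_mult = 2.5) {
  centers <- region_centers(spec$n_regions, orientation)
  cx <- centers[region, "x"] * spec$img_width
  cy <- centers[region, "y"] * spec$img_height
  r <- radius_mult * spec$region_radius_frac * spec$img_width
  list(x0 = max(1, floor(cx - r)), x1 = min(spec$img_width, ceiling(cx + r)),
       y0 = max(1, floor(cy - r)), y1 = min(spec$img_height, ceiling(cy + r)))
}

#' Write a corpus to disk as PNG images plus edge lists and a manifest
#'
#' Images are written as 8-bit grayscale PNG named
#' `<gene>__<orientation>__<replicate>.png`; the planted network goes to
#' `truth_edges.tsv` (header `tf_id<TAB>target_id`), the certified negative
#' pool to `certified_negatives.tsv`, and `manifest.json` lists every image
#' with its gene, orientation and MD5 checksum.
#'
#' @param corpus A `pixlink_corpus`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a tibble.
#' @export
write_corpus <- function(corpus, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)

  files <- character(nrow(corpus$images))
  if (nrow(corpus$images) > 0) {
    for (i in seq_len(nrow(corpus$images))) {
      row <- corpus$images[i, ]
      fn <- sprintf("%s__%s__%02d.png", row$gene_id, row$orientation,
                    row$replicate)
      path <- file.path(img_dir, fn)
      ok <- tryCatch({
        png::writePNG(row$image[[1]], path)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) stop("failed to write image: ", path)
      files[i] <- fn
    }
  }
  manifest <- tibble::tibble(
    file = file.path("images", files),
    gene_id = corpus$images$gene_id,
    orientation = corpus$images$orientation,
    md5 = if (length(files)) unname(tools::md5sum(file.path(img_dir, files)))
          else character(0)
  )
  edge_path <- file.path(out_dir, "truth_edges.tsv")
  utils::write.table(corpus$truth_edges, edge_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$negative_pool,
                     file.path(out_dir, "certified_negatives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
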