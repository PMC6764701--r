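# pixlink

Supervised prediction of gene regulatory links from spatial gene-expression
image pairs.

## The problem

Reconstructing a gene regulatory network (GRN) means deciding, for a
transcription factor (TF) and a candidate target gene, whether the TF
regulates the target. In situ hybridization (ISH) imaging records *where*
each gene is expressed — for example across a developing embryo, as
standardized 320 × 128 images in three orientations (lateral, ventral,
dorsal) — and regulatory partners tend to co-express in the same *local*
territories even when their whole-image staining levels are very different.
Global image similarity therefore misses real links; pixlink instead learns
the discriminating local patterns from known interactions.

pixlink is for computational biologists who have (i) per-gene image sets and
(ii) a trusted edge list to supervise with, and who want a tested,
reproducible pipeline from images to a predicted network — plus a synthetic
corpus generator with a planted ground truth so every stage can be exercised
and validated without any external data.

## The method

Each gene $g_i$ has a variable-size image set $X_i$ partitioned by
orientation into $X_{i,l}, X_{i,v}, X_{i,d}$. A labelled TF–target pair
$(g_i, g_j, y_{ij})$ is reduced to single-image instances: within each
orientation, every image of $g_i$ is paired with every image of $g_j$, the
two images are concatenated vertically (TF on top — the order is a
contract), and each instance inherits $y_{ij}$. A convolutional classifier
$\hat f$ scores instances, and the link score is the mean over all of them:

$$\hat y_{ij} = \frac{\sum_{o\in\{l,v,d\}}\sum_{p,q}
\hat f\!\left(x^{(p)}_{i,o}\oplus x^{(q)}_{j,o}\right)}
{\sum_{o\in\{l,v,d\}} |X_{i,o}|\,|X_{j,o}|},
\qquad \text{decision} = \mathbb{1}[\hat y_{ij} \ge 0.5].$$

Two backbones share a 128-tanh → 1-sigmoid head: a faithfully-audited
ResNet-50-style residual network for the full-size problem, and a compact
`small_cnn` for CPU-scale work. Downstream, the package computes the
benchmark metrics (accuracy, F1, top-10% false-positive ratio, score-range
histograms, hit ratio on all-positive link sets), extracts top-K confident
subnetworks with hub-gene degree analysis (SIF/GraphML/TSV export), and
produces occlusion sensitivity maps that localize the image regions driving
each prediction.

## Worked example

A synthetic 30-gene corpus with a planted GRN, trained end to end
(about four minutes on one CPU):

```r
library(pixlink)
library(dplyr)

spec <- corpus_spec(n_tfs = 6, n_targets = 24, interaction_density = 0.25,
                    noise_sd = 0.02, images_per_gene = c(1, 2), seed = 1)
corpus <- generate_corpus(spec)
corpus
#> <pixlink_corpus> 30 genes (6 TFs), 132 images (128x320), 36 truth edges

all_pairs <- tidyr::expand_grid(tf_id = corpus$tf_ids,
                                target_id = corpus$target_ids)
exclusion <- all_pairs |>
  anti_join(corpus$truth_edges,  by = c("tf_id", "target_id")) |>
  anti_join(corpus$negative_pool, by = c("tf_id", "target_id"))
negatives <- sample_negatives(corpus$tf_ids, corpus$target_ids,
                              corpus$truth_edges, exclusion = exclusion,
                              ratio = 1, seed = 1)
pairs <- make_pairs(corpus$truth_edges, negatives)
split <- split_by_gene(pairs, train_frac = 0.8, val_frac_of_train = 0.1,
                       seed = 1)
split
#> <pixlink_split> train 26 / val 3 / test 9 pairs (dropped 34 mixed);
#>   pair-level train fraction 0.763, val fraction 0.103, seed 1

model <- build_model(model_config("small_cnn", input_height = 128,
                                  input_width = 320, head_dropout = 0.1,
                                  head_batchnorm = FALSE, seed = 1))
model <- train_model(model,
                     enumerate_instances(split$train_pairs, corpus$images),
                     enumerate_instances(split$val_pairs, corpus$images),
                     corpus$images,
                     train_config(learning_rate = 0.05, epochs = 10,
                                  batch_size = 16, seed = 1))
glance(model)
#> # A tibble: 1 × 5
#>   backbone  epochs train_loss train_acc best_val_acc
#>   <chr>      <int>      <dbl>     <dbl>        <dbl>
#> 1 small_cnn     10    0.00435         1            1

preds <- predict_links(model, split$test_pairs, corpus$images)
preds |> select(tf_id, target_id, label, score, decision, n_instances)
#>   tf_id target_id label       score decision n_instances
#> 1  TF03      G021     1 0.998843744     TRUE           6
#> 2  TF04      G007     1 0.998933383     TRUE           6
#> 3  TF04      G009     1 0.998957686     TRUE           5
#> 4  TF03      G009     0 0.007612200    FALSE           7
#> 5  TF03      G011     0 0.002718187    FALSE           9
#> 6  TF03      G016     0 0.004485446    FALSE           7
#> 7  TF03      G022     0 0.004789655    FALSE           5
#> 8  TF04      G013     0 0.015303865    FALSE           5
#> 9  TF04      G016     0 0.005571213    FALSE           6

evaluate_predictions(preds)
#> <pixlink_eval> accuracy 1.000, F1 1.000, top-10% FP ratio 0.000
#>   (9 scorable, 0 unscorable)

extract_hubs(top_k_edges(preds, 9), min_degree = 2)
#> <pixlink_hubs> 4 hubs at degree >= 2 (of 9 nodes)
#> # A tibble: 4 × 4
#>   gene_id out_degree in_degree degree
#>   <chr>        <int>     <int>  <int>
#> 1 TF03             5         0      5
#> 2 TF04             4         0      4
#> 3 G009             0         2      2
#> 4 G016             0         2      2
```

Every held-out pair is classified correctly, positives score near 1 and
certified negatives near 0, and the hub table recovers the planted TFs as
the high-degree nodes. `autoplot()` methods visualize training history,
score-range histograms, and occlusion maps; `occlusion_map()` +
`render_overlay()` produce the interpretability overlays.

The whole pipeline is also available as one call — `run_experiment(config,
out_dir)` with a YAML/list configuration — and as a thin command-line tool
(`inst/cli/pixlink`) with `simulate`, `run`, `predict`, `evaluate`, `hubs`
and `occlude` subcommands.

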