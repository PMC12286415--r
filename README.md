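# slidewise

Tile-level classification and slide-level aggregation for whole-slide
histopathology images, built around the recurrence-prediction problem for
odontogenic keratocysts (OKCs): given an H&E-stained whole-slide image
(WSI), predict whether the lesion is of the recurrent or non-recurrent
type.

The package implements the full pipeline natively in R (with Rcpp kernels
for the convolutions):

1. **Tiling + QC** — complete 2048-px tiles from the top resolution level;
   tiles are kept or rejected as *white* (histogram entropy < 4 bits or
   grayscale variance < 100), *blurred* (variance-of-Laplacian < 100) or
   *stain artifact* (mean HSV saturation outside [0.05, 0.95]).
2. **Unsupervised encoder** — a three-stage strided convolutional
   autoencoder compresses a 512×512×3 scaled tile (flattened length
   786,432) to a 12,288-element bottleneck, viewable as a 64×64×3 grid
   (a ×64 reduction).
3. **Hybrid tile classifier** — a convolutional tower
   (conv 32 'same' → pool → conv 64 → pool → conv 128 → pool → conv 64 →
   global average pool) in parallel with a Perceiver-style iterative
   cross-attention branch: image patches become key/value tokens
   (`key_i = W_k x_i + b_k`, likewise values), a trainable latent array
   supplies the queries, attention weights are
   `softmax(q·k_i / sqrt(d))`, and three parallel attention units'
   refined latents are averaged before a sigmoid head. The branches
   concatenate (64 + 2 = 66) into a single sigmoid output unit.
4. **Attention heatmaps** — per-token attention mass mapped back to the
   patch grid, bilinearly upsampled and min-max normalised.
5. **Slide aggregation** — a slide is called *recurrent* when the
   fraction of QC-passing tiles predicted recurrent strictly exceeds
   0.20 (threshold and direction configurable; zero kept tiles gives an
   explicit `indeterminate` status).

Because clinical WSI cohorts are not deposited, the package ships a seeded
synthetic-fixture generator (`make_tile`, `make_slide`): recurrent-like
tiles carry a dark striped band on a pink background, non-recurrent-like
tiles are smooth, plus white and blurred tiles — enough structure to train,
evaluate and localise against, with byte-identical outputs per seed.

## Worked example

```r
library(slidewise)

## architecture bookkeeping
model <- build_classifier()
print(count_parameters(model))

## a small synthetic study (direct 64x64 path for speed)
tiles <- make_tile_set(100, tile_size = 512, noise_sd = 4, seed = 11,
                       transform = function(px) downscale_area(px, 8) / 255)
splits <- split_dataset(data.frame(class_label = tiles$labels),
                        train_config(seed = 11))
sets <- lapply(splits, function(s)
  list(features = tiles$tiles[s$.row], labels = tiles$labels[s$.row]))
model <- train_classifier(model, sets$train, sets$val,
                          train_config(epochs = 25, seed = 11))
print(evaluate_classifier(model, sets$test))

## slide-level call on a synthetic mosaic with 30% recurrent tiles
slide <- make_slide(synthetic_slide_spec(4, 3, 0.3, n_white_tiles = 2,
                                         tile_size = 512, seed = 3))
decision <- classify_slide(slide_handle(slide$pixels), model,
                           qc_cfg = qc_config(tile_size = 512))
print(decision)
```

This prints (about two minutes on one CPU):

```
 layer               output_shape        params
 input               (None, 64, 64, 3)   0
 conv1               (None, 64, 64, 32)  896
 pool1               (None, 32, 32, 32)  0
 conv2               (None, 30, 30, 64)  18,496
 pool2               (None, 15, 15, 64)  0
 conv3               (None, 13, 13, 128) 73,856
 pool3               (None, 6, 6, 128)   0
 conv4               (None, 4, 4, 64)    73,792
 global_average_pool (None, 64)          0
 attention_branch    (None, 2)           348,866
 concatenate         (None, 66)          0
 dense_out           (None, 1)           67
Total trainable parameters: 515,973

<eval_result>
  confusion: TP 20  FP 0  FN 0  TN 20
  recall 1.000  precision 1.000  F1 1.000  accuracy 1.000  AUC 1.000

<slide_decision> slide: recurrent
  tiles: 12 total, 10 kept, 3 predicted recurrent (fraction 0.300, threshold 0.20)
```

Reading it: the conv tower's per-layer counts (896 / 18,496 / 73,856 /
73,792) and the 67-parameter output unit are exact; the attention branch
is dimensioned by `attention_config_search()` against its published
348,867-parameter budget — the closest achievable configuration is one
parameter short (see the methods vignette for why no exact match exists),
hence the total of 515,973. On the separable synthetic tiles the
classifier reaches perfect held-out metrics, and the mosaic slide with a
planted 30% recurrent fraction is called recurrent because 0.30 > 0.20;
two white tiles were QC-rejected and never entered the denominator.

A command-line front end with `simulate` / `qc` / `train-encoder` /
`train` / `evaluate` / `predict-slide` / `run` subcommands lives at
`inst/cli/slidewise.R`, driven by the same functions plus a YAML config
for `run` (see `?run_pipeline`).

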