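# spheroidscreen

Image-based viability classification for 3D spheroid drug-efficacy
screens, in R.

Spheroids grown in hanging drops respond to cytotoxic compounds with a
visible morphological shift — from a round, cohesive mass with a sharp
high-contrast edge towards a blurred, irregular, fragmenting one.
`spheroidscreen` turns that observation into a complete, reproducible
classification pipeline. Because the original micrographs of such
screens are typically not deposited, the package includes a first-class
synthetic data path: a class-conditional micrograph generator and an
Annexin-V flow-cytometry simulator whose gated live fraction provides
the ground-truth label. It is aimed at people building or evaluating
automated spheroid screening readouts who need a tested reference
implementation of the classifier, the labelling rule and the evaluation
protocol.

## What it implements

* **Three-category viability labelling** from a gated Annexin-V live
  fraction *p*: `unaffected` (*p* > 0.80), `mildly_affected`
  (0.40 ≤ *p* ≤ 0.60), `affected` (*p* < 0.40); the uncovered band maps
  to `unlabeled` and is excluded from training.
* **The reference CNN**: input 400×320×1; four blocks of 3×3
  valid-padding convolution (32/64/64/128 filters) + ReLU + 2×2
  max-pool; flatten (52,992 features); dense 128 + ReLU + dropout;
  dense 3 + softmax — 6,913,091 trainable parameters. Shape inference
  (`out = in − k + 1` for conv, `⌊in/2⌋` for pool) and parameter
  counting (`kh·kw·c_in·c_out + c_out`; `n_in·n_out + n_out`) are exact,
  and the trainable instance (from-scratch RcppArmadillo engine with
  Adam, cross-entropy, inverted dropout) allocates exactly that count.
* **The evaluation protocol**: stratified 80/20 train/test split,
  five-fold cross-validation of the training pool (1,200 images → 960
  pool / 240 test; folds 768 train / 192 validation), 50 epochs with
  real-time augmentation (rotation, shear, zoom, horizontal flip,
  rescale) on training folds only, fold-averaged accuracy curves,
  best-fold selection, and per-class precision / recall /
  F1 = 2·p·r/(p+r) on the held-out test set.
* **Morphometry baseline**: Otsu segmentation, projected-area sphere
  volume in arbitrary units (V = 4/3·π·r_eq³), boundary edge contrast
  (mean Sobel gradient on the mask perimeter), solidity and component
  count, plus a two-threshold edge-contrast classifier that must also
  separate the synthetic classes — proof the signal is morphological.

## Worked example

Inspect the architecture:

```r
library(spheroidscreen)
s <- model_summary(model_spec())
head(s, 4)
#>            layer         output_shape params
#>         conv2d_1 (None, 398, 318, 32)    320
#>     activation_1 (None, 398, 318, 32)      0
#>  max_pooling2d_1 (None, 199, 159, 32)      0
#>         conv2d_2 (None, 197, 157, 64)  18496
attr(s, "total")
#> [1] 6913091
```

Run the reduced-scale (64×64, 60 images/class, 10 epochs) pipeline in
about a minute on one CPU:

```r
ds   <- simulate_dataset(per_class = 60,
                         config = simulation_config(64, 64, base_radius = 16),
                         seed = 1)
plan <- make_splits(ds$manifest, seed = 1)          # 144 pool / 36 test
cv   <- train_cv(ds$images, ds$manifest$true_class, plan,
                 model_spec(input_shape = c(64, 64, 1)),
                 augmentation_config(), epochs = 10, batch_size = 16,
                 seed = 1)
tail(cv$curves, 3)
#>    epoch   acc_avg val_acc_avg
#> 8      8 0.8262969   0.9241379
#> 9      9 0.9061769   0.9034483
#> 10    10 0.8697301   0.9576355
evaluate(cv$best_model, ds$images[plan$test_idx],
         ds$manifest$true_class[plan$test_idx])
#> Test accuracy: 1.000
#>            class precision recall f1 support
#>       unaffected         1      1  1      12
#>  mildly_affected         1      1  1      12
#>         affected         1      1  1      12
```

`acc_avg`/`val_acc_avg` are training and validation accuracy averaged
over the five folds per epoch; the final table is the per-class report
of the best fold model on the untouched 20% test split. The full-scale
profile (`default_run_config("full")`: 400×320, 400 images/class, 50
epochs) runs the same code path and is a multi-hour CPU job.

A shell workflow is available as a thin wrapper:

```sh
Rscript inst/cli/spheroid-screen.R simulate --profile smoke --out ds/
Rscript inst/cli/spheroid-screen.R train    --profile smoke --data ds/
Rscript inst/cli/spheroid-screen.R inspect
Rscript inst/cli/spheroid-screen.R baseline --profile smoke --data ds/
```

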