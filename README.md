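# sndm — self-normalized density maps for counting microbial colonies

Counting colonies on Petri dishes decides whether a sample is contaminated,
and doing it by eye is slow. `sndm` is an R toolkit for *density-map*
counting: a nested U-shaped convolutional network transforms a dish image
into a non-negative map whose pixel sum is the colony count,

> **y** = M(**x**),  count = Σᵢⱼ yᵢⱼ,

with ground-truth maps built by stamping each annotated bounding-box center
onto an empty map and blurring with a per-colony unit-mass Gaussian. The
package's centerpiece is the **self-normalized density map (SNDM)**: a
bypass head reads the deepest encoder features and predicts a per-image
scalar β that rescales every output logit map, Pᵢ = σ(β·Sᵢ), letting the
network correct its own density normalization (the classic failure mode of
plain DM models on crowded dishes). Training uses deep supervision — a
pixel-summed binary cross entropy on the fused map and every side map —
plus the penalty ½(1−β)² expressing the prior β ≈ 1; β is produced by a
bounded activation λ·σ(z) with λ = 1.5.

Included, all tested end to end on one CPU:

* a synthetic Petri-dish scene generator with bounding-box annotations
  (circular dish, three illumination modes, overlapping and near-edge
  colonies, 0–100 colonies with ~85% of dishes under 50) standing in for
  request-only laboratory datasets;
* count-conserving density-target rendering and counting by pixel sum;
* the nested-U network (miniature and full-scale 11-block layouts) with
  forward, backward and Adam implemented from first principles in
  RcppArmadillo — in `dm` mode (β ≡ 1) and `sndm` mode;
* uncertainty quantification by **bootstrap ensembles** (B = 20 subsets of
  ≈0.63 N pairs, population-variance 1σ) and **Monte Carlo dropout**
  (r = 20 stochastic passes);
* counting metrics (MAE, sMAPE with a documented 0/0 convention),
  1σ calibration, stratified reports (≤50 / >50 colonies), uncertainty
  binned by colony size and coverage, and β-versus-coverage linear fits per
  size group;
* tidyverse-native surfaces: tibble records, `tidy()`/`glance()` methods,
  `autoplot()` for scenes, fits and evaluations, plus a thin CLI
  (`inst/scripts/sndm`) with generate / make-targets / train / predict /
  evaluate / smoke subcommands.

## Worked example

Generate a small annotated benchmark, train a miniature DM and SNDM, and
compare them:

```r
library(sndm)

p <- scene_params(image_size = 48L,
                  count_distribution = count_nbinom(mu = 6, size = 2,
                                                    max_count = 20L),
                  seed = 7L)
scenes <- lapply(sndm:::derive_seeds(7L, 60L),
                 function(s) generate_scene(p, seed = s))
recs  <- prepare_training_set(scenes)          # images + clipped targets
train <- recs[1:40]; val <- recs[41:50]; test <- scenes[51:60]

tc <- train_config(learning_rate = 1e-3, max_epochs = 15L, seed = 1L)
fit_dm   <- fit_sndm(build_model(model_config("dm",   input_size = 48L,
                                              base_channels = 4L, seed = 2L)),
                     train, val, tc)
fit_sndm <- fit_sndm(build_model(model_config("sndm", input_size = 48L,
                                              base_channels = 4L, seed = 2L)),
                     train, val, tc)

glance(evaluate_model(fit_dm,   test, "single"))
glance(evaluate_model(fit_sndm, test, "single"))

mc <- mc_dropout_predict(fit_sndm$model, test[[1]],
                         dropout_config(r = 20L, seed = 3L))
mc
```

Output from this exact script:

```
# A tibble: 1 × 5
  method     N   mae smape within_1sigma
  <chr>  <int> <dbl> <dbl>         <dbl>
1 single    10  2.01  23.7             0
# A tibble: 1 × 5
  method     N   mae smape within_1sigma
  <chr>  <int> <dbl> <dbl>         <dbl>
1 single    10  2.01  23.8             0
<ensemble_prediction> mc_dropout: count 4.22 +- 1.622 (1 sigma, 20 members)
```

`mae` is the mean absolute counting error in colonies; `smape` the
symmetric percentage error, inflated here by very low true counts;
`within_1sigma` is the share of dishes whose true count lies inside the
predicted ±1σ band (0 here because single-pass predictions carry σ = 0 and
count as covered only when exact). The Monte Carlo dropout line reads
"about 4 colonies, ±1.6 at 1σ" for the first test dish, whose true count
is 6. On sparse 48 px toy dishes the two modes coincide (β stays near 1 and
both land at MAE 2.01) — the self-normalization earns its keep on crowded
dishes, where plain density maps underestimate. The package's acceptance
experiment runs the comparison at 96 px on 300 scenes with counts up to 60;
there the SNDM miniature cuts the crowded-stratum MAE from 10.1 to 6.0 and
the overall MAE from 1.88 to 1.59 (printed by
`tests/testthat/test-acceptance.R`'s headline-analog test under its fixed
seed).

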