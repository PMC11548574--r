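# ccan — cross-attention class alignment for heterogeneous EEG transfer

`ccan` trains cross-subject motor-imagery (MI) EEG classifiers in the
*heterogeneous* setting: the new (target) subject and the auxiliary
(source) subjects may have performed **different imagery task sets**
(heterogeneous label spaces) and may even have been recorded with
**different montages and sampling rates** (heterogeneous feature spaces).
It is aimed at BCI researchers who want a complete, CPU-only, dependency-
light reference implementation of class-conditional cross-domain
alignment, together with the scaffolding needed to study it: scenario
enumeration, preprocessing, a synthetic EEG generator and a seeded
training loop.

## The method

Classes are paired positionally by an arrow notation: `1,2->1,3` matches
source class 1 with target class 1 and source class 2 with target class 3;
both sides are remapped to indices `0..M-1`.  Five scenario families over
the four-class MI universe are supported (binary/ternary, partially or
completely different labels, plus one cross-dataset problem), with
enumeration counts 24, 12, 6, 12 and 1.

Each mixed batch (half source, half target) flows through four components:

* a **generator** of two convolutional pathways (40 temporal kernels of
  length *L* and 40 spatial kernels of length *C*, in opposite orders,
  with batch norm, ELU, average pooling and dropout), fused into `t`
  tokens of width `D = 80`;
* a **cross-encoder**: multi-head self-attention
  `Attention(Q,K,V) = softmax(QKᵀ/k)V` per domain, then three parallel
  cross-attention operations (summed) in which the source stream provides
  in turn the values, queries and keys while the target stream supplies
  the rest; the target path never reads the source;
* a **class discriminator** (layer norm + linear map to `r` units) trained
  with the alignment ratio loss

  `L_dis = L_corr / L_ncorr`,

  where `L_corr` is the mean Euclidean distance between source and target
  mean features of corresponding classes and `L_ncorr` the mean over
  non-corresponding ordered pairs;
* **dual softmax classifiers** sharing a cross-entropy loss
  `L_cls = −(1/Bn) Σᵢ Σₘ y_im log(ŷ_im)`; predictions average the heads.

Training alternates two ADAM steps per batch (lr 2·10⁻⁴, β₁ = 0.5,
β₂ = 0.999, batch 64): step 1 updates generator + encoder + discriminator
under `L_dis`; step 2 updates generator + encoder + classifiers under
`L_joint = L_cls + w_cen·L_cen`, where the centre loss `L_cen` pulls every
feature toward its class centre in the target domain.  Accuracy is
`Σᵢ aᵢᵢ / N` on the target-test confusion matrix.

There is no deep-learning framework underneath: the package ships a small
reverse-mode autodiff engine (R tape + Armadillo batched matmuls) that the
whole network runs on.

## Worked example

A scenario-1 problem (`1,2->1,3`) on synthetic EEG: 4 latent classes,
8 channels at 100 Hz, 3 source subjects, snr 5.

```r
library(ccan)

cfg  <- synthetic_config(n_trials_per_class = 16, classes = 1:4, C = 8,
                         T = 250, fs = 100, snr = 5, seed = 7)
pair <- generate_domain_pair(cfg, cfg, n_source_subjects = 3)
spec <- parse_spec("1,2->1,3", scenario_id = 1)
data <- assemble_scenario(spec, pair$source, pair$target, split = 0.5, seed = 7)
data
#> <scenario_data> 1,2->1,3 | source 96 trials, target 16 train / 16 test, shared generator: TRUE

mcfg <- model_config(C = 8, T = 250, M = 2, L = 10,
                     pool_len = 40, pool_stride = 10)
tcfg <- train_config(epochs = 30, batch = 32, seed = 7)
res  <- fit(data, mcfg, tcfg)

round(res$accuracy, 3)          # per-epoch target-test accuracy
#>  [1] 0.5 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0
#> [20] 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0 1.0
evaluate(res$model, data$target_test)$confusion
#>      [,1] [,2]
#> [1,]    8    0
#> [2,]    0    8
round(res$alignment$init, 3); round(res$alignment$final, 3)
#> [1] 0.909
#> [1] 0.437
```

The accuracy trace shows the target subject's held-out trials being
decoded perfectly from epoch 2 on; the confusion matrix counts true class
(rows) against predicted class (columns).  The alignment numbers are the
mean distance between corresponding-class mean features in discriminator
space before and after training — alignment tightens while accuracy rises.

A thin command-line front end (`inst/cli/ccan.R`) exposes `simulate`,
`enumerate`, `build-scenario`, `train` and `evaluate` subcommands over the
same functions.

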