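# segmatch

Semi-supervised semantic segmentation for instrument-like scenes, built
around consistency regularization with adversarially refined strong
augmentations — plus the full evaluation-metric stack used in surgical
instrument segmentation (Dice, Normalized Surface Dice with a pixel
tolerance, and the Ch_IoU / ISI_IoU / mc_IoU family).

**Who it is for.** Researchers who want a fully seeded, CPU-sized, dependency
-light testbed for FixMatch-style semi-supervised segmentation: every
component — synthetic data, backbone, augmentations, attack, losses, metrics
— is implemented here in R (convolutions in C++ via Rcpp), with exact
hand-written gradients, so the algorithm is testable end-to-end without
datasets, GPUs or a deep-learning framework.

## The algorithm

One network $f_\theta$ (a residual encoder–decoder) is trained on batches
mixing labelled and unlabelled images:

- labelled images: soft Dice + cross-entropy loss $L_s$;
- each unlabelled image goes through two branches sharing $\theta$:
  - **weak branch** — an invertible spatial transform $\omega_e$ (flip,
    90° rotation, crop/resize); the prediction is mapped back with
    $\omega_e^{-1}$ (segmentation is equivariant to spatial transforms),
    sharpened per pixel, $\tilde y_i = \mathrm{Sharpen}(\mathrm{Softmax}(p_{w_i}), T)$,
    and filtered to the confident set $N_v = \{i: \max_c p^c_{w_i} \ge t\}$;
  - **strong branch** — three random photometric ops, then $K$ iterations of
    I-FGSM against the frozen network,
    $x^s_{k+1} = \mathrm{Clip}_{x^s_0,\epsilon}\{x^s_k +
    \tfrac{\epsilon}{K}\mathrm{sign}(\nabla_{x^s_k} L_u)\}$,
    so the consistency target is enforced on the hardest admissible input;
- the unsupervised loss is the confidence-masked soft cross-entropy
  $L_u = \frac{1}{|D_u|}\sum_u \frac{1}{|N_v|}\sum_{i\in N_v}
  \ell_{CE}(\tilde y_i, p_i)$, and the total objective is
  $L = L_s + w(t)\,L_u$ with a Gaussian ramp-up $w$ ($w(0)=0$).

Defaults: $\epsilon = 0.08$, $K = 25$ (desk profile: 3), $T = 0.5$,
$t = 0.8$, SGD momentum 0.95, learning rate $0.01(1 - e/E) \times 0.7$.
See `vignettes/segmatch-methods.Rmd` for assumptions, numerical choices and
limitations.

## Worked example

```r
library(segmatch)

# a seeded synthetic world: bright capsule "instruments" over textured tissue
sc  <- scene_config(height = 32, width = 32, n_classes = 2,
                    object_width_range = c(3, 6),
                    background_texture_scale = 8, seed = 1)
ds  <- generate_dataset(sc, 80, labelled_fraction = 0.1)  # 8 labelled, 72 not
test_sc <- sc; test_sc$seed <- 999L
test <- lapply(1:30, function(i) generate_scene(test_sc, i))

tc  <- train_config(epochs = 15, batch_size = 8, seed = 1,
                    adversarial = adv_config(epsilon = 0.08, steps = 3),
                    loss = loss_config(rampup_epochs = 5))
mc  <- model_config(depth = 2, base_channels = 8, n_classes = 2, seed = 1)
fit <- train(ds, tc, mc)
rep <- evaluate(fit$model, test, n_classes = 2)
round(c(dice = rep$dice, nsd = rep$nsd), 3)
```

On this machine the snippet prints (numbers are deterministic for the seed):

```
 dice   nsd
0.929 0.978
```

i.e. after 15 epochs on 8 labelled + 72 unlabelled 32×32 scenes the model
reaches a mean foreground Dice of about 0.93 on 30 held-out scenes, and
about 98% of boundary pixels lie within the scaled NSD tolerance (1 px at
this resolution) of the true boundary. With 30 epochs and the acceptance
protocol (supervised baseline at equal step budget, 3 seeds) the
semi-supervised gain over supervised-only training is +0.9 to +1.1 Dice
percentage points per seed. `fit$history`
holds per-epoch `L_s`, `L_u`, ramp weight, attack norm and confident-pixel
fraction.

## Command line

```sh
inst/exec/segmatch generate --config cfg.yaml --out data/
inst/exec/segmatch train    --config cfg.yaml --data data/ --out run/
inst/exec/segmatch evaluate --pred run/preds --gt data/masks --tolerance 13 --classes 2
inst/exec/segmatch ablate   --config cfg.yaml --out ablation/
```

`cfg.yaml` overrides keys of a profile (`profile: desk` or `paper`); unknown
keys are rejected. `generate` writes `images/NNNN.png`, `masks/NNNN.png`
(8-bit class ids) and `split.json`; `train` writes `history.csv`,
`model.json` and `report.json`; `ablate` trains the
full / no-adversarial / no-weak / no-strong grid and writes
`ablation.json`.

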