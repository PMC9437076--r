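# sctflow

Structure- and flow-constrained cycle-consistent adversarial translation of
T2-weighted MR into synthetic CT (sCT) for MR-only radiotherapy planning.

MR gives the soft-tissue contrast needed to delineate organs at risk, but no
electron density for dose calculation; a synthetic CT fills that gap. This
package implements four paired-training objectives over one shared
architecture (two residual generators, two patch discriminators):

| variant      | generator objective                                        |
|--------------|------------------------------------------------------------|
| `cyclegan`   | L<sub>GAN</sub> + 10 L<sub>cycle</sub>                     |
| `structcgan` | L<sub>GAN</sub> + 8 L<sub>cycle</sub> + 2 L<sub>SSIM</sub> |
| `flowcgan`   | L<sub>GAN</sub> + 8 L<sub>cycle</sub> + 2 L<sub>flow</sub> |
| `sfcgan`     | L<sub>GAN</sub> + 6 L<sub>cycle</sub> + 2 L<sub>SSIM</sub> + 2 L<sub>flow</sub> |

with least-squares adversarial terms, windowed SSIM (11×11, C1 = 0.0001,
C2 = 0.009), and a dual-sided optical-flow consistency term: dense Farneback
flow is precomputed between adjacent ground-truth axial slices, and the
synthesized slice *n* is warped towards both ground-truth neighbours,
`||f(n,n−1)(sCT_n) − CT_{n−1}||₁ + ||f(n,n+1)(sCT_n) − CT_{n+1}||₁`,
averaged over modalities. Alongside the models it ships the whole pipeline:

* **preprocessing** — body masking (0 outside the body for MR, −1024 HU for
  CT), truncation (CT at 1400 HU, MR at the in-body 99th percentile),
  invertible 16-bit normalization, end-slice trimming, bicubic resizing,
  site-based train/test split (sites 2+3 train, site 1 test);
* **optical flow** — a Farneback polynomial-expansion estimator and a
  bilinear warping operator (no external CV dependency);
* **training** — Adam, batch 4, 200 epochs with a 100 + 100 constant/linear
  learning-rate schedule, 50-image history buffers, seeded and resumable;
* **evaluation** — ME / MAE (HU, after denormalization) and PSNR (16-bit
  scale) inside the body contour and per organ mask, aggregated as
  mean ± SD across volumes;
* **synthetic phantoms** — seeded co-registered pseudo-MR/CT pelvis pairs
  with organ masks and smooth interslice drift, so the whole pipeline runs
  with no external data.

The network engine (convolutions, instance norm, residual blocks,
backpropagation, Adam) is implemented in the package itself over
RcppArmadillo kernels and is finite-difference-checked in the test suite.

## Worked example

Generate a small cohort, preprocess it, precompute flows, train the combined
model briefly, and evaluate the synthesized CT in HU:

```r
library(sctflow)

cohort <- generate_cohort(4, site_assignment = c(1, 2, 2, 3), seed = 7,
                          n_slices = 12, size = 64)
pairs  <- lapply(cohort, function(ph)
  list(ct = prepare_volume(ph$ct, target = 64),
       mr = prepare_volume(ph$mr, target = 64)))
caches <- lapply(pairs, function(p)
  list(ct = build_flow_cache(p$ct), mr = build_flow_cache(p$mr)))

sites <- vapply(pairs, function(p) p$ct$site_id, integer(1))
ds <- make_training_set(pairs[sites != 1], caches[sites != 1])

cfg <- train_config("sfcgan", epochs = 5, batch_size = 4, seed = 1,
                    ngf = 3, ndf = 3, n_res = 2,
                    lr_constant_epochs = 5, lr_decay_epochs = 0)
res <- train(cfg, ds)
tail(res$history[, c("epoch", "gan", "cycle", "ssim", "flow", "g_net")], 3)

ti  <- which(sites == 1)[1]
sct <- translate_slices(res$state$g_ct, pairs[[ti]]$mr$slices)
evaluate_volume(pairs[[ti]]$ct$slices, sct, pairs[[ti]]$ct$body_mask,
                rec = pairs[[ti]]$ct$record)
```

On this 64×64 phantom cohort with deliberately narrow networks the 5-epoch
run prints:

```
  epoch    gan  cycle   ssim   flow  g_net
3     3 0.5504 1.2486 0.7485 1.1233 11.786
4     4 0.4862 1.1202 0.7072 0.9690 10.560
5     5 0.4007 0.9467 0.6505 0.8277  9.038

  region ME_HU MAE_HU PSNR_dB n_voxels
1   body -90.4  154.3   21.11    12814
```

Every component of `g_net` falls as training proceeds (cycle from ~1.7 at
the start to 0.95; the weighted total from ~14 to 9.0), and the held-out
volume's body-contour MAE of 154 HU compares with 351 HU for the same
generator before any training. These are desk-scale diagnostics from a
width-3 network after 30 optimizer steps — they demonstrate the machinery,
not clinical image quality.

A thin command-line interface over the same functions is installed at
`inst/cli/sctflow.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sctflow.R", package="sctflow"))')" \
    simulate --patients 4 --out phantoms --size 64 --seed 7
```

with further subcommands `prepare`, `flow`, `train`, `evaluate`
(see `?sctflow_cli`).

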