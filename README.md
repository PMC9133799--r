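# voxrecon

Reconstructing the image a subject was looking at — and naming its
semantic category — from voxelwise brain responses is starved for data:
paired (image, fMRI) samples number in the hundreds to low thousands and
cover a sliver of natural-image categories. `voxrecon` implements a
self-supervised two-network approach to this problem for R, together
with its evaluation suite and interpretability tools, all testable end
to end against a simulated "virtual subject" with known ground truth.

The core idea: train an image→voxel **encoder** `E` on the scarce paired
data under the fMRI loss

    L_r(r̂, r) = α·MSE(r̂, r) − (1 − α)·cos∠(r̂, r),   α = 0.9,

then freeze it and train a voxel→image **decoder** `D` on mixed batches
that combine a supervised term `L_D = L_s(D(r), s)` on paired samples
with a cycle-consistency term `L_ED = L_s(D(E(s)), s)` on *unpaired*
images (no responses, no labels). The image loss
`L_s = L_RGB + L_perceptual + λ_TV·TV` mixes pixel error with a
perceptual similarity measured on channel-normalized multi-block
features of a hierarchical backbone. Because unpaired images are cheap,
the decoder can adapt to image and category statistics beyond the paired
set; the package quantifies the effect through n-way identification and
category-free classification of reconstructions against a class-centroid
gallery (Pearson correlation ranking, rank scores, top-k). Noise ceilings (split-half, Spearman–Brown), voxelwise
prediction accuracy, and population-receptive-field estimation
(gradient-based and weight-based, with eccentricity/polar-angle
summaries) complete the toolbox.

There is no deep-learning framework underneath: the networks, the
backward passes and the Adam optimizer are implemented in R with a few
compiled convolution/readout kernels (RcppArmadillo), and every gradient
is verified against central finite differences in the test suite.

## A worked example

Simulate a subject and benchmark, train both phases, and evaluate:

```r
library(voxrecon)

subject <- virtual_subject(n_voxels = 100, image_side = 32,
                           sigma_n = 0.5, seed = 1)
bench <- make_benchmark(stimulus_spec(image_side = 32), subject, seed = 1)

bb  <- backbone_spec(seed = 1)
enc <- train_encoder(bench$train,
                     encoder_config(n_voxels = 100, image_side = 32),
                     bb, train_schedule(epochs = 15, lr = 3e-3,
                                        milestones = c(10, 13)))$model

dcfg <- decoder_config(n_voxels = 100, base_resolution = 4,
                       base_channels = 32, up_channels = c(32, 16, 16),
                       kernel = 3)
dec <- train_decoder(bench$train, bench$unpaired, enc, dcfg,
                     train_schedule(epochs = 15, milestones = c(10, 13),
                                    drop_factor = 0.2))$model

Rbar   <- apply(bench$test$responses, c(1, 3), mean)  # repeat-averaged
recons <- decode(dec, Rbar)
nway_identification(recons, bench$test$images,
                    bench$unpaired$images[1:100], n = 2,
                    seed = 1, backbone = bb)$accuracy
```

Running `scripts/acceptance.R` (below) with `--seed 1` prints, among
others:

```
noise_ceiling_median                     0.9681  (n = 100)
encoder_prediction_r_median              0.5026  (n = 100)
ident_2way_selfsup_pct                  54.0000  (n = 16)
ident_2way_supervised_pct               54.2500  (n = 16)
class_rank_median_selfsup               61.0000  (n = 16)
class_rank_median_supervised            57.5000  (n = 16)
prf_center_error_median_px               1.8134  (n = 60)
prf_confined_fraction_pct               95.0000  (n = 60)
```

Reading: with 8 test repeats the measurement ceiling is high (0.97); the
encoder explains a modest share of single-voxel variance at this scarce
(96-pair), low-SNR scale; identification of the seen image and
classification rank are close to chance and near-identical for the
self-supervised and supervised-only decoders — at this desk scale the
decoder is limited by the information in the responses rather than by
training data, so the benefit of unpaired training does not materialize
(the methods vignette analyzes why, and what regime it needs). The
encoder's gradient receptive fields land within ~2 px of the generative
ground-truth pRF centers, with 95% of maps spatially confined.

## Command line

A thin CLI over the same functions lives at `inst/cli/voxrecon.R`:

```sh
Rscript inst/cli/voxrecon.R simulate --out bench --seed 7
Rscript inst/cli/voxrecon.R train-encoder --data bench --out enc.rds
Rscript inst/cli/voxrecon.R train-decoder --data bench --encoder enc.rds --out dec.rds
Rscript inst/cli/voxrecon.R reconstruct --data bench --decoder dec.rds --out recon
Rscript inst/cli/voxrecon.R evaluate --data bench --recon-dir recon --out eval.csv
Rscript inst/cli/voxrecon.R classify --data bench --recon-dir recon --out ranks.csv
Rscript inst/cli/voxrecon.R prf --encoder enc.rds --out prf.csv
```

Every run writes a JSON manifest (resolved configuration, seed, package
version) next to its output.

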