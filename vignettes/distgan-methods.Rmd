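---
title: "Adversarial distance-map regression: models, mappings and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial distance-map regression: models, mappings and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distgan)
```

## The problem and the model

Protein structure prediction from sequence hinges on estimating, for every
residue pair $(i, j)$, the spatial distance between their reference atoms.
`distgan` implements a *regression* approach: a convolutional generator $G$
maps a stack of sequence-derived features $x$ (130 channels over the
$L \times L$ pair grid) to a real-valued distance map, and a discriminator
$D$ is trained adversarially to tell generated maps from experimental ones
*conditioned on the same features*. The discriminator loss is the standard
binary cross-entropy of a sigmoid classifier,

$$\mathcal{L}_D = -\big(\mathbb{E}_{x,y}[\log D(x,y)] +
  \mathbb{E}_{x}[\log(1 - D(x, G(x)))]\big),$$

and the generator combines the adversarial objective with a
$\lambda$-weighted L1 regression term,

$$\mathcal{L}_G = \mathbb{E}_x[-\log D(x, G(x))] +
  \lambda \, \|G(x) - y\|_1,$$

using the non-saturating form of the adversarial term so that the generator
keeps receiving gradient even while the discriminator confidently rejects
its outputs. A generator-only baseline trained with $\lambda \|G(x)-y\|_1$
alone (the *control*) is the reference point for every adversarial claim:
pure L1 regression recovers low frequencies (local averages) well but blurs
the sharp stripes — secondary-structure contact patterns — that make a
distance map usable for folding. The adversarial term exists to restore
that high-frequency texture.

Two discriminator designs are provided. The *patch classifier* is a fully
convolutional network of 4×4 kernels (stride 2 except the last two layers,
first width doubling per layer, final sigmoid channel) whose output is a
grid of per-patch probabilities; its receptive field is the patch size, and
`receptive_field()` computes it analytically
($RF = 1 + \sum_i (k_i - 1)\prod_{j<i} s_j$; 4 layers give 34, 5 layers
give 70). The *spatial-pyramid-pooling* classifier — the preliminary design
— pools three convolution layers over 8×8, 4×4 and 2×2 partitions into a
fixed-length vector and scores the whole map with one scalar. The patch
variant judges local texture rather than global appearance, treating the
map as a Markov random field; a modified discriminator loss that clips the
fake-side argument to $[0, 0.9]$ is available so that fake patches already
judged realistic (e.g. blank long-range background) drop out of the
discriminator's learning signal.

## Mappings between real space and training space

Networks with batch normalisation and bounded activations train on values
in $(-1, 1)$ ("training space"). Labels map through
$V_{TS} = \tanh\!\big((5 V_{RS} - 50)/12\big)$: the inner linear transform
sends the informative 4–16 Å band onto $[-2.5, 2.5]$, where tanh has its
largest derivatives, so that band occupies most of the output range while
all distances remain representable and the map stays invertible. The
inverse, applied to symmetrised generator output, recovers Ångströms.
Before inversion, values are clamped to $[-1 + 10^{-7}, 1 - 10^{-7}]$: a
saturated tanh output is otherwise not invertible, and a bounded clamp
keeps inference deterministic. Feature channels instead map linearly,
$V_{TS} = (2V_{RS} - \mathrm{Max} - \mathrm{Min})/(\mathrm{Max} -
\mathrm{Min})$, with the extremes taken per channel over the grid of the
protein at hand (per-protein statistics keep inference streaming —
no dataset pass is needed). A constant channel (e.g. the broadcast protein
length) maps to zeros with a warning rather than an error, because such
channels are legitimate.

## Architecture choices

The generator is a residual network: blocks of three convolutions
(3-per-block outperformed 2-per-block in the source experiments), each
convolution followed by its activation and then batch normalisation, with
7×7 kernels in the published configuration and Swish
($x \cdot \sigma(\beta x)$, one learnable $\beta$ per layer, initialised
at 1) as activation. The final convolution has one channel and a tanh, so
outputs live in training space by construction. Capacity presets follow
the published split: a 77-conv-layer Model X for chains of ≤ 350 residues
and a lighter 52-layer Model L for longer chains (`route_model()` applies
the 350-residue threshold). Total conv layers are stem + blocks + head;
when the body count is not a multiple of the block size the remainder is
placed as plain convolutions before the head (the exact interior layout of
the published models is not specified, so this rule is ours).

The attention module reweights the input stack in two stages:
channel attention (a 130–75–130 bottleneck perceptron on the sum of global
average and max pooling per channel, sigmoid output) followed by pixel
attention (a single 7×7 convolution over the 2-channel concatenation of
per-pixel channel mean and max, sigmoid output), composed exactly as
$(\mathrm{Raw} \times \mathrm{CAF}) \times
\mathrm{PAF}(\mathrm{Raw} \times \mathrm{CAF})$. The motivation is that the
four genuinely 2D channels occupy only 3% of the input and risk being
swamped by 124 broadcast 1D channels.

Unstated details we fixed: leaky-ReLU slope 0.2 in the discriminator;
discriminator batch normalisation present but switchable (see below); Adam
$\beta_1 = 0.5$, $\beta_2 = 0.999$, the customary setting for adversarial
training; discriminator and generator alternate 1:1 per minibatch; log
arguments clamped at $10^{-7}$ with all clamp events counted in the
training log.

## Training data flow

Every protein is its own minibatch (sizes vary; batch normalisation then
acts per channel over the pair grid). Per epoch, each protein contributes
six ground truths drawn without replacement from its label ensemble — the
deposited structure plus conformational snapshots — emulating the source
pipeline's use of molecular-dynamics snapshots as label augmentation. The
published schedule (100 epochs at 1e-4/1e-5/1e-6 over 20/30/50-epoch
stages) is the default `lr_schedule_staged()`; desk-scale runs use the
same staged shape at higher rates (`desk_lr_schedule()`) because tiny
networks at a few hundred updates need larger steps to move at all.
Reported losses are exponential-moving-average smoothed (decay 0.99).
Final predictions average the upper and lower output triangles, then
invert the label mapping; restraints are exported for pairs predicted
inside 4–16 Å as `center ± 0.4 Å`, 1-based residue indexing, in
CNS/CONFOLD-style `assign` statements.

## What the synthetic proteins emulate — and what they do not

Real training data (thousands of PDB chains, HHblits alignments, CCMpred
couplings, predicted secondary structure and solvent accessibility) is out
of scope; the package generates its own study system so that every stage
runs and is testable offline:

* **Backbones** are single-trace-atom chains of ideal-geometry segments
  (helix 1.5 Å rise / 100° twist, strand 3.3 Å rise, persistent-random-walk
  loops) with a soft confinement bias and rejection sampling until
  clash-free. They have realistic local geometry and globular contact
  density but no side chains, no sequence, and no evolutionary structure.
* **Jitter ensembles** replace molecular dynamics for label augmentation:
  cumulative seeded Gaussian perturbation with bond-length re-projection,
  honouring the snapshot schedule (total steps / save interval; the
  published 2,500,000 / 5,000 gives 500 snapshots) and the qualitative
  property that structures drift away from the start. There is no force
  field, so the *physics* of the augmentation is not reproduced, only its
  statistical role. The drift amplitude is a free parameter (default
  0.1 Å per saved snapshot per coordinate), not calibrated to any
  particular end-point RMSD.
* **Feature bundles** mirror the 2 + 62×2 + 4 = 130 channel layout. The 2D
  channels are degraded monotone transforms of the true map — information
  bearing, with the first channel exactly the true map at zero noise. The
  degradation blends the channel toward a Gaussian-blurred version of
  itself and adds spatially *smooth* symmetric noise, because real
  pair features (evolutionary couplings, mutual information) are diffuse:
  they locate contact stripes coarsely but carry none of the pixel-level
  texture of a real map. Independent per-pixel noise would be the wrong
  emulation — a regressor can pass such noise straight through and appear
  "sharp" without having learned any texture. The 1D block carries one-hot
  secondary structure plus seeded noise padded to 62 rows (62 is chosen so
  the double broadcast reproduces the published 124). Real extractors have
  structured errors and inter-channel correlations these bundles still do
  not model.
* **Toy alignments** exist solely to exercise the effective-depth
  statistic $N_\mathrm{eff} = \sum_i 1/S_i$, where $S_i$ counts sequences
  at ≥ 75% identity to sequence $i$ (self included — a sequence is always
  100% identical to itself, which also keeps the sum finite). Identity is
  exact column matches over alignment length, gaps counting as mismatches.

Consequently, green tests here certify the machinery — mappings, shapes,
gradients, losses, selection rules, export formats, the direction of the
adversarial effect — not performance on real proteins.

## Desk-scale experiment sizes

The test suite trains on deliberately small problems: 32-residue proteins,
a 12-layer 16-channel generator with 5×5 kernels, a 4-layer patch
discriminator with first width 32, 20 proteins per replicate with 6 held
out, feature degradation 0.5, and five epochs. These sizes are the
package's chosen study conditions for its qualitative claims; anything
larger belongs to the full-scale configs (`generator_config_model_x()`
etc.), which the architecture supports but the tests do not exercise.

The adversarial-versus-control comparison scores sharpness (mean absolute
discrete Laplacian) on the symmetrised generator output in *training
space*. This is deliberate: the label mapping's inverse is steep outside
the 4–16 Å band, so tiny training-space fluctuations over the blank
long-range background inflate an Ångström-space Laplacian and drown the
texture signal the comparison is about. In training space the background
saturates flat near +1 and the Laplacian concentrates on the informative
band. The discriminator's first width of 32 was chosen from
discriminator-only training probes (one is kept as a test): it must
actually separate real from generated maps at this scale, since an
adversarial gradient from a chance-level discriminator tests nothing.

The desk-scale discriminator runs without batch normalisation: with one
protein per minibatch, per-sample normalisation removes exactly the
channel-mean differences between blurred and sharp maps that the
discriminator must detect, and we observed the discriminator failing to
learn with it enabled. The published system trained at far larger scale
where this choice is less consequential; ours is recorded here as a desk-
scale necessity. (switchable via `patch_disc_config(batchnorm = )`).

## Numerical choices and degenerate inputs

* Training-space clamp before `atanh`: $\pm(1 - 10^{-7})$.
* Log clamp in all cross-entropy losses: $10^{-7}$, with clamp counts in
  the training log.
* Constant feature channels: mapped to zeros, warning, never an error.
* Non-Euclidean distance maps (negative leading eigenvalues beyond
  tolerance in the double-centred Gram matrix): flagged, best-effort
  embedding returned.
* Chirality: distances determine a structure only up to reflection. The
  embedder returns both mirror images, ranked by the sign of the mean
  consecutive-quadruple torsion angle against the right-handed helix
  convention of the synthetic backbones. This is a heuristic: for chains
  with little helix content the ranking can be wrong, which is why both
  embeddings are returned.
* Restraint indexing is 1-based in files (folding-engine convention),
  0-based nowhere user-visible; the boundary is documented at the writer
  and parser. Self and near-diagonal pairs (`|i - j| <` 2) are never
  restrained; the 4 Å floor would exclude bonded neighbours anyway.
* The regression target atom: the synthetic system has a single trace atom
  per residue, so the question of which real atom pair (C$\beta$–C$\beta$
  by the contact convention) defines the target arises only for real
  structures, which are out of scope here.

## A worked desk-scale run

```{r quick-run, eval = FALSE}
ds <- simulate_dataset(8, length = 28, seed = 1)
fit <- train_gan(ds[1:6], desk_generator_config(), desk_disc_config(),
                 loss_config(), epochs = 4,
                 lr_schedule = desk_lr_schedule(), seed = 1)
tidy(fit)          # per-epoch raw and smoothed losses
autoplot(fit)      # loss curves

pred <- predict_dmap(fit$generator, ds[[7]]$stack)
evaluate_prediction(pred, ds[[7]]$dmap, coords_true = ds[[7]]$protein$coords)

r <- select_restraints(pred)
write_cns_restraints(r, tempfile(fileext = ".tbl"))
```

## Known limitations

* No real-data ingestion (PDB parsing beyond minimal trace export, MSA
  construction, coupling analysis) — by design.
* The embedder is a validation device, not a folding engine: classical
  multidimensional scaling on a noisy map is far weaker than simulated
  annealing under restraints.
* Training is single-device, double precision, CPU-oriented; the full
  published capacities (Model X/L) are expressible but impractical to
  train here.
* The adversarial-versus-control sharpness comparison is a qualitative,
  stochastic experiment. At the desk sizes above, the adversarial effect
  is directionally consistent — the GAN's output carries more
  high-frequency texture than the control's on most held-out proteins —
  but its *magnitude* is not calibrated per protein: where the control
  happens to be already near the true sharpness, the GAN can overshoot,
  and per-protein "who is closer" comparisons land nearer a coin flip
  than the strong margins seen at full scale. The test suite runs this
  comparison and reports the per-protein detail; treat its win rate as a
  property of these tiny study conditions, not of the architecture.
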