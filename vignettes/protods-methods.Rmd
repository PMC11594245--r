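---
title: "Proto-DS: methods, assumptions and design choices"
author: "ProtoDS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proto-DS: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtoDS)
```

## The problem

Near-infrared (NIR) hyperspectral cameras image a physical sample — a
coffee bean, a dried tangerine peel, a herb slice — as a small cube of
per-pixel reflectance spectra. Classifying such *instances* (authentic vs
adulterated product, storage age classes, species) is routine when classes
are balanced, but real collections are severely skewed: the interesting
class may contribute one to twenty training instances against hundreds of
majority instances. Conventional classifiers trained by plain
cross-entropy then collapse onto the majority class.

ProtoDS implements a two-step training scheme for this regime:

1. **Instance-wise spectral contrastive pretraining** (no labels): learn an
   embedding in which pixel spectra from the same physical instance lie
   close together and pixels from different instances lie apart.
2. **Episodic fine-tuning with a Dice + cross-entropy objective**: turn the
   embedding into a prototypical classifier while counteracting
   majority-class domination through the Dice (soft-F1) loss.

## Preprocessing

Raw sensor counts $I_o$ are min–max calibrated against a dark-current
reference $I_D$ and a white reference $I_W$:

$$I_c = \frac{I_o - I_D}{I_W - I_D}.$$

Calibration demands $I_W - I_D > 0$ elementwise wherever the division is
taken; a violated element is reported with its pixel and band.

A pixel is **effective** when its mean calibrated reflectance over the
retained bands is *strictly* greater than 0.1; this removes background,
occlusion shadows and dead sensor elements. Two choices here were genuinely
open and are fixed as follows:

* the mean is computed **after** band cropping, so the masking decision is
  made on exactly the spectra the classifier will see;
* the threshold comparison is strict (`>`), so a pixel at exactly 0.1 is
  excluded.

Band retention keeps the closed interval [1000, 1600] nm (both endpoints
in), discarding the noisy extremes of the 900–1700 nm sensor range. On a
uniform 256-band grid this leaves $D = 192$ bands, which is the input
dimension of the default network; the dimension always follows the data,
not a constant. Wavelength grids are treated as band centres; no spectral
resampling is performed.

Every effective pixel contributes its own spectrum: an instance is an
$N \times D$ matrix, not an averaged spectrum. This multiplies the
training pool per physical sample by two orders of magnitude, which is
what makes training deep models on tens of instances possible.

## The embedding network

The embedding $f_\phi : \mathbb{R}^D \to \mathbb{R}^M$ is a stack of
(default four) blocks, each **BatchNorm → Linear → LeakyReLU**, hidden
width (and $M$) 256. The batch-norm layer leads each block so the raw
reflectance spectrum is rescaled before the first linear map; the first
linear layer maps $D \to 256$, later ones $256 \to 256$. The leaky-ReLU
negative slope is 0.01 (configurable).

The forward/backward passes and the Adam optimiser
($\beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}$, learning rate
$10^{-4}$) are implemented in base R on BLAS matrix operations. Batch-norm
conventions: biased variance for normalisation, unbiased for the running
estimates, momentum 0.1, $\epsilon = 10^{-5}$. Training mode uses batch
statistics and updates the running estimates; all reported inference uses
running statistics, so the embedding of a spectrum never depends on what
else happens to be in its batch (this is asserted by tests). Gradients for
every layer are verified against central finite differences in the test
suite.

## Prototypes and classification

The prototype of class $k$ is the mean embedding of its support samples:

$$c_k = \frac{1}{|y_k|} \sum_{(x_i, y_i) \in y_k} f_\phi(x_i),$$

and a query $x$ is classified by a softmax over negative distances:

$$p_\phi(y = k \mid x) =
  \frac{\exp(-d(f_\phi(x), c_k))}{\sum_{k'} \exp(-d(f_\phi(x), c_{k'}))}.$$

$d$ is the **squared** Euclidean distance by default — the convention of
the prototypical-network literature, under which the posterior is a proper
Gaussian-mixture responsibility; plain Euclidean distance is available as
a configuration switch. The softmax is max-logit stabilised. Prediction
ties break towards the lowest class id, deterministically.

At test time an instance's pixels are embedded individually and averaged
by a **set-pooling** layer (a plain arithmetic mean — permutation and
sample-size invariant) into a single vector that is classified against the
prototypes. Per-pixel probability maps skip the pooling and paint each
effective pixel's own posterior back onto the image plane, with `NA` at
masked-out pixels.

## Step 1: contrastive pretraining

The pretext task assumes only that pixels of one physical instance share
an illumination and composition context. For a query pixel $x^q_i$, a
positive key $x^+_i$ is a *different* pixel of the same instance and $B$
negative keys are pixels of other instances. The loss per query is the
InfoNCE form

$$\ell_{SSL} = -\log
  \frac{\exp(s(f_\theta(x^q_i), f_\theta(x^+_i))/\tau)}
       {\exp(s(f_\theta(x^q_i), f_\theta(x^+_i))/\tau)
        + \sum_{j=1}^{B} \exp(s(f_\theta(x^q_i), f_\theta(x^-_j))/\tau)},$$

computed log-sum-exp stabilised, with $B = 16$ and $\tau = 1$ by default.
Two points in this formulation were underdetermined and are resolved as
package design choices:

* the score $s$ must be a **similarity** for the loss to pull positives
  together; the default is the negative squared Euclidean distance
  (cosine similarity is a config option). This choice makes the natural
  limits hold: equal positive/negative scores give $\ln(1+B)$, and the
  loss vanishes as the positive coincides with the query while negatives
  recede;
* the denominator **sums over all $B$ negatives** (standard InfoNCE),
  rather than using a single negative term.

Negatives exclude the query's own instance by default, consistent with
the hypothesis that same-instance spectra should embed nearby; a
`negativesIncludeOwnInstance` flag draws them from the whole pool instead.
A `positivePoolSize` option builds the positive key as the mean embedding
of several same-instance pixels rather than a single pixel; single-pixel
keys are the default. One query is drawn per sampled instance per step,
16 instances per optimiser step, and an epoch is one pass over all
training instances as query sources. Instances with a single effective
pixel cannot form a pair and are skipped with a warning. Labels are never
read anywhere in this step — the test suite proves it by permuting the
label column and requiring the bit-identical pretrained network.

## Step 2: fine-tuning with Dice + cross-entropy

Each epoch is an episode: a random subset of every class's instances
(default fraction 0.5, minimum one instance — so a single-instance
minority class is always fully in support) is embedded and averaged into
the epoch's prototypes; then **all** training pixel spectra serve as
queries in shuffled mini-batches (default 256 spectra), each producing
posteriors against the epoch's prototypes and one Adam update of

$$\ell = \lambda_{CE} \cdot \text{CE} + \lambda_D \cdot \ell_{Dice},
\qquad
\ell_{Dice} = \frac{1}{C} \sum_c \left(1 -
  \frac{2\sum_i p_{ic} y_{ic}}{\sum_i p_{ic}^2 + \sum_i y_{ic}^2}\right),$$

with unit weights by default. The second factor is the soft Dice–Sørensen
coefficient; for hard 0/1 predictions it equals the one-vs-rest F1 score
exactly (the suite verifies this identity on a thousand random
configurations), and because true negatives never enter it, the majority
class cannot dominate the objective. With the Dice term switched off the
objective reduces to the classic prototypical loss
$-\log p_\phi(y = k^\ast \mid x)$.

Numerical details, all of which matter in the imbalanced regime:

* the Dice term of a class absent from a mini-batch's truth is constant in
  the predictions, so its gradient is exactly zero; the implementation
  short-circuits it rather than evaluating a $0/\text{denominator}^2$
  expression that can lose meaning when the prediction mass underflows.
  A denominator of exactly zero defines the term as 0;
* Dice is computed per query mini-batch, not per epoch;
* the true-class probability is clamped at $10^{-12}$ before the log;
* prototypes are treated as constants within an epoch (stop-gradient):
  gradients flow through the query embeddings only, and the prototypes
  are refreshed from a fresh support subsample every epoch. This keeps the
  hand-written backward pass tractable; with per-epoch refreshing the
  support embeddings track the network closely, and the arrangement
  mirrors how the final model is deployed (fixed prototypes, moving
  queries);
* batch-norm running statistics continue to update during fine-tuning
  (the alternative — freezing them after pretraining — was considered and
  rejected because evaluation runs in inference mode on statistics that
  should reflect the final embedding distribution).

After fine-tuning, the deployed prototypes are recomputed from **all**
training pixel spectra with the final network in inference mode. The two
flags `useSSL`/`useDice` generate the four ablation variants (full,
w/o Dice, w/o SSL, vanilla prototypical network).

## Evaluation protocol

Metrics are instance-level (after set pooling): balanced accuracy (mean
per-class recall; invariant to prevalence, equal to
(sensitivity+specificity)/2 in binary tasks), macro F1, macro one-vs-rest
AUROC (midrank convention for ties, matched to an all-pairs oracle in the
tests) and macro average precision (step-wise interpolation), plus
per-class sensitivity and specificity — reported one-vs-rest per class,
with no invented scalar summary for the multiclass case.

The imbalance protocol first fixes a class-stratified test set (training
side floored), identically across all minority sizes at a given seed; the
remaining training pool is then thinned: the majority class is kept whole,
the least-represented minority class is reduced to $n$ instances, and
intermediate minority classes are scaled as
$\mathrm{round}_{\text{half-up}}(n \cdot m_k / m_{least})$ from the
full-dataset class counts $m_k$. Half-up rounding is a package choice (the
convention was unstated); the harness also logs raw counts so any
imbalance-rate definition can be recomputed from them. The ablation runner
retrains every variant from scratch per grid cell and records failures
without aborting the grid.

The separability diagnostic projects embeddings onto their first two
principal components, fits one 2-D Gaussian per class, takes each class's
region to be its 95% confidence ellipse (the contour level is a package
choice) and reports pairwise Intersection-over-Union computed on a
discretised grid — robust where analytic ellipse–ellipse intersection is
fragile; the tests require the grid estimate to be stable under grid
refinement. Singular covariances are ridge-regularised with a warning.

## The synthetic-data generator

Real instance collections of this kind are rarely redistributable, so the
generator is a first-class module emulating the statistical structure the
method relies on:

* **class signatures**: smooth curves (baseline + Gaussian bumps) on the
  900–1700 nm grid, constrained inside (0.1, 1.0) so foreground pixels
  pass the effective-pixel rule, with a minimum pairwise separation
  $\delta$ (RMS reflectance difference per band), enforced by bounded
  resampling;
* **instance-level illumination**: a multiplicative log-normal factor
  shared by all pixels of an instance — multiplicative rather than
  additive so that dimmer pixels keep their spectral shape, which is
  precisely the structure the contrastive pretext task exploits;
* **pixel-level variation**: per-pixel log-normal scale jitter and i.i.d.
  additive Gaussian band noise, clipped to [0, 1.2] (the ceiling exceeds
  1 because min–max calibrated reflectance can);
* **shadow pixels**: a configurable fraction rescaled to a mean
  reflectance in (0.02, 0.07), guaranteed to fail the strict 0.1 rule;
* **raw mode**: optional raw/dark/white triplets built by inverting the
  calibration equation, so the full preprocessing chain can be exercised
  end to end.

Everything is deterministic under the configuration seed, byte for byte.
The generator intentionally does **not** model spatial texture,
band-correlated instrument noise, scattering physics or wavelength
miscalibration; conclusions drawn from passing tests are therefore about
the learning machinery under the stated statistical assumptions, not
about any particular instrument or commodity.

## Study sizes used by the checks

The seeded experiment baked into the tests and the acceptance script uses
sizes chosen to exercise the imbalanced regime while staying desk-scale:
binary classification, 100 majority / 5 minority training instances,
30 + 30 test instances, 6×6-pixel instances, signature separation
$\delta = 0.15$, additive noise s.d. 0.02, illumination jitter s.d. 0.10,
shadow fraction 0.10, 60 pretraining epochs and 30 fine-tuning epochs,
five seeds. The structure-recovery check pretrains on 40 unlabeled
instances for 50 epochs and measures same- vs cross-instance embedding
distances on 16 held-out instances. The full-data defaults
(`sslConfig(epochs = 200)`, `finetuneConfig(epochs = 50)`) remain the
recommended settings for real cubes.

## Known limitations

* The stop-gradient treatment of episodic prototypes is an approximation
  to fully differentiated episodic training; at the scales tested it
  converges reliably, but very deep stacks or very low support fractions
  may behave differently.
* SMOTE-style oversampling hybrids and class-reweighted baselines are out
  of scope; the evaluation harness accepts any classifier that yields
  labels and scores, so such methods can be compared externally.
* No spatial information is used: the model is purely spectral by design,
  and will not exploit texture differences where they exist.
* Training is CPU-bound base R; it is comfortable at hundreds of
  instances × dozens of pixels, not at megapixel ROI scales.
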