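# ProtoDS

Prototypical-network classification of near-infrared hyperspectral
instances under severe class imbalance, trained in two steps:
instance-wise spectral contrastive pretraining followed by episodic
fine-tuning with a combined Dice + cross-entropy objective ("Proto-DS").

## Who this is for

Labs using NIR hyperspectral cameras to sort physical samples — detecting
adulterated foodstuffs, grading storage age, separating look-alike
species — where the interesting class has only a handful of labelled
instances against hundreds of majority instances. Conventional
cross-entropy training collapses onto the majority class in this regime;
ProtoDS is built for it.

## The method in brief

Each physical instance is a small reflectance cube. After dark/white
calibration `I_c = (I_o − I_D)/(I_W − I_D)`, effective-pixel masking
(mean retained-band reflectance > 0.1) and band cropping to
[1000, 1600] nm, every effective pixel contributes its own spectrum
`x ∈ R^D`.

An embedding network `f_φ : R^D → R^M` (stacked BatchNorm → Linear →
LeakyReLU blocks, width 256) is trained in two steps:

1. **Contrastive pretraining** (no labels): pixels of the same instance
   are positives, pixels of other instances negatives, scored by an
   InfoNCE loss with `B = 16` negatives and temperature `τ = 1`.
2. **Episodic fine-tuning**: per epoch, class prototypes
   `c_k = mean of support embeddings` are extracted from a random support
   subsample; all training pixels are queries classified by
   `p(y = k | x) ∝ exp(−‖f_φ(x) − c_k‖²)` and optimised with
   `CE + Dice`, where the Dice term `1 − 2Σp·y/(Σp² + Σy²)` per class is
   a soft F1 complement that ignores true negatives and therefore cannot
   be dominated by the majority class.

At test time all pixel embeddings of an instance are averaged (set
pooling) and classified against the prototypes. Evaluation reports
balanced accuracy, macro F1 / AUROC / AP and per-class
sensitivity/specificity, with a ratio-scaled minority-downsampling
protocol for imbalance sweeps, an ablation runner (full / w/o Dice /
w/o SSL / vanilla prototypical network) and a PCA + Gaussian-ellipse IOU
separability diagnostic.

A seeded synthetic-cube generator (class signatures from Gaussian bumps,
instance-level log-normal illumination, pixel noise, shadow pixels,
configurable imbalance) makes the whole pipeline testable without any
proprietary data. See the methods vignette
(`vignettes/protods-methods.Rmd`) for assumptions and design choices.

## Worked example

```r
library(ProtoDS)

# an imbalanced synthetic dataset: 100 majority / 5 minority training
# instances, 30 + 30 test instances, 6x6-pixel cubes, 256 bands
model <- signatureModel(2, nBands = 256, delta = 0.15)
cfg <- simConfig(seed = 1001, majorityTrain = 100, minorityTrain = 5,
                 testPerClass = 30, pixels = c(6, 6), noiseSd = 0.02,
                 shadowFraction = 0.10)
ds <- simulateDataset(model, cfg)
train <- splitToInstances(ds$train)   # band-cropped, masked pixel spectra
test <- splitToInstances(ds$test)

ncol(spectra(train[[1]]))
#> [1] 192

full <- trainProtoDS(train, sslCfg = sslConfig(epochs = 60),
                     ftCfg = finetuneConfig(epochs = 30), seed = 1)
evaluateModel(full, test)
#> EvalReport (2 classes, 60 instances)
#>   B.Acc 1.0000 | M.F1 1.0000 | M.AUROC 1.0000 | M.AP 1.0000
```

The pretraining loss trace (`full@trainingInfo$sslLossTrace`) drops from
about 63 in the first epoch to about 22 in the last on this data — the
embedding has learned to tell instances apart before ever seeing a label.
Balanced accuracy 1.0 means both the majority class and the 5-instance
minority class are recovered perfectly on the held-out instances; under
harder noise or smaller separation the minority sensitivity column of
`perClassMetrics()` is the number to watch.

Variants for ablation come from two flags:

```r
vanilla <- trainProtoDS(train, ftCfg = finetuneConfig(epochs = 30),
                        useSSL = FALSE, useDice = FALSE, seed = 1)
```

A thin CLI over the same functions lives at `inst/exec/protods`
(`simulate`, `preprocess`, `train`, `predict`, `evaluate`, `probmap`).

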