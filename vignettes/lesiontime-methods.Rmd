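---
title: "Methods: longitudinal multi-lesion CT prognosis with two-level attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal multi-lesion CT prognosis with two-level attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patients with metastatic cancer carry several lesions that are imaged
repeatedly during therapy. Response criteria such as RECIST v1.1 compress
this longitudinal, multi-lesion information into a single diameter-sum
change between two scans. `lesiontime` implements a richer alternative: a
two-level attention model that fuses every lesion's whole imaging time
series, then the set of lesions, into one patient-level probability of poor
overall survival (OS < 12 months), alongside the classical comparators
(RECIST, tumour-burden change), a Cox-regression nomogram that fuses all
channels, and the survival-evaluation toolkit needed to compare them.

Because the package cannot ship clinical data, it includes a first-class
phantom-cohort simulator with a known per-patient latent risk, so every
stage of the pipeline can be exercised and validated against ground truth.

## ROI preprocessing

Each annotated lesion at each timepoint becomes a 3-channel patch:

1. the bounding box is expanded 1.5-fold about its centre (clipped at the
   image edge);
2. the rectangular ROI is padded symmetrically to its minimum circumscribed
   square (the extra pixel of an odd pad goes to the trailing side; the pad
   value is the window minimum, which renders as dark background) and
   resampled bilinearly to the configured side (224 px by convention,
   64 px at desk scale);
3. HU values are windowed: lung lesions with level -400 / width 1500,
   all other sites with level 50 / width 350, mapping the window linearly
   onto [0, 1] with clipping;
4. the same operations applied to the slices directly above and below the
   annotated slice give the three channels; at a volume boundary the
   central slice is replicated.

Windowing precedes resampling in this implementation; both operations are
monotone and the composition differs from the reverse order only through
interpolation at clipped values. Training-time augmentation rotates the
three channels jointly by an angle drawn uniformly from [-30, 30] degrees
(bilinear, out-of-frame pixels filled with the patch minimum); it is
refused in validation mode. The boxes are drawn once at baseline and keep
their size across timepoints, which preserves scale information: growth and
shrinkage are visible as the lesion filling more or less of its fixed crop.

## The two-level attention model

Per-patch features come from a small strided convolutional network in the
miniature ResNet-18 spirit (four 3x3 stages, channels 3-8-16-32-d, global
average pooling). Its weights are drawn once from a seeded He
initialisation and frozen: training updates everything downstream (the
linear projection, both attention levels, the aggregation token, the
temporal position embedding and the MLP head) but not the convolutions.
This transfer-style split keeps desk-scale CPU training tractable while
retaining what matters in the phantom: lesion size, contrast and their
change over time. Feature vectors are z-scored per dimension with
statistics computed on the training cohort and frozen into the checkpoint.

The temporal stage runs pre-norm multi-head self-attention (default 2
layers, 4 heads, model width 64, all configurable) over each object's
timepoint sequence, after adding a learned temporal position embedding;
the valid timepoints are then mean-pooled. The object stage prepends a
learnable aggregation token to the set of object vectors and runs the same
encoder without positional information; the patient vector is read at the
aggregation position, so the output is invariant to lesion order and to
padding. A two-layer perceptron with softmax yields the risk: the
probability of the poor-OS class. The convention is fixed as
risk = P(OS < 12 months); risks above the frozen cutoff define the
high-risk group.

Masking is implemented with additive negative-infinity logits, so masked
keys receive exactly zero attention weight (testable as an identity, not a
tolerance). Missing follow-ups, missing markers and padded lesions all use
the same mechanism; a patient scored at a horizon whose scans are partly
missing gets bit-identically the score of the shorter horizon. The same
skeleton instantiated on tumour-marker series (one object per marker
channel, scalar values embedded with a channel indicator) gives the
marker-based model; markers are z-scored per channel with training-cohort
statistics.

All forward and backward passes are hand-implemented in vectorised R and
verified against central finite differences in the test suite.

## Losses and training

Patients who died before 12 months are `poor`, patients observed beyond 12
months are `good`, and patients censored before 12 months have no binary
class: they are excluded from the cross-entropy term but retained in the
ranking term, where their ordering information is still valid. The ranking
term is the negative Cox partial log-likelihood (Breslow ties, averaged
over events) of the logit-scale risk score over the mini-batch — the
canonical loss that orders all samples by risk. The total is the unweighted
sum of both terms; either can be disabled for ablation. Training uses Adam
(default learning rate 3e-3, batch 32, 10 epochs at desk scale, up to four
follow-ups), with Polyak-Ruppert averaging of the weights over the last
40% of steps, which removes much of the stochastic-gradient endpoint noise
at no extra cost. Runs are deterministic given the seed; a non-finite loss
aborts with diagnostics.

## RECIST and tumour-burden comparators

Because the boxes are size-constant by design, response is measured on the
image: within 2.5-fold the box, after two passes of a 3x3 mean filter, the
background level is taken from the crop border, the foreground from the
strongest central deviation, and the lesion extent from the subpixel
half-contrast crossings along the central profiles (a 10 HU conspicuity
floor declares unmeasurably faint lesions vanished). On phantoms this
tracks the true diameters with r above 0.95. RECIST v1.1 then classifies
the change in the target-lesion diameter sum between baseline and the
second follow-up — or the first, when only one exists — as CR / PR / SD /
PD (PR at -30%, PD at +20% and at least +5 mm absolute or a new lesion,
which is an input flag, not detected). The tumour-burden change is the
percent change of the summed target-lesion areas between the same scans.
Target lesions are the baseline lesions with longest diameter above 10 mm
(at most five, largest first, ties by lesion id), plus the primary, which
is always kept.

## Nomogram fusion and calibration

A Cox proportional-hazards fit on the training cohort combines the imaging
score, optionally the marker score (the without-marker variant is a refit,
not an imputation, mirroring cohorts that lack marker data), the RECIST
category (an ordered factor with treatment dummies) and clinical covariates
(sex, HER2 status). The one-year survival of a patient is
`S0(12) ^ exp(lp - mean training lp)` with the Breslow baseline; nomogram
points rescale each covariate's coefficient-times-value contribution so
that the widest span is worth 100 points, making points and linear
predictor affinely interchangeable. Calibration groups patients into
deciles of predicted one-year survival and compares Kaplan-Meier-observed
with predicted survival per bin; the Hosmer-Lemeshow statistic is referred
to chi-square with g - 2 degrees of freedom. That reference distribution
assumes the probabilities come from a fitted model, so the package's
null-calibration tests simulate a fitted logistic model rather than
plugging in true probabilities (with true external probabilities the
statistic is approximately chi-square with g degrees of freedom instead).

## Survival evaluation

Harrell's concordance (ties one half, the usual comparability rules,
computed via the survival package and checked against brute-force pair
enumeration), a one-year AUC defined as the binary AUC for death before 12
months with patients censored before 12 months excluded (the
censoring-weighted time-dependent variant is deliberately out of scope;
exclusion matches the model's own label definition), the Youden cutoff
chosen on the training cohort by scanning every midpoint between adjacent
distinct scores (ties towards the lower threshold) and then frozen for all
validation cohorts, Kaplan-Meier curves, the log-rank test, and the hazard
ratio of high versus low risk from a univariate Cox fit. Confidence
intervals are seeded percentile bootstraps with 2000 replicates by default.

## Explanations

Attention read-outs summarise the last layer of each level: per-timepoint
importance (attention received by each timepoint, averaged over heads,
lesions and valid queries, renormalised per group) and a site-by-site
matrix of inter-lesion attention with rows renormalised over the lesion
tokens — so a single-lesion patient contributes a 1x1 entry of exactly 1.
Head aggregation is by mean. Grad-CAM weights the final convolutional
feature maps by the gradient of the chosen class logit (the gradient path
runs through both attention levels), rectifies, upsamples to the patch and
max-normalises; an identically zero map is returned flagged rather than
rescaled. Extraction is a pure read-out: the risks it reports are
bit-identical to prediction.

## The phantom cohort

The simulator generates what the pipeline needs and nothing more: one
stomach primary plus one to five target lesions per patient (sites drawn
as lymph node 55%, liver 40%, lung 5%), baseline longest diameters
log-uniform on 12-40 mm and always above 10 mm, up to five scans with
monotone dropout (a missed visit ends the series, probability 0.2 per
visit), and three tumour-marker channels measured at the visits with 10%
extra missingness. A latent risk z ~ N(0, 1) drives everything: survival
is Weibull (shape 1.3, scale 14 months) with proportional-hazards
log-hazard `1.0 * z`, so the median OS sits near one year; censoring is
exponential with its rate calibrated against the drawn survival times to
hit the requested marginal fraction (default 25%); lesion diameters follow
a log-scale random walk with drift `-0.04 + 0.18 z` per visit (treatment
shrinks the average lesion; high risk grows), per-step noise 0.06, a weak
baseline-size tilt (0.08 z) and Gompertz-like saturation of growth near
75 mm; markers are a monotone noisy transform of z drifting over time.

Lesions render as soft-edged ellipses with site-appropriate HU: air
background near -800 HU for lung, perinodal fat near -90 HU for lymph
nodes, bright parenchyma (70 HU) with hypodense metastases for liver, and
fluid-like background for the stomach primary, all under 12 HU of noise,
at 2.5 mm/pixel in 64-pixel slices, with integer-rounded HU so NIfTI
round-trips are exact. Blob pixel count scales with the squared diameter.

What the phantom does not emulate: real CT texture, respiratory motion,
registration error, contrast-phase differences, inter-reader box
variability, non-proportional hazards, and informative censoring. Passing
tests on phantoms therefore demonstrates that the machinery is correct and
that the method recovers a known signal under realistic noise — not
clinical performance.

## Desk-scale study sizes and numerical choices

The parameter-recovery study uses 300 training and 100 held-out phantoms,
64-pixel patches, model width 64 and 10 epochs — sizes chosen so the whole
suite runs comfortably on a single CPU. Under these conditions the
two-follow-up model concordance with the held-out latent risk is about
0.67-0.71 across seeds versus about 0.51-0.54 for the baseline-only model,
reproducing the qualitative benefit of follow-up imaging. Other choices
made where the design was genuinely open: bilinear interpolation
everywhere; risk scored on the logit margin inside the ranking loss
(unbounded scale, monotone in the probability); duplicate lesions are
scored but flagged; the fusion-beats-single-channel property is tested
with two synthetic noisy readouts of the latent risk, because the phantom
has one latent factor and the property concerns the Cox fusion machinery,
not the trainer; rotation augmentation is off by default in the desk-scale
trainer because features are cached once per cohort (a flag enables it).

## Known limitations

The frozen extractor cannot learn texture features; only what random
convolutions preserve reaches the attention stages. Pure-R training is
practical at desk scale only. The one-year AUC ignores censoring beyond
exclusion. RECIST here implements diameter-sum change only (no nodal
short-axis rules, non-target lesions or confirmation scans). Arterial and
venous phases are treated as separate objects when both exist; the
generator emits venous only, and liver lesions are restricted to the
venous phase at load time.
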