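---
title: "Attention-based multiple instance learning for treatment-response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based multiple instance learning for treatment-response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milpath)
```

## The problem

In triple-negative breast cancer, pathologic complete response (pCR) to
neoadjuvant chemotherapy is a strong surrogate for survival, but no reliable
pre-treatment biomarker exists. A pre-treatment H&E biopsy slide carries a
single outcome label, while the information lives in thousands of small
tissue regions — a classic weakly supervised setting. `milpath` implements
the standard answer to it: attention-based multiple instance learning (MIL),
where a slide is a *bag* of patch-level feature vectors and the model learns
both which patches matter and how the slide classifies.

## Model

Each slide is partitioned into non-overlapping square patches (512 px at
40x, 0.25 µm/px, in the intended clinical setting). Each patch $i$ is
encoded to a feature vector $h_i \in \mathbb{R}^d$ by a pluggable encoder;
in production that is a pathology foundation model with $d = 1536$, and in
this package's tests a deterministic linear stub. The bag is aggregated by
tanh attention:

$$\alpha_k = \frac{\exp\{w^\top \tanh(V h_k)\}}{\sum_j \exp\{w^\top \tanh(V h_j)\}},
\qquad z = \sum_k \alpha_k h_k,$$

with learnable $V \in \mathbb{R}^{L \times d}$ and $w \in \mathbb{R}^L$
(non-gated form; no gating branch). A linear layer plus sigmoid maps $z$ to
$p = \Pr(\text{pCR})$. The softmax is computed with max-subtraction, so
$\sum_k \alpha_k = 1$ to machine precision for any parameters.

Cohorts are imbalanced, so training minimises a class-weighted binary
cross-entropy with inverse-frequency weights
$w_{\text{pCR}} = N / (2 N_{\text{pCR}})$ and
$w_{\text{non-pCR}} = N / (2 N_{\text{non-pCR}})$; their count-weighted mean
is exactly 1, so the loss scale is unchanged while minority errors cost
more. Weights are computed on each training split, never on the full
cohort, to avoid leaking test composition into the loss.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `learning_rate` | 1e-4 | SGD step size |
| `weight_decay` | 1e-3 | L2 penalty on $V$, $w$ and head weights |
| `momentum` | 0.9 | SGD momentum (conventional; head bias excluded from decay) |
| `batch_size` | 1 bag | one optimisation step per slide |
| `max_epochs` | 1024 | upper bound on epochs |
| `patience` | 50 | early-stopping epochs without validation improvement |
| `L` | 256 | attention hidden size |
| `patch_size` | 512 px | tile side length |
| `tissue_fraction_min` | 0.10 | minimum tissue per kept tile |

The training protocol constants (learning rate, weight decay, patience,
epochs, batch size) follow the fixed protocol of the intended study design;
`L`, `momentum` and the single-linear-layer head are this package's own
choices where the protocol leaves them open — a deeper head or gated
attention would add capacity the synthetic benchmark does not need.
Gradients of the full model are derived analytically and checked against
central finite differences in the test suite.

Because the model is small, the optimiser and backward pass are written
directly in R; a run is a pure function of the bags and the seed, which is
what makes the byte-identical reproducibility contract testable.

## Evaluation protocol

Patients (not slides) are split into $k = 5$ stratified folds: within each
class, patients are shuffled under the seed and dealt round-robin, with the
fold cursor carried across classes so per-fold class counts and fold sizes
both stay within one of exact proportionality. In fold $f$, fold $f$ is the
test set, fold $f{+}1 \pmod k$ the validation set (used only for early
stopping), and the rest train. The fold rotation for validation is a design
choice; the protocol only requires that all three splits exist per fold.

Metrics are the standard six — accuracy, AUC, F1, sensitivity, specificity,
precision — with AUC computed as the Mann–Whitney concordance (ties 0.5)
from midranks, which equals the $O(n^2)$ pairwise definition exactly (both
routes are tested against each other, plus pROC as an external check).
Decision threshold is 0.5 with ties counted positive; a metric with a zero
denominator is reported as `NaN` with a warning, never silently 0. Fold
aggregation reports the arithmetic mean and the sample (n−1) standard
deviation.

## Attention maps and biomarker overlap

Per-patch attention is rasterised onto the tile grid (`assemble_heatmap`),
optionally min-max normalised for display (a constant map renders 0.5 by
convention). Hotspot filtering offers the median rule (cells at or above
the median attention; always at least half the tissue cells) and top-$q$%
selection by count, `ceiling(q * n)`, with ties broken by (row, column)
ascending so masks are deterministic and nest: top 1% ⊆ top 5% ⊆ top 10%.
The binarised attention map used for biomarker overlap is the median mask
upsampled to pixel resolution (each tile paints its full pixel block); the
median rule is the default because it is the map paired with binarisation
in the intended workflow, with top-$q$% binarisation available via the
`level` argument.

The overlap statistic divides the intersection of the binarised attention
map with a biomarker mask by the *biomarker mask's own area* — a coverage
(recall-style) score, not the symmetric Jaccard index. The implementation
follows that printed definition and reports the Jaccard value in a clearly
separate column, since the two answer different questions. Pixel area is
the denominator; a per-connected-component (cell-count) variant was
considered and left out as under-specified. Masks are consumed pre-aligned;
`align_mask` offers nearest-neighbour resampling and an optional affine
transform as a convenience, not a registration method.

## The synthetic benchmark

`gen_bags()` generates the study conditions every stage is tested under:
100 bags of 50–200 patches, $d = 16$, background patches
$\mathcal{N}(0, 1)$ i.i.d. per feature, and in positive bags a fraction
$\rho = 0.2$ of patches shifted by $\mu = 3$ standard deviations along the
first coordinate. Labels are Bernoulli(0.5). One patient per slide. The
Gaussian planted-signal model is the simplest distribution under which
attention-MIL is provably learnable, and it carries ground-truth patch
flags so attention recovery (mean $\alpha$ on signal patches exceeding
background) can be measured directly; with $\mu = 0$ no patches are flagged
and the two classes are identically distributed, giving the null case.
`gen_slide_image()` renders toy slides (pink textured tissue on white) for
the tiling path, and `gen_biomarker_masks()` produces marker masks covering
signal tiles with a controllable concordance, so the full
attention-to-biomarker overlap chain is testable end to end.

What passing these tests shows — and does not show: the mathematics,
optimisation and bookkeeping of the method are correct, and the model
recovers planted signal under a large, well-separated effect. Synthetic
bags do not emulate H&E texture statistics, foundation-model embedding
geometry, stain variation, or patient-level correlation between slides;
performance on the synthetic benchmark says nothing quantitative about
clinical cohorts.

## Numerical choices and problem sizes

Probabilities are clamped at $\varepsilon = 10^{-7}$ inside the loss;
softmax uses max-subtraction; both are invisible at the package's 1e-6
tolerances. All randomness (initialisation, shuffling, augmentation draws,
simulation) flows through explicit seeds via a save/restore RNG wrapper, so
no call disturbs the caller's RNG state. The test suite runs the full
study conditions (100 bags, default protocol) once for the recovery checks
and uses reduced sizes elsewhere (40 bags, shorter schedules, smaller $L$)
— determinism and correctness properties are scale-free, so small fixtures
test them as well as large ones. Feature containers and checkpoints are
keyed R serialisation files; features round-trip bit-exactly.

## Known limitations

- The encoder stub is a linear projection: good for contracts and
  determinism, useless as a feature extractor for real tissue.
- Augmentation operates on images; when training from precomputed
  features, augmentation cannot apply (the pipeline trains from features).
- Single-label binary classification only; no multi-class head, no gated
  attention, no GPU path.
- Patient-level stratification assumes one label per patient; a patient
  with discordant slide labels is reduced to the maximum label.
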