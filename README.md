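# milpath

Attention-based multiple instance learning (MIL) for predicting pathologic
complete response (pCR) to neoadjuvant chemotherapy from pre-treatment
H&E-stained biopsy slides.

A biopsy slide carries one outcome label but thousands of informative tissue
regions, so the problem is weakly supervised: the slide is a **bag** of
patch feature vectors $h_1, \dots, h_N \in \mathbb{R}^d$, aggregated by
learned tanh attention

$$\alpha_k = \frac{\exp\{w^\top \tanh(V h_k)\}}{\sum_j \exp\{w^\top \tanh(V h_j)\}},
\qquad z = \sum_k \alpha_k h_k,$$

and classified by a sigmoid head, $p = \sigma(u^\top z + b)$. Training
minimises a class-weighted binary cross-entropy (inverse-frequency weights
$w_{\text{pCR}} = N/2N_{\text{pCR}}$, $w_{\text{non-pCR}} = N/2N_{\text{non-pCR}}$)
by SGD, one bag per step, with early stopping on validation loss.
Evaluation is patient-level stratified 5-fold cross-validation reporting
accuracy, AUC, F1, sensitivity, specificity and precision. The attention
weights double as an interpretability signal: rasterised to heatmaps,
filtered to median / top-10/5/1% hotspot masks, binarised to pixel
resolution, and scored against binary immune-biomarker masks (PD-L1, CD8+,
CD163+) with a coverage-style overlap statistic
$|A \cap B| / |B|$ (the Jaccard index is reported alongside).

The package covers the full chain — slide tiling with saturation/Otsu
tissue detection, patch augmentation, a pluggable encoder contract with a
deterministic stub, the MIL model with hand-derived analytic gradients,
evaluation, heatmap post-processing, biomarker overlap, and a synthetic
planted-signal cohort generator so everything is testable without slide
data. See `vignettes/attention-mil.Rmd` for the methods account.

## Worked example

Generate a synthetic cohort (100 bags of 50–200 patches, d = 16; positive
bags carry 20% of patches mean-shifted by 3 SD), train, and evaluate on
held-out bags:

```r
library(milpath)

cohort <- gen_bags(sim_config(seed = 11))
model  <- train_mil(cohort$bags[1:60], cohort$bags[61:80],
                    train_config(seed = 7))

y <- cohort$labels$label
p <- vapply(cohort$bags[81:100], function(b) predict(model, b)$p, numeric(1))
auc_roc(y[81:100], p)
#> [1] 1

res <- predict(model, cohort$bags[[1]])
res
#> <attention_result> S001: N = 83 patches, p(pCR) = 0.9908, max alpha = 0.3472
```

Attention concentrates on the planted signal patches (mean α 0.052 on
signal vs 0.0017 on background for this slide). Rasterise it, binarise by
the median rule, and score coverage of biomarker masks generated at 0.9
concordance with the signal:

```r
hm    <- assemble_heatmap(res, cohort$bags[[1]]$refs)
masks <- gen_biomarker_masks(cohort$signal_flags[[1]], cohort$bags[[1]]$refs,
                             concordance = 0.9, seed = 3)
cohort_iou_report(score_slide_overlap(binarize_attention(hm), masks, "S001"))
#> <iou_report> per-marker coverage of biomarker masks by attention:
#>  marker      mean sd n
#>   PD-L1 0.9500000 NA 1
#>     CD8 0.7142857 NA 1
#>   CD163 0.8000000 NA 1
#> overall mean: 0.821
```

The coverage score is the fraction of each biomarker's area that falls
inside the attended region, so 0.95 for PD-L1 means 95% of the PD-L1 mask
lies under the binarised attention map.

A full pipeline (simulate → train → evaluate → heatmap → overlap) runs from
one config and one seed, writing CSV/JSON/PNG artifacts and a run manifest:

```r
run_pipeline(c("simulate", "train", "evaluate"), load_config("cfg.yaml"), "out/")
```

or from a shell via the thin wrapper `inst/cli/milpath.R`.

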