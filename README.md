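# twintower

Twin-tower multimodal fusion of brain MRI and gene expression for
predicting glioma patients' response to therapy.

## The problem

Radiogenomic cohorts are dominated by single-modality samples: of the
TCGA-derived glioma data this package targets, 95 samples carry MRI
only, 452 carry RNA-seq only, and just 50 carry both. Training a joint
model only on paired samples wastes ~90% of the cohort. The twin-tower
architecture solves this *unimodal dominance* problem in two stages:

1. **Stage 1 — modality towers.** An image encoder (low-complexity CNN:
   three conv/pool/ReLU blocks with 8/16/32 filters, dense 32 → 16) is
   trained on image-only samples; a gene encoder (dense autoencoder
   64 → 32 → 64, MSE reconstruction, plus a supervised 64/16/sigmoid
   head on the bottleneck) is trained on gene-only samples.
2. **Stage 2 — frozen transfer.** Both towers are frozen. The 16 image
   features and 32 bottleneck gene features of each dual-modality
   sample are standardized per modality (Gaussian normalization, fitted
   on stage-2 training features only), concatenated (width 48), and a
   fusion MLP (64/128/16, sigmoid output) is trained on the scarce
   paired subset. A mixture-of-experts fusion layer is available as an
   alternative (`fusion_config(mode = "moe")`).

Evaluation uses the standard confusion-matrix metrics

    accuracy = (TP + TN) / (TP + FP + FN + TN)
    precision = TP / (TP + FP)
    recall = TP / (TP + FN)
    F1 = 2 * precision * recall / (precision + recall)

plus ROC/AUC (threshold sweep with tie grouping, trapezoidal
integration), with stratified 3-fold cross-validation of the stage-2
transfer.

The package also ships the full ingestion path for real data — NIfTI
volume sets with maximum-tumor-slice extraction, transcript→gene
collapsing via a GTF annotation with the keep-first duplicate rule,
clinical label binarization, seeded stratified splits — and a synthetic
radiogenomic cohort generator that reproduces the 95/452/50 modality
structure with exactly controllable image-side and gene-side label
signal, so every stage is testable without any download.

All networks and optimizers (SGD with momentum, Adam, backprop through
conv/pool/dense layers) are implemented in base R on BLAS matrix
products; runs are bit-reproducible from a seed.

## Worked example

```r
library(twintower)

# a synthetic cohort with the study's modality structure, at desk scale
chrt <- generate_cohort(synth_config(seed = 1))
chrt
#> Multimodal cohort: 597 samples
#>   image-only: 95, gene-only: 452, dual-modality: 50
#>   label prevalence: 0.477
#>   stage1_gene_test  stage1_gene_train  stage1_image_test stage1_image_train
#>                 90                362                 19                 76
#>        stage2_test       stage2_train
#>                 20                 30

fit <- twin_tower(chrt, synth_train_config(seed = 1))
evaluate_model(fit, chrt, "stage2_test")
#> Binary classification metrics (n = 20)
#>  accuracy precision    recall        f1       auc
#>     0.700     0.750     0.600     0.667     0.870

# ablation: the frozen towers' own stage-1 classifiers on the same set
evaluate_tower(fit$image_tower, chrt, "stage2_test")$accuracy  #> 0.65
evaluate_tower(fit$gene_tower, chrt, "stage2_test")$accuracy   #> 0.65
```

On this seed the fused model (accuracy 0.70, AUC 0.87) beats both
unimodal ablations (0.65 each) because the generator gives each
modality half of the label signal. With only 20 held-out dual-modality
samples the per-seed margin is noisy (see the methods vignette for the
distribution across seeds); the qualitative gain is the architectural
claim the package tests, not a reproduction of any real-data figure.

Real data enter through the same types:

```r
vol <- load_volume_set(c(T1 = "t1.nii.gz", T2 = "t2.nii.gz",
                         T1ce = "t1ce.nii.gz", FLAIR = "flair.nii.gz",
                         SEG = "seg.nii.gz"))
slice <- extract_max_tumor_slice(vol)   # 5 x 240 x 240, normalized
gm <- build_gene_matrix(list(S1 = "S1.quant.tsv"), "annotation.gtf")
labels <- read_clinical_labels("clinical.csv",
                               positive_categories = c("Complete Response",
                                                       "Partial Response"))
```

A thin command-line front end is available at `exec/twintower`
(`simulate`, `train`, `cross-validate`, `evaluate`).

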