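# dermwolf

Gray wolf optimization for dermoscopic melanoma analysis: an improved gray
wolf optimizer (IGWO) with fitness-based omega regeneration, classical
dermoscopy preprocessing (Gaussian denoising, DullRazor hair removal,
lookup-table contrast stretching), Kapur-entropy multilevel thresholding
with the optimizer in the loop, and a compact class-weighted CNN with
patient-grouped splits and IGWO-driven hyperparameter search — all
testable end to end on a seeded synthetic dermoscopy generator, with no
external downloads.

Intended users: researchers in biomedical image analysis who want a
self-contained, reproducible R implementation of this metaheuristic +
segmentation + classification stack, either to study the optimizer
variant itself or to run the pipeline on their own PNG dermoscopy data.

## The method in brief

**IGWO.** Canonical GWO pulls each agent `x` toward the three best
solutions (alpha, beta, delta): `D_e = |C e − x|`, `X_e = e − A D_e`,
`x ← (X_α + X_β + X_δ)/3`, with `A = 2 a r₁ − a`, `C = 2 r₂` and
`a = 2(1 − t/T)` decaying linearly. The improved variant ranks agents by
fitness every iteration and regenerates the worst `⌊rN⌋` (default 30%):
with probability `p = 0.7` an eliminated agent becomes a copy of an elite
(rank-weighted 3:2:1), otherwise a Gaussian probe
`x_α + σ·g, σ = 1/(t+1)` around the leader. Per-agent greedy memory keeps
only improving moves.

**Segmentation.** Thresholds `TH = [th₁ … th_{m−1}]` maximize the Kapur
objective `J = Σ_j H_j`, where `H_j` is the Shannon entropy of the
within-class intensity distribution; the optimizer searches integer
thresholds in 1..254 (25 repeats, averaged), and the mask is cleaned by
fill–open–close (3×3 element) plus largest-component selection.

**Classification.** Three {3×3 conv, ReLU, 2×2 max-pool} blocks →
dense 128 → dropout → softmax-2, trained with class-weighted
cross-entropy (`w_c = n/(2 n_c)`) under RMSprop
(lr 0.001 paper / 0.005 desk, ρ = 0.9, ε = 1e−7), batch 32, early
stopping on validation loss (patience 10). The search space for the
hyperparameter search is `(f₁, f₂, f₃) ∈ [16, 256]³` (integers) and
dropout `d ∈ [0.2, 0.8]` (continuous), objective = validation loss.

See `vignettes/dermwolf-methods.Rmd` for the full account, including the
design decisions taken where the method description is ambiguous.

## Worked example

Generate a small synthetic cohort, run the whole pipeline (synthesize →
patient-grouped split → preprocess → segment → train → evaluate), and
print the report:

```r
library(dermwolf)

cfg <- pipeline_config(
  out_dir = "run1", seed = 7,
  synth   = list(n_images = 250, n_patients = 50, image_size = 32),
  segment = list(n_images = 3, pop_size = 20, max_iter = 60, repeats = 3)
)
rep <- run_pipeline(cfg)
print(rep)
```

```
<pipeline_report>
split:
        benign malignant
  train    162        18
  val       31         4
  test      32         3
segmentation median IoU:
  variant       iou
1    igwo 0.8509934
test metrics:
confusion (positive = malignant): TP=3 FP=0 FN=0 TN=32
  precision          1.0000 (100.0%)
  sensitivity        1.0000 (100.0%)
  specificity        1.0000 (100.0%)
  f1                 1.0000 (100.0%)
  accuracy           1.0000 (100.0%)
  balanced_accuracy  1.0000 (100.0%)
  g_mean             1.0000 (100.0%)
  mcc                1.0000 (100.0%)
  kappa              1.0000 (100.0%)
  auc                1.0000 (100.0%)
```

The split table shows the patient-grouped 70/15/15 partition preserving
the 10% malignant fraction; the IoU line is the overlap between the
optimizer-driven segmentation and the generator's exact ground-truth
masks (pixelation bounds it at the 32-px desk size — the 128-px
segmentation benchmark reaches a median of ~0.95); the metrics block is the held-out test-set report (at this desk
scale the synthetic two-class task is fully separable, so a successful
run reaches perfect scores — the interesting failures are collapse to the
majority class, which the class weighting prevents).

Individual pieces are plain functions, e.g.

```r
b  <- benchmark_function("rastrigin", 10)
sp <- search_space(b$lower, b$upper)
gwo_optimize(b$fn_mat, sp, igwo_config(seed = 1), vectorized = TRUE)$best_fitness
#> [1] 0

img <- make_lesion_image(benign_lesion_params(128), seed = 5)
th  <- find_thresholds(rgb_to_gray(img$image), m = 2, igwo_config(seed = 1), repeats = 25)
attr(th, "J")   # Kapur entropy at the chosen threshold (th = 165)
#> [1] 6.311051
```

A thin command-line front end over the same functions lives in
`inst/cli/dermwolf.R` (subcommands `synth`, `preprocess`, `segment`,
`train`, `evaluate`, `run`).

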