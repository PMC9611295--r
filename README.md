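# plinet

Phase-lag-index brain functional networks for task-switching EEG.

`plinet` is an R package for asking whether two task conditions —
for example a working-memory block recorded before and after a long,
fatiguing mental-arithmetic session — differ in the brain's functional
network organisation, and *which* connections carry the difference. It
is aimed at EEG researchers who work with multichannel task-state
recordings on an extended 10–20 montage and want a reproducible,
scriptable pipeline from raw channel × sample matrices to ranked
discriminative connections and cross-validated classification.

## What it computes

For each recording, after common average referencing and zero-phase
Butterworth decomposition into delta (0.5–4 Hz), theta (4–8 Hz), alpha
(8–13 Hz) and beta (13–30 Hz):

* **Sliding-window PLI connectivity.** The phase lag index between
  channels x and y over a window is
  `PLI = | mean_t sign(Δφ(t)) |`, with Δφ the Hilbert-phase difference
  wrapped to (−π, π]. Windows are 4 s with a 2-s step (a 400-s record
  gives 199 windows); with 60 channels there are 1770 pairs per band,
  7080 over the four rhythms. Window-averaged matrices are the per-
  recording connectivity.
* **Weighted graph metrics over a sparsity sweep.** The mean PLI matrix
  is proportionally thresholded (strongest s·1770 edges, weights kept)
  at s = 0.15 … 0.30 in 1 % steps, and at each level the weighted
  characteristic path length Lw, clustering coefficient Cw, global
  efficiency Eglobal and local efficiency Elocal are computed (path
  length = sum of reciprocal weights along the shortest path). Each
  metric is summarised by its trapezoidal area under the curve across
  the sweep.
* **Condition statistics.** One-way ANOVA compares the AUC features and
  every edge's PLI between conditions; edges at p < 0.05 enter the
  ranking stage.
* **Consensus SVM-RFE ranking.** RBF-kernel SVM recursive feature
  elimination is repeated on 1000 class-stratified 90 % subsamples and
  aggregated by positional vote counting; the top 20 connections are
  reported with scalp-region categories (frontal / central / parietal /
  occipital / temporal) and the direction of the condition difference.
* **Classification.** Stratified 10-fold cross-validated SVM, random
  forest and KNN on the concatenated four-band PLI feature vector.

A synthetic cohort generator (`synthetic_config()`,
`generate_cohort()`) produces two-condition, 60-channel recordings of
1/f background noise with *planted* band-specific phase coupling
(shared narrowband source, constant π/4 lag) on chosen channel pairs,
so the whole pipeline can be validated against known ground truth. See
`vignette("plinet-methods")` for the model, parameter and design
details.

## Worked example

Simulate a small two-condition cohort with one planted beta-band edge
(F3–P4, coupling 0.2 in condition A vs 0.8 in condition B) and run the
full pipeline on the beta rhythm:

```r
library(plinet)

cfg <- synthetic_config(
  n_subjects = 8, duration_s = 60, fs = 200,
  planted_edges = list(planted_edge("beta", "F3", "P4", 0.2, 0.8)),
  seed = 42)

pc <- pipeline_config(
  input = cfg, bands = eeg_bands()["beta"],
  rfe = list(n_runs = 100, subsample = 0.9, C = 1, kernel = "rbf"),
  classify = list(models = c("svm", "rf", "knn"), folds = 8),
  n_top = 5, seed = 42)

res <- run_pipeline(pc)
res$feature_comparisons[, c("band", "metric", "F", "p", "significant")]
#>   band  metric         F            p significant
#> 1 beta      Lw 4085.8704 1.135749e-18        TRUE
#> 2 beta      Cw  650.5328 3.894483e-13        TRUE
#> 3 beta Eglobal 1273.8721 3.775636e-15        TRUE
#> 4 beta  Elocal 1158.1662 7.300973e-15        TRUE

as.data.frame(res$top)[, c("rank", "channel_a", "channel_b", "votes",
                           "region_category", "direction")]
#>   rank channel_a channel_b votes  region_category direction
#> 1    1        F3        P4    70 frontal-parietal     B > A
#> 2    2        F3        F1    30  frontal-frontal     B > A
#> 3    3       FC4        P4    24 central-parietal     B > A
#> 4    4        C2        P4    26 central-parietal     B > A
#> 5    5        F1        P4    49 frontal-parietal     B > A

res$reports$svm
#> <classification_report> svm, 8-fold CV on n = 16
#>   mean accuracy 1.000 (sd 0.000)
```

Reading the output: the planted contrast shifts all four AUC network
features (the tiny p values reflect the deliberately large coupling
difference), the planted F3–P4 edge is ranked first by the consensus
with the correct direction (B, the strongly coupled condition, has the
larger PLI), and the runner-up edges all involve F3 or P4 — a real
common-average-reference effect discussed in the vignette. The planted
contrast is easily classified from the PLI features.

Real recordings enter the same machinery as plain numeric matrix files
(rows = channels in montage order) with a `manifest.csv`, via
`pipeline_config(input = "<dir>")`; a custom montage can be supplied as
a `label,region` CSV. A thin command-line front end is installed at
`inst/cli/plinet` (subcommands `simulate` and `run-all`).

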