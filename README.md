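# pcgewt

Grading left anterior descending (LAD) coronary artery stenosis from
diastolic heart sounds.

A stenosed coronary artery radiates a faint turbulent murmur in early
diastole, when coronary flow peaks. `pcgewt` implements a complete,
testable analysis pipeline for single-channel phonocardiogram (PCG)
recordings:

1. **Preprocess** — resample to 2000 Hz, normalize to [−1, 1], denoise with
   sym3 wavelet thresholding at the universal threshold
   `β_j = σ_j √(2 ln N_j)`, `σ_j = median(|CD_j|)/0.6745`.
2. **Segment** — detect the second heart sound (S2) on the envelope of the
   high-passed signal (ECG R-peak gating when available), mark the S2 end
   at 10% of the peak envelope, and cut a fixed 128 ms diastolic window
   starting 100 ms after the S2 end (256 samples).
3. **Decompose** — a Meyer-type empirical wavelet transform with fixed
   boundaries splits each window into three modes: 0–150, 150–500 and
   >500 Hz. Transitions of half-width `τ = 0.1π` are shaped by
   `β(x) = x²(3−2x)`, making the bank a tight frame (energies partition
   exactly; synthesis reconstructs to machine precision).
4. **Featurize** — band spectral energies `e(1)`, `e(2)`, `e(3)` (V²·s,
   Parseval convention) and ratios `P1 = e2/e1`, `P2 = e3/e1`. `e(2)` and
   `e(3)` grow monotonically with stenosis severity.
5. **Compare & classify** — rank statistics (Mann–Whitney U,
   Kruskal–Wallis, DeLong AUC comparison) and participant-wise
   classification into mild (<50%), moderate (50–75%) and severe (>75%)
   stenosis with an RBF-kernel SVM (SMO solver) and softmax
   gradient-boosted trees, both implemented in compiled code in-package
   and tuned by grouped, stratified five-fold CV.

Because no public clinical recordings exist for this task, the package
ships a first-class synthetic cohort generator (`simulate_cohort()`) with
ground-truth event times: 75 participants in seven stenosis groups
(10/10/10/15/10/10/10), ten analyzable diastoles each, a murmur whose
amplitude grows as `stenosis^1.5` (calibrated so mean `e(2)` at 30%
stenosis is ~1e-6 V²·s), and configurable background noise. See the
methods vignette (`vignettes/diastolic-ewt-methods.Rmd`) for what the
generator does and does not emulate.

## Worked example

```r
library(pcgewt)

sim  <- simulate_participant(stenosis_pct = 30, seed = 42, participant_id = "P001")
rec  <- preprocess_pcg(sim$record)            # resample + normalize + denoise
s2   <- detect_s2(rec, rec$r_times)           # 14 S2 events found
segs <- extract_diastoles(rec, s2)            # 256 x 10 diastole matrix
bank <- ewt_filter_bank(2000)
feats <- do.call(rbind, lapply(seq_len(ncol(segs$segments)), function(k)
  compute_features(ewt_decompose(segs$segments[, k], bank),
                   participant_id = "P001", cycle_index = k)))
signif(colMeans(feats[c("e1", "e2", "e3", "P1", "P2")]), 3)
#>       e1       e2       e3       P1       P2
#> 2.68e-05 1.13e-06 6.52e-07 4.20e-02 2.50e-02
```

The mean `e(2)` of ~1.1e-6 V²·s is the expected order of magnitude for a
30% stenosis; a murmur-free normal subject gives `e(2)` several orders of
magnitude lower.

The full end-to-end experiment (simulate 75 participants, 750 segments,
600/150 participant-wise split, tune and evaluate both classifiers; ~5 min
on one CPU):

```r
out <- run_pipeline(default_config(seed = 11))
out$report_svm$accuracy   # 0.82    (C = 3.2, gamma = 0.1)
out$report_xgb$accuracy   # 0.8467  (100 trees, lr 0.01, depth 3, subsample 1)
out$report_xgb$auc
#>      class       auc  ci_lower  ci_upper
#> 1     mild 0.9825000 0.9651286 0.9998714
#> 2 moderate 0.8961364 0.8409863 0.9512865
#> 3   severe 0.9639815 0.9339495 0.9940135
```

These numbers measure the pipeline on synthetic data; they are not
clinical performance claims.

## Command line

```sh
Rscript inst/cli/pcgewt.R simulate --out-dir cohort/ --seed 1
Rscript inst/cli/pcgewt.R extract  --manifest cohort/manifest.csv --out features.csv
Rscript inst/cli/pcgewt.R run      --out-dir results/ --seed 1
```

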