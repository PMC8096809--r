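# oncorecur

Weakly supervised prediction of distant breast-cancer recurrence — one
year in advance — from a patient's stream of free-text clinical notes.

Free-text notes carry the most nuanced record of a cancer patient's
clinical course, but exhaustive manual chart review scales to hundreds of
patients, not thousands. `oncorecur` implements a complete
weak-supervision pipeline for this problem, aimed at clinical NLP
researchers and methodologists:

1. **Preprocessing** — lowercasing, punctuation stripping, digit runs
   spelled as words, stopword/heading/boilerplate/proper-noun removal, a
   corpus-level rare-word filter, and CLEVER-style lexicon normalisation
   ("brother" → "FAM", "cancer"/"lesion" → "CA").
2. **Embedding** — skip-gram word vectors (negative sampling; defaults
   dim 300, window 30, 30 epochs) and tf-idf-weighted note vectors
   `V_note = (1/N) Σ_w tf(w)·ln(N_notes/df(w))·V_w`.
3. **Timelines** — chronological per-patient note-vector sequences with
   one-year-ahead labels (`y_t = 1` iff recurrence occurs within 365
   days of note `t`), truncated/right-padded to a fixed length with a
   zero-weighted pad class.
4. **Model** — a 1-directional, many-to-many stacked LSTM
   (50 units + batch-norm + 20% dropout → 25 units + 20% dropout →
   3-class softmax; 77,978 ≈ 78 K trainable parameters), trained with
   weighted categorical cross-entropy and Adam under three supervision
   strategies: *traditional* (manual labels only), *weak #1*
   (manual + high-specificity NLP labels), *weak #2*
   (manual + high-sensitivity NLP labels). An XGBoost single-note
   baseline quantifies the value of temporal context.
5. **Evaluation** — note-level AUROC (Mann-Whitney concordance), the
   Youden-optimal operating point, patient-level bootstrap uncertainty,
   prediction intervals (days between the first above-threshold alarm
   and the confirmed recurrence), and t-SNE embedding diagnostics.
6. **Synthetic data** — a generator for realistic longitudinal note
   corpora (renewal-process visit streams, Zipf vocabulary, a noisy
   escalating recurrence signal, and a configurable imperfect weak-label
   extractor), so the entire pipeline runs end-to-end without access to
   protected health data.

The skip-gram trainer and the LSTM (forward pass, backpropagation
through time, Adam, batch normalisation) are implemented in
Rcpp/RcppArmadillo, single-threaded and bitwise reproducible given a
seed.

## Worked example

A full three-strategy, two-model comparison on a 2,000-patient synthetic
cohort (the compact desktop configuration; ~90 s on one CPU core):

```r
library(oncorecur)
res <- run_experiment(demo_experiment_config(seed = 1))
res$report[, .(strategy, model, auroc, auroc_se, sensitivity, specificity)]
#>       strategy  model     auroc    auroc_se sensitivity specificity
#> 1: traditional   lstm 0.8127207 0.117701240   0.7391304   0.9565826
#> 2: traditional    gbt 0.7308489 0.039987923   0.4565217   0.9425770
#> 3:       weak1   lstm 0.9878517 0.009162109   0.9782609   0.9747899
#> 4:       weak1    gbt 0.7528316 0.052914582   0.6956522   0.7955182
#> 5:       weak2   lstm 0.9785653 0.016553960   0.9782609   0.9537815
#> 6:       weak2    gbt 0.7652539 0.045876506   0.6086957   0.9103641
```

Each row is one supervision strategy crossed with one model, evaluated
note-by-note on the same fixed, manually labelled test cohort with
post-recurrence notes excluded. `auroc` is the probability a random
positive note outscores a random negative one; `sensitivity` and
`specificity` are taken at the ROC operating point maximising their sum;
`*_se` columns are patient-level bootstrap standard deviations. The
pattern mirrors the scientific claim the package exists to study: both
weak-supervision strategies beat the small manually curated training set
for the sequence model, and the LSTM beats the single-note
gradient-boosted baseline under every strategy because the synthetic
recurrence signal is noisy per note but consistent over time.

Per-patient probability trajectories and alarm lead times:

```r
det <- res$details[["weak2.lstm"]]
probs <- split(det$scores, det$pids)[unique(det$pids)]
pi <- prediction_intervals(res$test_timelines, probs, det$threshold)
pi$histogram   # counts of lead times in 100-day bins
#>   [0,100) [100,200) [200,300) [300,400) [400,500)
#>         0         0         3         3         1
```

Most successfully flagged test patients are first alarmed 200–400 days
before their confirmed recurrence, i.e. at roughly the intended one-year
horizon.

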