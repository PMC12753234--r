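# lupine

Deep matrix-completion imputation for quantitative proteomics.

Protein quantification matrices from TMT, DIA, or LFQ workflows are riddled
with missing values, and the missingness is *not at random*: low-abundance
measurements preferentially drop out (left-censoring, MNAR). `lupine` imputes
such matrices with a deep matrix-completion model — each protein `i` and
sample `j` carries a learned embedding, and a multilayer perceptron predicts
the log-scale intensity from the concatenated pair:

    xhat_ij = MLP([ W_i , H_j ]),    W: n x p,  H: q x m

with leaky-ReLU activations (slope 0.1), trained by MSE with Adam
(lr = 0.001, batch size 128) under an explicitly MNAR regime: train/test
partitions come from a Gaussian *thresholds matrix* that censors
low-intensity entries, and training batches are sampled with a bias toward
low-intensity values. The final imputation averages an ensemble of
independently seeded models with hyperparameters drawn from a grid
(factor counts, hidden layers, nodes per layer).

Around the core model the package provides the full evaluation stack:

* **quantio** — wide-TSV readers/writers, sample-keyword exclusion,
  multi-dataset joint-matrix assembly (union of proteins, NaN fill,
  min-present filtering);
* **partition** — MNAR thresholds/Bernoulli and MCAR partitioners, analytic
  Bernoulli-probability calibration, left-skewed batch sampling;
* **baselines & metrics** — kNN and Perseus-style Gaussian down-shift
  imputers, held-out test MSE, per-protein residual comparisons;
* **simulate** — a two-condition spike-in generator with controlled
  MNAR/MCAR missingness and known differential-abundance labels;
* **da_stats** — paired t-tests, Benjamini–Hochberg adjustment, DA calling
  (adj-p < 0.01, |log2 FC| > 0.5), precision-recall AUC, and within-complex
  vs random protein correlation analysis.

## Worked example

Simulate a small two-condition study, censor it MNAR, impute, and test for
differential abundance:

```r
library(lupine)

# 500 proteins, 64 samples per condition, 20% of proteins DA (10% mean shift)
sim <- simulate_da(n_proteins = 500, n_samples = 64, delta_pct = 0.10, seed = 1)
#> simulated_study: 500 proteins x 64 samples per condition, 50 up / 50 down DA (delta 0.1)

# censor 20% of entries, mostly MNAR (low values drop out first)
joint <- inject_missingness(cbind(sim$A, sim$B), target_frac = 0.2, seed = 2)
X <- quant_matrix(joint)
#> quant_matrix: 500 proteins x 128 samples (20.0% missing, 1 dataset)
mean(cbind(sim$A, sim$B)[is.na(joint)])   # censored values sit left of ...
#> 10.74
mean(joint, na.rm = TRUE)                 # ... the retained ones
#> 12.34

# impute with a 3-member ensemble from the desk-scale hyperparameter grid
res <- ensemble_impute(X, n_models = 3, grid = reduced_grid(), base_seed = 3)
res$member_traces[[1]]
#> training_trace: 12 epochs, stopped by tolerance, final val MSE 2.418

# paired differential-abundance testing on the imputed matrix
tests <- paired_t_tests(res$imputed$values, pairs = cbind(1:64, 64 + 1:64))
table(call_da(tests)$call)
#>       up     down   not_da excluded
#>       41       31      428        0

# rank by p-value and score against the spiked-in truth
truth <- seq_len(500) %in% c(sim$true_da_up, sim$true_da_down)
pr_auc(tests$p_value, truth, tiebreak = abs(tests$log2_fc))
#> 0.947
```

The censored values average 1.6 log2 units below the retained ones — the
left shift that MNAR-aware imputation is built for. Of the 100 spiked
proteins, 72 are called at the strict thresholds and the p-value ranking
recovers the spike-in set with a precision-recall AUC of 0.95.

Real cohort matrices follow the same pattern, starting instead from
`read_quant_matrix()` / `build_joint_matrix()`, with `mnar_partition()` and
`test_mse()` for held-out benchmarking against `knn_impute()` and
`gaussian_downshift_impute()`. A thin command-line front end covering the
same workflow (join, partition, impute, benchmark, simulate, da,
complexcorr) is installed under the package's `exec/` directory.

## Notes

* Inputs are assumed log-scale and reference-normalized; the package applies
  no transform. Peptide-to-protein rollup and reporter-ion normalization are
  upstream concerns.
* See the methods vignette (`vignettes/lupine-methods.Rmd`) for the model,
  the MNAR partitioning and batch-bias machinery, stopping criteria,
  the simulation's scope, and known limitations.
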