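# dsafgs

Hybrid autoencoder-filtered gene selection with Shapley attribution for
binary event prediction from genome-scale expression data.

## The problem

Expression cohorts in clinical genomics pair ~20,000 gene measurements
with a few hundred patients and a binary endpoint (event / no event).
Massive redundancy — duplicate probes and tightly co-regulated
transcripts — and class imbalance make both classification and
interpretation fragile. `dsafgs` is for researchers who want a *small,
named* panel of genes driving an event classifier, selected without ever
leaving the original feature space: every retained feature is a real
gene, never a latent projection.

## The method

1. **Redundancy clustering** — gene–gene Pearson correlation `r`;
   average-linkage hierarchical clustering on `d = 1 − r`, cut at `k`
   clusters (default 500).
2. **Autoencoder filter** — per cluster, an autoencoder
   (`P–⌊P/5⌋–⌊P/10⌋–⌊P/5⌋–P` neurons for `P` patients; relu, Adam 0.01,
   MAE, 1000 epochs) is trained with *patients as features and genes as
   samples*; the cluster representative is the gene with minimal mean
   absolute reconstruction error.
3. **F ranking** — representatives are ranked by the one-way statistic
   `F = (SSB/1) / (SSW/(n−2))` over the two label groups (equal to the
   squared pooled t) and truncated to candidate sizes {5, 10, 50, 100, 300}.
4. **Classifier** — a grid of feed-forward nets (depths {2, 3, 4} × first
   widths {8, …, 256}, halving; sigmoid output; binary cross-entropy;
   Adam 0.001) evaluated by 10 × 90/10 stratified Monte-Carlo
   cross-validation, SMOTE applied to training folds only; the chosen
   configuration maximizes mean test accuracy.
5. **Attribution** — Kernel SHAP: weighted least squares over coalition
   indicators with the Shapley kernel
   `w(s) = (m−1)/(C(m,s)·s·(m−s))`, exact enumeration for ≤ 15 genes,
   interventional masking against a 100-patient background; genes ranked
   by mean |φ|. An exact-enumeration Shapley solver is included for
   validation.

## Worked example

Everything below is generated in code — no downloads.

```r
library(dsafgs)

coh <- generate_cohort(synthetic_spec(
  n_patients = 80L, n_genes = 300L, n_clusters = 10L,
  n_informative = 4L, effect_size = 1.5,
  class_balance = c(44L, 36L), seed = 19L))
coh$informative_genes
#> [1] "G001" "G031" "G061" "G091"

cfg <- run_config(k_clusters = 10L, subset_sizes = c(5L, 10L),
                  ae = list(epochs = 60L),
                  grid = list(depths = 2L, first_widths = c(8L, 16L), epochs = 80L),
                  cv = list(iterations = 3L),
                  shap = list(background = 20L, budget = 300L),
                  seed = 19L, verbose = FALSE)
report <- run_pipeline(coh$dataset, cfg)
print(report)
#> RunReport (seed 19)
#>   best subset size: 5 genes; hidden layers ( 16, 8 )
#>  n_genes mean_accuracy sd_accuracy  ci_lower  ci_upper best_accuracy hidden
#>        5     0.9583333  0.07216878 0.8168825 1.0997841         1.000   16-8
#>       10     0.7916667  0.07216878 0.6502159 0.9331175         0.875   16-8
#>   held-out: accuracy 1.000, sensitivity 1.000, specificity 1.000, AUC 1.000
#>   top SHAP genes: G061, G001, G031, G139, G091
```

Reading the output: the per-size table is the cross-validated accuracy of
the best architecture at each candidate panel size (mean ± sd over the
Monte-Carlo iterations, with the 95% interval `mean ± 1.96·sd`); the
5-gene panel wins, and the mean-|φ| SHAP ranking places the four planted
informative genes among its top five positions. On real data you would
start from files instead:

```r
ds <- read_expression_matrix("expression.tsv")   # genes x patients, gzip ok
ds <- attach_labels(ds, "labels.tsv")            # patient_id <TAB> event
ds <- qc_filter_samples(ds)$dataset
report <- run_pipeline(ds, run_config(seed = 1L), out_dir = "results/")
```

A thin command-line wrapper with `run` and `simulate` subcommands is
installed at `inst/cli/dsafgs.R`.

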