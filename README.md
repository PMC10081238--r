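# robustewas

Robust epigenome- and transcriptome-wide association testing by k-fold
Stouffer meta-analysis.

## The problem

In epigenome- and transcriptome-wide association studies (E/TWAS), hundreds
of thousands of markers (methylation sites, transcripts) are each tested for
association with an outcome. Multiple-testing corrections control false
discoveries caused by sampling fluctuation, but they do nothing against
false discoveries caused by **outliers and other data artefacts** — and
because an artefact can manufacture an artificially small p-value, such
findings are disproportionally over-represented among the top hits, where
they then fail to replicate.

A single *bivariate* outlier — one individual with extreme values in both
the outcome and the marker — is the dangerous case: a concordant extreme
pair manufactures association signal out of nothing, and it will
"replicate" in a split-half design at an inflated rate because the outlier
sits in either the discovery or the replication half.

## The method

The robust E/TWAS procedure implemented here:

1. partition the n samples into *k* equal, non-overlapping folds
   (stratified on a binary outcome);
2. run the covariate-adjusted linear association test separately in each
   fold — the model `marker ~ intercept + outcome + covariates` is refit
   per fold;
3. transform each fold's T statistic into a signed Z statistic through the
   exact t-tail mapping and combine them with Stouffer's method,
   `Z_meta = Σ zᵢ / √k`;
4. apply the multiple-testing correction to the meta-analysis p-values.

An artefact contaminates only the fold containing it, so its influence on
`Z_meta` is diluted by `1/√k`; the remaining folds are untouched. At `k = 1`
the procedure reduces exactly to the conventional full-sample analysis.

The package also provides the comparator strategies (full-sample analysis;
split-half discovery/replication with a one-sided replication test in the
discovery direction), diagnostics (genomic inflation factor λ, MAD-based
residual outlier flags, per-feature outlier-sensitivity refits), a
simulation framework for type-I error and power under univariate and
bivariate outliers, and a synthetic EWAS fixture generator with known
truths.

## Worked example

One null marker (n = 250, zero true correlation) contaminated with a single
concordant bivariate outlier 6 SDs out:

```r
library(robustewas)
set.seed(42)
pair <- generate_pair(250, rho = 0)
cont <- inject_bivariate_outlier(pair$y, pair$x, count = 1, magnitude = 6)
ds <- ewas_dataset(matrix(cont$x, 1, dimnames = list("cg_demo", NULL)), cont$y)

full_sample_ewas(ds)[, c("t_stat", "p")]
#> full-sample p: 0.00341   t: 2.96
robust_ewas(ds, k = 10, seed = 7)[, c("z_meta", "p_meta")]
#> robust k=10 p_meta: 0.112   z_meta: 1.59
outlier_sensitivity(cont$y, cont$x)
#> outlier_sensitivity: p_full = 0.00341, p_trimmed = 0.264 (2 sample(s) removed)
#>   p_trimmed / p_full = 77.5 -> not outlier-driven (cut 100)
```

The full-sample test is fooled (p = 0.003 for a null marker); the robust
k = 10 analysis dilutes the contaminated fold and reports p = 0.11. The
post-hoc MAD sensitivity refit shows the evidence collapsing ~78-fold when
the flagged observations are removed.

The same phenomenon at study scale — empirical type-I error at α = 0.05
over 2,000 null replicates, one bivariate outlier each:

```r
cfg <- sim_config(n = 250, n_sims = 2000, rho = 0, n_bivariate_outliers = 1,
                  k_values = c(2, 5, 10, 20), seed = 1)
run_type1_study(cfg)
#>      method  k      metric        scenario alpha   rate       se n_used
#>        full NA   rejection bivariate1_mag6  0.05 0.5305 0.011160   2000
#>      robust  2   rejection bivariate1_mag6  0.05 0.4385 0.011095   2000
#>      robust  5   rejection bivariate1_mag6  0.05 0.2780 0.010018   2000
#>      robust 10  rejection bivariate1_mag6  0.05 0.1705 0.008409   2000
#>      robust 20  rejection bivariate1_mag6  0.05 0.1015 0.006753   2000
#>  split_half NA conditional bivariate1_mag6  0.05 0.0643 0.008886    762
#>  split_half NA       joint bivariate1_mag6  0.05 0.0245 0.003457   2000
```

The nominal rate is 0.05: the full-sample analysis rejects 53% of null
markers, and the inflation of the robust method falls monotonically with
the number of folds. For split-half replication both the conditional
replication rate among discoveries and the joint
discovery-and-replication rate are reported.

## Command line

A thin CLI over the same functions ships in `inst/cli/robust-ewas.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "robust-ewas.R", package = "robustewas"))')
Rscript "$CLI" run --markers betas.tsv --phenotype pheno.tsv \
    --outcome-column status --method robust --k 5 --seed 1 --out results.tsv
Rscript "$CLI" simulate --mode type1 --config sim.yaml --out rates.tsv
Rscript "$CLI" diagnose --markers betas.tsv --phenotype pheno.tsv \
    --outcome-column status --features cg00000029 --out diag.tsv
```

Marker matrices are TSV/CSV, features x samples (EWAS convention; an
orientation flag handles the transpose). Every results file carries a
`#`-prefixed reproducibility header (version, seed, k, adjustment,
thresholds) and is re-readable with `read_results()`.

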