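# tumorir — tumor-infiltrating B- and T-cell repertoire analysis

Bulk RNA-seq of solid tumors captures the transcripts of infiltrating B and
T lymphocytes alongside the tumor's own. After a tool such as MiXCR extracts
receptor reads and their CDR3 regions, each sample yields a clonotype table:
one row per distinct receptor nucleotide sequence with its chain, V/J gene
calls, CDR3 and read count. `tumorir` is an R package for everything
downstream of that table, aimed at analysts comparing the immune repertoire
of tumor and normal tissue cohorts:

* **Clone assignment.** Sequences with the same V gene, J gene, CDR3 length
  and CDR3 nucleotide identity ≥ 0.90 (immunoglobulin) / 0.95 (T-cell
  receptor) form a clone — connected components under single linkage
  (`assign_clones`, `build_clonotype_matrix`).
* **Richness and diversity.** Receptor expression `M / (N + M)` and Shannon
  entropy `H = −Σ pᵢ log₂ pᵢ` over clone frequencies, with a read-level
  subsampling sensitivity analysis (`receptor_expression`,
  `shannon_entropy`, `subsample_metrics`).
* **Clonal networks.** Vertices are unique sequences sized by identical
  reads; edges follow the clone definition; Gini indices of vertex and
  cluster sizes quantify clonal expansion, Gini(V), and clonal dominance,
  Gini(C) (`build_network`, `network_metrics`).
* **Compositional clonotype selection.** Counts are compositional, so
  selection works in centred log-ratio coordinates with an offset of 1
  against zeros, `clr(x)ⱼ = log xⱼ − mean log x`; an L1-penalised logistic
  regression picks the clonotypes separating tumor from normal, and Ward
  clustering groups samples on them (`clr_transform`, `lasso_select`,
  `cluster_samples`).
* **Prognostic variance partitioning.** A Bayesian RKHS regression
  `y = Xβ + p + ε` with `p ~ N(0, K σ²ₖ)`, `ε ~ N(0, I σ²ₑ)` and `K` a
  normalised linear kernel on the whole CLR clonotype profile, fitted by an
  eigenbasis Gibbs sampler; the headline quantity is the posterior of
  `σ²ₖ / (σ²ₖ + σ²ₑ)`, the repertoire's share of prognostic phenotypic
  variance (`linear_kernel`, `rkhs_gibbs`, `variance_explained`).
* **Synthetic cohorts with known truth.** `simulate_cohort()` generates
  MiXCR-like cohorts with controllable clonal expansion, planted
  group-discriminative clonotypes and kernel-linked survival, so every
  stage has an exact recovery test (`sim_config`, `planted_clonotype_ids`).

The methods vignette (`vignettes/repertoire-methods.Rmd`) documents the
models, parameter choices, and what the synthetic cohorts do and do not
establish.

## Worked example: the analysis workflow

The `analysis/` directory is a numbered workflow over the package; each
script states what it found and writes its tables under `results/`
(the simulated cohort itself goes to `scratch/`, regenerated on demand):

```sh
Rscript analysis/01_simulate_cohort.R   # 144 tumor + 180 normal samples
Rscript analysis/02_diversity.R
Rscript analysis/03_network.R
Rscript analysis/04_clonotype_selection.R
Rscript analysis/05_prognostic_variance.R
```

Output of a complete run (seed 42):

```
cohort: 324 samples (144 tumor / 180 normal), 313764 records
mean receptor reads: tumor 7926, normal 2073
sample QC (>= 100 IG clones): 324 of 324 samples retained
expression: tumor mean 0.007857 vs normal 0.002069 (one-sided Wilcoxon p = 1.62e-53)
entropy: tumor mean 8.161 vs normal 7.457 (one-sided Wilcoxon p = 2.34e-50)
subsampling (tumor48): entropy 8.253 bits at 20% vs 8.368 at full depth
gini_v: tumor mean 0.527 vs normal 0.449 (one-sided Wilcoxon p = 1.95e-47)
gini_c: tumor mean 0.396 vs normal 0.379 (one-sided Wilcoxon p = 4.97e-10)
clonotype matrix after presence filter: 324 samples x 310 clonotypes
CLR-LASSO selected 10 clonotypes; 10 of 10 planted recovered, 0 others
tumor clusters (1 = lowest infiltration): sizes 42 / 38 / 64
variance explained by the IGK profile: 17.1% [2.6%, 48.2%] (simulated truth 24%)
```

Reading these numbers: tumor samples are richer (≈ 3.8× higher receptor
expression), more diverse (+0.7 bits of clone entropy), more clonally
expanded (higher Gini of vertex sizes) and more clonally dominated (higher
Gini of cluster sizes) than normal samples — the qualitative contrast the
pipeline is designed to detect, here planted by the generator. The
CLR-LASSO finds exactly the 10 planted discriminative clonotypes with no
false positives; Ward clustering on them splits the tumors into three
clusters ordered by infiltration. The RKHS posterior attributes 17% (95%
credible interval 3–48%) of the prognostic phenotypic variance to the IGK
profile, bracketing the simulated truth of 24%.

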