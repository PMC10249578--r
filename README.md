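# bcrpipe

Isotype-resolved B-cell receptor (BCR) repertoire analysis for antibody
amplicon data that captures the variable domain *and* the start of the
constant region in the same molecule — single-/few-cell sorted memory B
cells and bulk long-read tissue repertoires. The package is aimed at
immunologists studying clonal expansion, somatic hypermutation (SHM),
class-switch recombination (CSR) and receptor revision in tissue-infiltrating
B cells, e.g. in tumors or autoimmune lesions.

## What it does

* **Germline modelling** — V/D/J/C alleles with 5'→3' locus ranks P and the
  deletional IGH constant-gene order (IgM → … → IgA2), the geometry behind
  every upstream/downstream argument (`load_germline_fasta()`,
  `relative_position()`).
* **Annotation** — V(D)J assignment by local alignment (match +5, mismatch
  −4, gap open 10), junction/CDR3 extraction at the conserved Cys…Trp/Phe
  anchors, productivity calling, isotype assignment from the 3' constant
  fragment, and region-resolved mutation profiling: each mismatch classified
  Silent/Replacement by codon translation in the germline frame and
  Framework/CDR by the germline boundaries (`annotate_repertoire()`).
* **Clonotyping** — normalized CDRH3 Levenshtein distance, single-linkage
  clustering, tree cut at 0.05 (`cluster_clones()`).
* **Lineages** — germline-rooted maximum-parsimony trees with exact per-edge
  mutation lists and intra-clone CSR detection, always directed downstream
  in the constant order (`build_lineage()`, `detect_csr_within_clone()`).
* **Receptor revision** — VH replacement detected from same-CDR3 groups with
  discordant V calls via a crossover (allegiance changepoint) plus a cryptic
  RSS heptamer (CACAGTG, CAC core intact, ≤1 mismatch) within ±10 nt and an
  upstream invader; secondary lambda rearrangements from cells with two
  lambda chains, same J family, different V genes, one unproductive
  (`detect_vh_replacement()`, `detect_lambda_secondary()`,
  `revision_frequency()`).
* **CDR3 descriptors** — Kidera-factor means, group PCA, and
  Chou–Fasman-derived α/β/coil preference proportions (`kidera()`,
  `kidera_pca()`, `structure_propensity()`).
* **Statistics** — pooled two-sample proportion z-test
  (Z = (p_T − p_B)/√(p̂(1−p̂)(1/n_T + 1/n_B)), p̂ the pooled proportion),
  label-permutation ratio test (n = 1000, add-one empirical p), percentile
  bootstrap CIs (n = 1000, 95%), gene-usage and repertoire summary tables
  (`proportion_ztest()`, `permutation_ratio_test()`, `bootstrap_ci()`).
* **Simulation** — a fully ground-truthed repertoire generator with clonal
  expansion, SHM, CSR, unproductive rearrangements and mechanistic
  receptor-revision events (`simulate_repertoire()`).

I/O is standard: FASTA in, AIRR Rearrangement TSV throughout, Newick + JSON
for trees, TSV/JSON for tables. `run_pipeline()` (or the thin wrapper in
`inst/scripts/run-pipeline.R`) orchestrates all stages with a single seed
and a config hash stamped on every artifact.

## Worked example

```r
library(bcrpipe)

model <- demo_locus_model()
sim <- simulate_repertoire(sim_config(model, n_cells = 300, seed = 1,
                                      vh_replacement_rate = 0.2))
ann <- annotate_repertoire(sim$reads, model, collapse = TRUE)

clones <- cluster_clones(ann[ann$chain == "heavy", ])
clone_summary(clones)$n_nonsingleton
#> [1] 71

heavy <- ann[ann$chain == "heavy", ]
events <- detect_vh_replacement(heavy, model)
revision_frequency(events, heavy)$per_sample
#> # A tibble: 1 × 4
#>   sample_id n_events n_sequences frequency
#>   <chr>        <int>       <int>     <dbl>
#> 1 S1              39         357     0.109
```

Here 71 clonotypes contain more than one unique sequence, and 39 of 357
unique heavy-chain sequences (10.9%) carry a detected hybrid V — each call
backed by a same-CDR3 partner with a different V gene, a crossover at a
cryptic heptamer, and an upstream invader. Comparing against `sim$truth`
gives detector sensitivity and specificity directly.

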