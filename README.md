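# graphpop

Variation-graph (pangenome) references promise more accurate short-read
mapping than a linear reference because reads carrying non-reference alleles
can align through alternative paths instead of being mismatched, clipped, or
placed at the wrong locus — the mechanism behind *reference allele bias*.
But adding alleles also adds spurious paths, so the composition of the graph
matters: which variants, prioritized how, from which (sub)population?

`graphpop` re-creates this entire study design at desk scale, on fully
synthetic data, for populations with strong substructure (the motivating
case is cattle breeds):

* **Synthetic populations** — a pseudo-random reference with realistic
  mapping difficulty (interspersed repeat families, near-identical
  segmental duplications, microsatellite runs) and multi-population phased
  variant panels with a controllable site-frequency spectrum (default
  singleton proportion 0.14, indel fraction 0.11, indels < 50 bp).
* **Graph construction** — bubble graphs over a linear backbone from
  variants selected by alternate allele frequency (AF strictly greater than
  a threshold), count-matched across populations, pooled (pan-genome),
  random/unphased, personalized, or empty; haplotype walks; node/edge/k-mer
  statistics; GFA output.
* **Consensus references** — major-allele (AF > 0.5) linear references with
  UCSC-chain coordinate liftover.
* **Read simulation** — haplotype-aware paired-end reads (150 bp, fragments
  500 ± 50, substitution rate 0.01, indel rate 0.002) with exact truth
  coordinates.
* **Mapping** — a deterministic seed-and-extend aligner (Rcpp) over linear,
  consensus, and graph references (haplotype-restricted alternate-allele
  contigs with exact surjection to linear coordinates), with
  `MQ = min(60, 6·(best − second))` and joint pair scoring.
* **Genotyping** — a pileup caller with allelic-depth bookkeeping, binomial
  genotype likelihoods, and the conventional QD > 10, MQ > 40, DP > 25 site
  filters.
* **Evaluation** — every statistic of the study design: mapping-error rates
  with the `|mapped − true| ≤ k = 150` criterion, pseudo-ROC over MQ
  thresholds {60, 50, 40, 30, 20, 10, 0}
  (`TPR_i = Σ_{k=i}^{60} TP_k / n`), perfect/unique mapping summaries,
  allelic-ratio profiles by signed variant length
  (`AD_alt / (AD_ref + AD_alt)`, 0.5 = unbiased), and genotype concordance
  metrics (concordance, non-reference sensitivity, precision, non-reference
  discrepancy).

## Worked example

Compare a population-specific augmented graph against the linear reference
and a random-variant graph on a 100-kb genome:

```r
library(graphpop)
cfg <- experiment_config(
  genome_length = 100000L,
  pops = c(A = 10L, B = 10L, OUT = 10L),
  modes = c("empty", "targeted", "random"),
  sim = sim_params(n_pairs = 5000L),
  n_replicates = 3L, base_seed = 1L)
rep <- run_experiment(cfg, quiet = TRUE)
print(rep)
#> <experiment_report> 9 cells
#>       mode threshold n mean_error    se_error mean_perfect mean_unique
#> 1    empty        NA 3 0.02473333 0.001234684    0.1206000   0.9248667
#> 2   random        NA 3 0.02480000 0.001171893    0.1206333   0.9260333
#> 3 targeted        NA 3 0.01340000 0.001058301    0.1626333   0.9446000
```

The graph augmented with the read population's common variants (`targeted`)
roughly halves the proportion of incorrectly mapped reads relative to the
linear reference (`empty`), while a graph of random variants with unknown
frequency and phase (`random`) does not improve on it — the central
qualitative findings of frequency-based variant prioritization.
`mean_perfect` rises with the graph because reads carrying alternate
alleles can align end-to-end without mismatches; `run_bias_experiment()`
and `run_genotyping_experiment()` expose the companion allelic-ratio and
genotype-concordance analyses, and `plot_error_by_threshold()`,
`plot_pseudo_roc()` and `plot_bias_profile()` draw the standard figures.

The methods vignette (`vignettes/variation-graph-evaluation.Rmd`) documents
the population model, the repeat/duplication calibration, the mapper's
numerical choices, and known limitations.

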