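---
title: "Evaluating variation-graph references on synthetic structured populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating variation-graph references on synthetic structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(graphpop)
```

## The problem

A linear reference genome carries no allelic variation, so sequencing reads
from individuals that differ from it -- particularly reads spanning
insertions and deletions -- align worse than reads matching the reference.
This *reference allele bias* distorts mapping accuracy and allele-frequency
estimates. A variation-aware reference (genome graph) augments the linear
backbone with alternative alleles: nodes represent allele subsequences,
edges connect adjacent alleles, and every phased haplotype is a walk through
the graph. Because adding alleles also adds spurious alternative paths, the
central design question is *which* variants to add. Populations with strong
substructure (cattle breeds are the motivating case) make this concrete: does
a population-specific augmented graph beat a pan-population graph, a
consensus linear reference, or a graph of random variants?

`graphpop` re-creates this entire study design at desk scale on synthetic
data: population simulation, graph construction with allele-frequency
prioritisation, haplotype-aware read simulation, deterministic read mapping
to linear/consensus/graph references with surjection back to linear
coordinates, pileup genotyping, and the evaluation statistics (mapping-error
rates, pseudo-ROC, allelic-ratio bias profiles, genotype concordance).

## The synthetic population model

`generate_reference()` draws an i.i.d. ACGT sequence at a configurable GC
content (default 0.42) and overlays repetitive structure, because on a
featureless random sequence nearly every 150-bp read maps uniquely and
reference structure would be irrelevant. The repeat model (see
`repeat_spec()`) is deliberately simple but captures the two features that
matter for mapping:

* **Interspersed elements**: 8 families of 300-bp elements covering ~18% of
  the genome; each copy is mutated away from its family consensus by a
  per-copy divergence drawn uniformly from 1--8%, emulating the age spectrum
  of retrotransposon copies; 15% of copies are placed as tandem pairs.
* **Segmental duplications**: existing 1.5--5 kb segments re-copied
  elsewhere at 0--2% divergence, covering ~8% of the genome. Because a
  duplication is longer than a sequencing fragment, read pairs falling
  inside cannot be rescued by a uniquely mapping mate; the youngest copies
  are near-identical, and those locus pairs are where mapping errors -- and
  the rescue provided by having the read's alleles in the graph -- actually
  happen, as on real genomes.
* **Low-complexity runs**: 60-bp microsatellite runs (poly-A, AT, CA, AG)
  covering ~2% of the genome, where no reference structure helps.

The repeat mixture was calibrated once against the published statistics of
the cattle experiment this package emulates -- the order of magnitude of the
linear-reference paired-end mapping-error rate (~0.1%), the share of linear
errors attributable to reads carrying non-reference alleles (~29%), and the
share of errors at mapping quality 10 or below (~98%) -- and then frozen; at
the default experiment scale the synthetic values are ~1.5%, ~27% and ~97%.

Both classes are recorded as BED-style annotations, so mapping error rates
can be stratified by region exactly as annotation-based analyses do on real
genomes.

`simulate_population()` places biallelic SNPs and short (< 50 bp) indels at
non-overlapping anchored positions (indel fraction 0.11, the genome-wide
indel/SNP ratio of the motivating bovine panel) and assigns each variant a
frequency class per population from a discrete site-frequency spectrum with
controllable weights. The default singleton weight is 0.14, the proportion
observed in sequenced cattle (versus ~0.23 in humans); the remaining weights
put roughly a third of segregating sites below 5% frequency. A fraction of
variants (default 0.6) belongs to a pool shared across populations with
independently drawn per-population frequencies; the rest are private to one
population. Haplotypes are drawn by scattering the target allele count over
the population's chromosomes -- there is deliberately no linkage
disequilibrium or coalescent realism (a stated non-goal), which means
haplotype-restricted graph indexes are slightly *more* informative on real
data than here, where allele combinations are random.

What passing tests on these data do **not** show: performance on real error
profiles (quality-dependent errors, GC bias), structural variants, or
genomes whose repeat families have realistic length/divergence joint
distributions.

## Graph construction and variant prioritisation

`select_variants()` implements the selection modes: frequency thresholding
(strictly greater than the threshold, so threshold 1 yields an empty set),
count-matching across populations (each population's passing set is
subsampled to the smallest passing count so graphs carry equal information
density), pooled-frequency (pan) selection, random draws ignoring frequency
and phase, personalized sets (exactly one sample's variants), and the empty
set. Private alleles of the read-simulation sample are removed before any
non-personalized selection.

`build_graph()` splits the backbone at allele boundaries and chunks it into
nodes of nominal length 32 bp. The 32-bp default is inferred from the
observable behaviour of the reference toolchain (an empty chromosome graph
has length/32 nodes, rounded down); the final chunk of each segment absorbs
the remainder, so a node may exceed 32 bp by up to 31 -- we prefer matching
the observable node count over a hard length cap, and the remainder rule is
our own choice. SNPs become parallel single-base nodes, insertions extra
nodes between their flanking backbone nodes, deletions bypass edges; the
graph is a DAG whose backbone path spells the reference bit-exactly.
`graph_stats()` reports node/edge counts, the edge-to-node ratio and
(capped) k-mer path counts, with haplotype-restricted counting when walks
are embedded.

## Read simulation

`sim_params()` defaults follow the simulation settings of the study being
emulated: 150-bp reads, 500 +/- 50 bp fragments, substitution rate 0.01 and
indel rate 0.002 per base. The error model details the source setting leaves
open are fixed here for testability: substitutions are uniform over the
three alternative bases, indel errors are single-base with insertion and
deletion equiprobable, and reads are re-trimmed/padded to the nominal
length. Truth coordinates (leftmost reference coordinate of the error-free
source segment, lifted through the haplotype coordinate map) are recorded
before error injection. Fragments are drawn uniformly and in equal numbers
per haplotype; region labels are assigned by the true-origin midpoint.

## Mapping and surjection

The mapper is a deterministic seed-and-extend aligner (seeds k = 21 at
stride 10, banded affine-gap extension with match +1, mismatch -4, gap open
-6, gap extend -1). For graphs, the searchable space is realised as the
backbone plus *alternate-allele contigs*: variants closer than a read length
are clustered, and each cluster contributes one contig per allele
combination -- haplotype-observed combinations when a haplotype index is
supplied (the analogue of GBWT-restricted k-mer paths), enumerated
combinations (capped) otherwise, which is exactly the extra path mass that
makes unphased random-variant graphs ambiguous. Each contig carries an exact
coordinate chain to the reference; surjection is a chain liftover, with
alignments starting inside alternate-allele material assigned to the
preceding backbone coordinate (our convention; the reference toolchain
delegates this to its own surjecter).

Numerical choices worth knowing:

* Candidate loci are clustered from seed-diagonal votes, where a locus's
  votes are the number of *distinct seed offsets* supporting it -- counting
  raw hits would let self-similar low-complexity targets out-vote genuine
  loci.
* Allele-combination contigs of one site are resolved *within* a locus and
  do not consume the candidate-locus budget (8 loci per read), so linear and
  graph mapping explore equally many alternative placements; candidates
  surjecting within 50 bp are one locus.
* `MQ = min(60, 6 * (best - second best))`, 0 on exact ties; ties break to
  the lowest reference position. Paired mates are scored jointly with a
  Normal(500, 50) fragment-length prior.
* The extension band is 12 bp: wide enough for the 1-bp simulated error
  indels and for small panel indels to align as gaps, while longer indels
  soft-clip against a linear reference -- the behaviour that produces
  length-dependent reference bias in linear alignments.

## Genotyping and the bias mechanism

`pileup_and_call()` counts, per site, reads whose projected alignment spells
the full reference or alternate allele span; soft-clipped or partially
spanning reads are uninformative, and there is deliberately no local
realignment or soft-clip rescue. This makes the pileup caller a minimal
analogue of direct-pileup genotyping: against a linear reference, reads
carrying long insertions are clipped and lend no alternate support
(allelic ratio falls with insertion length), while against the graph the
same reads align full-length through the alternate allele and balance is
restored. Genotypes are maximum-likelihood under a binomial model (allele
balance 0.5 for heterozygotes, error 0.01 for homozygotes), and calls are
flagged with the QD > 10, MQ > 40, DP > 25 filter triple.

## Experiment orchestration and problem sizes

`run_experiment()` drives the full design from one `experiment_config()`:
one synthetic genome and panel per configuration, then per replicate a fresh
read simulation and one mapping per configured reference mode, with
replicate r seeded as `base_seed + r`. The desk-scale defaults -- a 200-kb
genome at one variant per 80 bp, three study populations of 20 diploids plus
an outgroup that supplies unphased random variants, 10,000--20,000 read
pairs per cell and ten replicates -- were chosen so that a full graph-type
comparison completes in minutes on one CPU while each cell still counts
hundreds of mis-mapped reads. At this scale the *large* contrasts (informed
graphs versus linear or random references) reproduce cleanly; the *adjacent*
contrasts in the graph-type ordering (personalized versus own-population
versus pan versus across-population) have true effect sizes near the
sampling noise floor, which is why the packaged acceptance checks allow a
small slack (5% of the linear error rate) on adjacent pairs while requiring
the full ordering structure.

`run_bias_experiment()` and `run_genotyping_experiment()` package the two
genotype-level analyses: allelic-ratio profiles by signed variant length
(with a configurable fraction of the sample's alleles left out of the graph,
mirroring sites absent from an augmented reference), and exact genotype
recovery from error-free reads at depth.

## Known limitations

* No linkage disequilibrium, recombination, or realistic SFS shapes beyond
  the class weights; no sex chromosomes or unplaced contigs.
* The mapper emulates seed-and-extend behaviour but not any specific tool's
  mapping-quality calibration; only threshold-based MQ behaviour is
  meaningful.
* Graphs are bubble graphs over a backbone (SNPs and indels < 50 bp); no
  inversions, duplications or translocations.
* The genotype caller is single-sample and pileup-based by design; its QUAL
  model preserves threshold semantics, not any external caller's numbers.

## Reproducing the evaluation

`scripts/acceptance.R --seed <s> --out <path>` regenerates the simulator
calibration quantities (empirical substitution and indel error rates, mean
fragment length) and the graph-mapping allelic-ratio balance at heterozygous
SNPs from scratch, writing them as JSON. The testthat suite contains the
full directional reproductions: the threshold-sweep error decrease, the
graph-type ordering, the bias-profile contrast, oracle equivalences for
every evaluation statistic, and parameter recovery.
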