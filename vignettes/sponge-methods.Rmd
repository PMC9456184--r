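---
title: "Methods: consensus lncRNAs and miRNA-sponge detection"
author: "lncSponge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus lncRNAs and miRNA-sponge detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models the package implements, the defaults it
ships with and why, and the design decisions taken where more than one
reasonable concretization existed. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

# The pipeline and its assumptions

The pipeline asks whether long non-coding RNAs of a blood-feeding
ectoparasite could act as sponges of host miRNAs, using only sequence and
expression evidence. Its stages and their core assumptions:

**Coding/noncoding classification.** A transcript is coding when it has an
open reading frame longer than 50 amino acids (read strictly: a 51-aa
protein qualifies, a 50-aa protein does not) *and* that ORF's translation
hits a reference protein set. ORFs require an `ATG` start and an in-frame
stop; open-ended ORFs are not called, which is conservative but
deterministic. Both strands are scanned by default because de novo
assembled contigs have unknown orientation (`bothStrands = FALSE`
restricts to the forward strand). The homology gate defaults to a
precomputed hit table so that results of an external protein-database
search can be injected; the built-in gate is a Smith–Waterman local
alignment with BLOSUM62, gap open 11 / extend 1, calling a hit at raw
score 60 or more — roughly the score of a conserved ~30-residue block, a
deliberately permissive stand-in for an E-value threshold since the
package does not implement Karlin–Altschul statistics.

The ORF-length accounting follows the invariant
`aaLength = (end - start)/3 - 1` (the encoded protein including the
initiator methionine, excluding the stop), and the strict `> 50 aa` gate
is applied to that quantity.

**lncRNA gate.** Noncoding transcripts of 200–1800 nt, inclusive at both
bounds ("between 200 and 1800" is read inclusively; both bounds are
configurable).

**Consensus clustering.** Greedy incremental clustering with CD-HIT
semantics: sequences sorted by decreasing length (ties by id) join the
first cluster whose *representative* they match at identity ≥ 0.98 and
coverage of the shorter sequence ≥ 0.80; membership is never re-checked
against other members, keeping the algorithm O(n·k) and faithful to the
cited tool. Identity is computed from a global–local alignment of the
shorter sequence against the longer (match +1, mismatch −1, gap −2, free
end gaps on the longer only) as matching columns over the aligned span. An
8-mer prefilter skips alignments that provably cannot reach the identity
threshold; the bound is conservative (validated against filter-off runs in
the tests). A cluster is *consensus-eligible* when it holds at least one
member from the primary source (`MG_SG`, the most stringently filtered
set) and one from a secondary source (`SG` or `WB`). The consensus
transcript is the cluster's longest member of any source (ties by id).
Whether the representative must itself come from the primary source admits
two defensible readings; both are implemented
(`requirePrimaryRepresentative`), with the cluster-level-membership
reading as default. Coding RNAs run through the identical path.

**Expression filter.** Transcripts of the primary source must reach 5 FPKM
in *every* sample of at least one group, where groups are the unfed
condition as a whole and each fed time point separately. FPKM is
`count / (length/1000) / (librarySize/10^6)`.

**Differential expression.** TMM normalization exactly as published
(M-values of library-scaled proportions against the reference sample whose
upper quartile is closest to the mean upper quartile; 30% two-sided trim
on M and 5% on A; precision-weighted mean; factors rescaled to geometric
mean 1 — the implementation matches the reference implementation to
machine precision in the test suite, which keeps the independent
step-by-step oracle honest). The test is the classic exact
negative-binomial test with a single common dispersion: counts are scaled
to a common effective library size (geometric mean of factor × library
size), group sums rounded, and the two-sided p-value sums all conditional
split probabilities no larger than the observed one. Conditioned on the
total, the split law is free of the mean (negative hypergeometric;
binomial in the Poisson limit), which is what makes the test exact without
estimating means. The common dispersion is a method-of-moments estimate:
per transcript `max(0, (s² − m)/m²)` from pooled within-group moments,
median over transcripts with mean above 1 — chosen over likelihood-based
estimators because it is fully specifiable and testable by parameter
recovery. Tagwise shrinkage and GLM variants are out of scope. DE calls
use BH-adjusted p-values at `alpha = 0.05` (there is no single canonical
threshold for such calls; the default is configurable), with `up_fed`/`up_unfed` labels
taken from the fold-change sign (prior count 0.125 per group mean avoids
infinite fold changes on zero groups).

**Target prediction.** The seed stage finds exact reverse complements of
miRNA positions 2–7 on the lncRNA sense strand and classifies upward:
pairing through position 8 gives 7mer-m8, an `A` opposite position 1 gives
7mer-A1, both give 8mer. Overlapping sites at distinct starts are all
counted, because downstream sponge scores are count-based. The
hybridization stage scores a miRanda-style local alignment of the full
miRNA against the site window: Watson–Crick +5, G:U wobble +2, mismatch
−3, gap open −8 / extend −2, with pair scores at seed positions 2–8
doubled (a perfectly paired 22-nt duplex scores 145 = 7×10 + 15×5). Since
pairing is antiparallel, the miRNA 3′ region can only pair lncRNA bases
5′ of the seed site, so the scored window extends 30 nt 5′-ward of the
site. A consensus site needs a 7mer-or-better seed *and* hybridization
score ≥ 70 — the exact score of a perfectly paired seed — so that
seed-perfect sites (8mer, 7mer-m8) pass on their own while 7mer-A1 sites
must earn ≥ 10 points of 3′-supplementary pairing. This seed-plus-hybridization
two-of-two rule is the package's consensus definition; trained
machine-learning site classifiers are deliberately out of scope.

**Null model.** Each null replicate shuffles every lncRNA and re-runs
target prediction with identical parameters. The default shuffle is a
uniform permutation (exact mononucleotide composition preserved),
matching the behaviour of the classic `shuffleseq` control; a
dinucleotide-preserving mode (random Euler path on the de Bruijn
multigraph) is provided because seed-site statistics are sensitive to
dinucleotide content. 19 replicates by default, so the smallest empirical
p is 1/20 = 0.05 under the `(r+1)/(n+1)` estimator, which never returns
zero.

**Sponge candidates.** Three approaches: maximum site count, maximum sites
per kilobase (`count × 1000 / length`), and Apriori itemset mining on the
binarized target matrix (transactions = lncRNAs, items = miRNAs). Default
minimum support is `max(3, 5%` of transactions`)` — a support floor low
enough to see three-lncRNA groups yet above singleton noise; no canonical
value exists, so it is configurable and logged. Itemset significance is the permutation p
against the shuffled null; the final report greedily takes up to three
significant itemsets by ascending p (ties: larger itemsets first, then
higher support, then itemset id) subject to pairwise disjoint supporting
lncRNA sets. Preferring larger itemsets on ties makes the report name the
maximal co-targeting combination rather than one of its (equally
supported) subsets. Ties in the max-count/max-density candidates break
lexicographically by (lncRNA, miRNA). The per-miRNA prioritization
statistic normalizes each target total by the maximum in its set with a
pseudocount of 1 (the raw ratio is undefined at zero) and ranks by
`N_fed/N_unfed`.

**Report.** Percentages are rounded half-up to one decimal (not banker's
rounding), the convention that reproduces dataset-scale figures such as
`deSummary(1110, 3118) = 35.6`. Cross-study overlap uses the union
denominator (Jaccard × 100) as the headline number and reports per-study
denominators alongside, since either convention appears in practice; neither convention is privileged downstream.

# The synthetic-data generator

The generator is first-class, tested code; it defines the conditions under
which the pipeline is validated.

- **Sequence model:** i.i.d. uniform A/C/G/T — the simplest null
  compatible with seed-site statistics. Real transcriptomes have biased
  composition and repeats; passing tests therefore demonstrate correct
  mechanics and calibrated statistics, not performance on real tick data.
- **Clusters:** 60 true clusters, lengths uniform on 200–1200 nt, each
  present in the three sources with probabilities (0.75, 0.6, 0.5) and
  copied with a per-base substitution rate of 0.005. Two independently
  mutated copies then diverge ≈ 1%, leaving a clear margin below the 2%
  identity budget of the 0.98 clustering threshold. Planted ORF
  boundaries and planted seed sites are shielded from substitution (and
  substitutions creating in-frame stops inside a planted ORF are
  reverted) so that planted structure survives in every copy; coordinates
  are stable because only substitutions, never indels, are introduced.
- **Coding clusters** (35%) carry a forward-frame ORF of 52–120 aa whose
  translation seeds the reference protein set; noncoding clusters are
  rejection-sampled until no frame contains an ORF of ≥ 50 aa, so the
  classification truth is unambiguous.
- **Counts:** negative binomial with dispersion 0.1, lognormal baseline
  means (median 80), per-sample library factors log-uniform on [0.5, 2],
  five replicates per (tissue, condition) group; 25% of clusters get a
  planted fed/unfed log2 fold change of ±2, shared across tissues.
- **Sponge plan:** three disjoint groups of three miRNAs, each
  co-targeting three lncRNAs with 3 planted 8mer sites per (miRNA,
  lncRNA), plus one high-count sponge with 10 sites for a single miRNA.
  Planted clusters are forced to be present in the primary and one
  secondary source so that the sponge ground truth survives consensus
  selection. Sites are planted at uniformly drawn non-overlapping
  positions via the order-statistics construction, which succeeds
  whenever the sites fit and fails loudly otherwise.

Features of real data the generator does not emulate: splice isoforms,
composition bias and repeats, read-level noise (counts are drawn at the
transcript level, as the pipeline consumes expected counts), 3′-UTR
context effects on targeting, and pathogen-infection covariates.

# Numerical choices and degenerate inputs

- Empirical p-values use `(r+1)/(n+1)`; BH adjustment uses the standard
  step-up with monotonicity enforcement.
- Exact-test p-values are clamped to 1 (tie tolerance 1e−8 on log
  probabilities can otherwise overshoot by rounding); totals of zero give
  p = 1.
- All randomness flows from explicit seeds; every seeded operation
  restores the caller's RNG state. Stage seeds derive from the master
  seed with fixed per-stage offsets so stages can be rerun independently.
- Dinucleotide shuffling resamples the last-exit edges until they form an
  arborescence into the terminal vertex (bounded retries); homopolymers
  and length-1 sequences are their own shuffle.
- Empty inputs return typed empty results (empty cluster tables, empty
  site tables with a warning for empty miRNA/lncRNA sets); an all-zero
  target matrix yields no max-count/density candidate, with a warning.

# Problem sizes used in validation

The suite validates oracle equivalence on 100 random 1–2 kb sequences
(ORF scan), 10 random miRNA/lncRNA pairs (seed scan), 10-miRNA × 40-lncRNA
binary matrices against exhaustive enumeration (Apriori), and fixed count
matrices for TMM/BH. Calibration uses 2000-transcript null simulations at
dispersion 0.1 (4 vs 4) and 1000-transcript recovery at dispersion 0.2
(5 vs 5). Planted-structure recovery runs the full pipeline on the default
60-cluster study (~120 transcripts) with 19 null replicates, and the
null-sanity check uses 20 replicate mini-studies. These sizes were chosen
as the smallest instances that still give the statistics meaningful
resolution.

# Known limitations

- The hybridization score is an alignment heuristic, not a thermodynamic
  ΔG; conservation and accessibility are out of scope.
- A single common dispersion is deliberately simple; strongly
  heteroskedastic data would warrant tagwise shrinkage in an external
  tool.
- The homology gate's raw-score threshold is not an E-value; for real
  data, inject a hit table from a proper database search.
- Consensus clustering checks candidates against representatives only
  (true greedy semantics); pathological chains of borderline similarity
  can split clusters that all-pairs methods would merge.
- KEGG/pathway enrichment of the prioritized miRNAs is intentionally not
  performed: the pipeline exports ranked miRNA lists for external
  enrichment services.
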