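---
title: "Methods: integrating small-RNA differential expression with substitution-line QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating small-RNA differential expression with substitution-line QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirqtl)
```

# The problem

Heat stress at the rice flowering stage sterilises spikelets, and breeding
for tolerance needs both loci (QTLs) and candidate regulators (miRNAs and
their target genes). `mirqtl` implements an integrative funnel that narrows
a genome-wide list of heat-responsive miRNAs down to a handful of
candidates: miRNAs must be differentially expressed under heat, their
predicted target genes must fall inside heat-tolerance QTL intervals mapped
on a chromosome single-segment substitution line (SSSL) panel, and the
target's expression must be anti-correlated with its miRNA across
conditions.

This vignette documents the models, the parameters that matter, and the
design decisions taken where the underlying procedures left choices open.

# Heat-tolerance phenotyping

Per plant, spikelet fertility is `SFP = FSP / TSP * 100` (percent of
spikelets filled), summarised as mean and sample standard deviation over
replicate plants (ten per group in the reference design). The heat
tolerance index is

\[ HI = \frac{\text{heat-stressed } SFP}{\text{control } SFP}, \]

so `HI = 1` means no fertility loss under stress. `heat_tolerance_index()`
uses the **ratio of group means** by default because that is the arithmetic
that reproduces published summary values exactly (55.8/66.4 gives 0.84); a
mean-of-per-plant-ratios mode exists for paired uncertainty estimation.
Reported `HI_sd` for the ratio-of-means mode is delta-method propagated
from the two group standard errors, and the `±` spread of the reference
table is interpreted as a standard deviation (its definition is not
stated in the source material; the label makes the assumption explicit).

# DE-miRNA calling from pooled count libraries

The design is 12 libraries: two genotypes (heat-tolerant donor GXN,
heat-sensitive recurrent parent HJX) × control/heat × 1, 6, 24 h of stress,
with biological replicates pooled into each library before sequencing.

1. **Confirmation**: a miRNA is kept when its raw count reaches 10 reads in
   at least one library (inclusive threshold).
2. **Normalisation**: `TPM = count / library_total * 1e6`. The library
   total defaults to the column sum of the confirmed matrix; when the
   metadata carries a `total_reads` column (total sequenced reads), the
   flag `total_from = "meta"` uses it instead. Both behaviours exist
   because "total reads" is ambiguous once a matrix has been subset.
3. **Fold change**: `log2((TPM_heat + c)/(TPM_control + c))` with a
   pseudo-count `c = 0.25` TPM. The source procedure states no
   pseudo-count; 0.25 is small relative to the 10-read confirmation floor
   and keeps zero-TPM ratios finite. It is configurable.
4. **Testing**: Fisher's exact test on the 2×2 table of *raw counts*
   (miRNA count vs rest-of-library, heat row vs control row). Exact tests
   need integers, so TPM feeds only the fold change. The two-sided p-value
   uses point-probability ordering (the sum of all tables, at fixed
   margins, whose probability does not exceed the observed one; ties
   included with a 1e-7 relative guard).
5. **FDR**: Benjamini–Hochberg within each contrast, matching
   per-comparison DE lists.
6. **Gates**: DE requires `|log2FC| >= 1`, `p <= 0.05` and `FDR <= 0.05`
   simultaneously; otherwise the call is `ns`.

DE miRNAs are then classified into four genotype categories
(co-regulated same direction, co-regulated opposite, GXN-specific,
HJX-specific). A miRNA DE at several timepoints within one genotype gets
that genotype's majority sign; an exact up/down tie is treated as
opposite-capable, which is the conservative reading for the "opposite
patterns" category.

**A calibration caveat that shapes the tests.** Fisher's exact test on one
pooled library per condition models *sampling* noise only. Our null
simulations at the generator's default biological overdispersion
(`dispersion = 0.1`, variance `mu + 0.1 mu^2`) show ~13–14% of truly null,
well-expressed miRNAs passing all three gates — the well-known
anti-conservativeness of exact tests applied across biological variation,
and the reason replicate-aware count models exist. The package therefore
calibrates the false-positive property in the Poisson limit
(`dispersion = 0`), i.e. under the sampling model the test itself assumes;
there the empirical false-positive fraction is far below 0.05. Users should
read single-library Fisher p-values as measures of sampling surprise, not
of biological reproducibility.

# SSSL QTL mapping

Each SSSL carries exactly one donor segment in an otherwise
recurrent-parent genome, so a phenotypic difference from the parent maps a
QTL to that segment without interval-mapping machinery.

- **Segment geometry** (`segment_interval()`): between two donor-type
  markers the chromosome is 100% donor (DD), between donor and recipient
  markers 50% (DR), so segment length = DD core span + half of each DR
  flank. When a donor run touches a terminal marker no recipient marker
  bounds it; the interval extends to the chromosome end and, by default,
  that terminal span counts as fully donor (`terminal = "full"`,
  matching interval tables that end in "End"); `terminal = "half"`
  treats it like a DR flank. Both conventions are implemented because the
  original length calculation does not state the terminal rule.
- **Declaration** (`qtl_test()`): two-sided two-sample t-test of line
  versus parent replicates, pooled variance by default (the classical
  equal-variance form; `welch = TRUE` available), declared at raw
  `p < 0.05`. No multiple-testing correction is applied across the panel
  by default, matching the single-line declaration rule; an optional BH
  mode exists. With ~19 effect-free lines per screen this rule implies
  roughly one false declaration per screen in expectation — an inherent
  property of the per-line rule, demonstrated by the package's null
  simulations, not a defect of the implementation.
- **Effects** (`additive_effect()`): `a = (line mean − parent mean)/2`
  (two donor allele doses per segment) and `a% = a / parent mean × 100`.
  The identity `a% × parent mean / 100 = a` holds to numerical precision
  on every emitted result.
- The replicate unit is whatever the phenotype table provides — per-plant
  HI values or per-experiment means — since the declaration rule only
  needs exchangeable replicates; the reference design used three
  independent experiments of ten plants per group.

# Target scoring

The in-repo scorer stands in for external plant target predictors, with
the scheme fully specified rather than inherited from a binary: penalties
mismatch 1.0, G:U wobble 0.5, gap 2.0, doubled within miRNA positions
2–13; at most one gap per site and no gap at or before miRNA position 10;
report sites with total penalty ≤ 3.0 (a strict mode at ≤ 2.0 mirrors the
tighter cutoff of the classical tools). T and U are equivalent on input.

The search is exhaustive: every window of every transcript, every allowed
single-gap placement (an unpaired miRNA base, or one bulged target base),
no heuristics. Overlapping candidate alignments of one locus are resolved
to the best-scoring one (ties: ungapped first, then leftmost), so a
reported "site" is a distinct locus; this is what makes "a perfect planted
site yields exactly one hit" well-defined, since gapped shadows of the
same locus would otherwise be reported alongside it. An independent naive
scorer in the test suite checks the implementation window by window.

The predicted cleavage position is the transcript base pairing miRNA
nucleotide 10 (0-based; the slicing bond is immediately 5' of it),
following the realised pairing in gapped alignments.

# Integration and ranking

Target genes of DE miRNAs are intersected with QTL intervals under
half-open interval arithmetic in megabases; the default emits a pair on
any overlap (≥ 1 bp), with a containment mode available since the original
criterion ("located in the QTL regions") does not specify partial-overlap
handling. Candidates are then filtered and ranked: genes whose mean
abundance falls below 1 TPM are dropped as "not expressed" (the exclusion
threshold is not stated in the source material; 1 TPM is the conventional
floor and is configurable), pairs with expression correlation above 0 are
dropped, and survivors are ordered by Pearson anticorrelation of log2
relative-to-control profiles over the (genotype, timepoint) cells, ties
broken by complementarity score.

# The synthetic-data generator

`simulate_all()` generates every input the pipeline reads; its defaults
*are* the study conditions, and the tests run against them.

- **Counts**: log-normal baseline abundances scaled to one million reads
  per library, negative-binomial observation noise with variance
  `mu + phi mu^2`, `phi = 0.1` by default (a standard overdispersed model
  for pooled small-RNA libraries; `phi = 0` gives the Poisson limit used
  for calibration checks). Twenty spiked heat-responsive miRNAs at
  `|log2FC| = 2`, 75% down-regulated (echoing the observed dominance of
  down-regulation under heat), drawn from the well-expressed fraction
  (baseline expectation ≥ 50 reads, as real DE miRNAs are confirmed,
  well-expressed sequences), responding at all three timepoints of their
  assigned genotype (a persistent response pattern). Power is assessed as
  a correct-sign DE call in at least one spiked contrast. Because spiking
  changes library composition, realised TPM fold changes are slightly
  compressed toward zero relative to the planted absolute fold change;
  the near-balanced read mass of the default up/down mix keeps this
  compression small.
- **Panel**: 23 lines over 12 rice-sized chromosomes (lengths 23–43 Mb),
  8 evenly spaced markers per chromosome, donor runs of three markers
  tiling the genome. Four planted QTLs on chromosomes 3, 6, 8 and 12 with
  additive effects 3.59, 5.60, 9.24 and 2.72 on a percent-scale
  stress-fertility phenotype (parent mean 18.5 — the value implied by the
  published effect/percentage pairs), replicate noise sd 1.5 with ten
  replicates per line, chosen so the largest effect is detected
  essentially always and the smallest with high but not perfect
  reliability.
- **Annotation/targets**: 60 decoy genes placed uniformly; 8 true target
  genes assigned to distinct spiked miRNAs, each transcript carrying an
  embedded site (reverse complement of the miRNA with 0–2 planted
  mismatches outside the seed-weighted region). Six of the eight sit
  inside planted QTL intervals, two outside; two in-QTL targets are
  simulated as not expressed, exercising the expression filter the same
  way the original analysis excluded unexpressed candidates. Expressed
  true targets get expression profiles anti-correlated with their miRNA's
  spike profile (noise sd 0.2); decoys get independent noise.

All generators are pure functions of `(config, seed)`; a fixed seed gives
byte-identical outputs.

**What the generator does not emulate**: read-level artefacts (adapter
trimming, multimapping, isomiRs), linkage disequilibrium and segment
overlap structure of a real SSSL library, correlated gene expression, or
annotation errors. Passing tests therefore demonstrate that the pipeline's
logic recovers planted signal under its own statistical assumptions — not
that those assumptions hold for any particular real data set.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: 1000-miRNA × 20-run null
simulations and the 200-miRNA default fixture for DE calibration and
power; 100 simulated panels for effect-estimate accuracy and 10 panels for
exact-recovery screening; 100 random miRNA/transcript pairs (transcripts
up to a few hundred nt) for scorer/oracle equivalence; and the full
default fixture for the end-to-end funnel. These sizes were chosen to give
stable Monte-Carlo estimates at interactive runtimes.

Numerical conventions: internal genome coordinates are 0-based half-open
megabases (GFF3 input converted from 1-based closed, BED taken as is);
Fisher ties are included via a 1e-7 relative guard; degenerate t-tests on
two constant equal samples return `p = 1`; zero-variance expression
profiles yield an undefined correlation flag rather than a number; BH on
an empty vector returns an empty vector.

# Known limitations

- Single-library Fisher testing is anti-conservative under biological
  overdispersion (see above); treat DE lists from unreplicated designs as
  screening output.
- The raw per-line QTL declaration rule implies ~1 false declaration per
  23-line screen at `alpha = 0.05`; the package reports what the rule
  declares and leaves correction off by default deliberately.
- The complementarity scheme is a documented reconstruction; scores are
  scheme-dependent and not comparable across schemes, which is why output
  carries the scheme parameters.
- QTL intervals from terminal donor runs depend on the chosen terminal
  convention; both are implemented and labelled.
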