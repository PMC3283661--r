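---
title: "Methods: staged SNP filtering, cluster-based array design and trio phasing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged SNP filtering, cluster-based array design and trio phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures behind
`snparraydesign`, the reasoning behind its defaults, and what its
synthetic-data verification does and does not demonstrate.

## The problem

A genotyping array is built in three steps: *detection* of a large SNP
pool by resequencing a diversity panel at low coverage, *validation* of
a small subset on a cheap assay to calibrate filtering thresholds, and
*final choice* of array content. With a detection pool 250 times larger
than the array, filtering can be fastidious: the goal is not to keep
every true SNP but to keep only SNPs that will convert into working,
informative assays across breeding germplasm. The package implements
that cascade for a diploid crop with a chromosome-scale assembly and a
reference genetic map — the setting of the apple 8K array, whose
conditions (27 detection accessions, one candidate per 288 bp, 29%
exon space, ~5× per-accession coverage, 2.24 cM/Mb) are the package
defaults.

## Stage 1: hard rejection rules

Each candidate carries per-accession reference/alternate read counts
and phred-scale allele qualities. Eight rules are evaluated
independently (no short-circuiting, so per-rule tallies are complete);
a candidate is kept only if it violates none.

| rule | rejects when | default |
|---|---|---|
| 1 | call within the first/last `end_margin` bases of an LG | 60 bp |
| 2 | non-ACGT reference base at the call or within `ambiguity_window` | 60 bp |
| 3 | another candidate within `adjacent_window` (inclusive) | 50 bp |
| 4 | mean copy number over ±`cn_flank` strictly above `cn_max` | 60 bp, 2.0 |
| 5 | best observed quality of a supported allele strictly below `qual_min` | 20 |
| 6 | ≥ `accession_fraction` of accessions-with-reads carry an allele with < `min_reads_per_allele` reads | 0.5, 2 |
| 7 | either allele's summed depth strictly above mean + `depth_sd_mult`·SD of total depth over **all** candidates | 3 |
| 8 | A/T or C/G transversion (needs two Infinium II bead types) | on |

Readings that the rule wording leaves open, fixed here and
configurable: comparisons phrased "less/more/greater than" are strict
while "within"/"at least" are inclusive; rule 5 aggregates each
allele's quality as the best (max) across accessions, so one
well-supported accession suffices; rule 6 counts an accession as
failing when *any* allele it shows reads for is below the two-read
minimum, and its denominator is accessions with any reads; rule 7 uses
the **population** SD of total (both-allele, all-accession) depth
computed once over the full pre-filter candidate set, and tests each
allele's sum separately; rule 4 takes the length-weighted mean of the
copy-number track over the flank with untracked positions counting as
copy 1, since the flank width is not otherwise specified we reuse the
60 bp ambiguity window.

## Stage 2: exon space

The exon space is the union of gene-model exons and cDNA alignment
blocks, merged per linkage group with abutting intervals joined
(`IRanges::reduce` under the hood). Intervals are 1-based inclusive on
both ends; BED input/output converts from/to 0-based half-open. A SNP
is exonic iff its position lies in the merged space. Membership is
verified in the tests against brute-force interval scans.

## Stage 3: focal points and clusters

Primary anchors (previously validated, genetically mapped SNPs) all
become focal points. Genetic gaps above `gap_threshold_cM` (3 cM) are
filled with physically placed secondary anchors whose cM positions are
interpolated piecewise-linearly between primaries (clamped at the LG
ends): the anchor closest to the gap midpoint is added first, then
sub-gaps are processed recursively until no gap exceeds the threshold
or anchors run out; unfillable gaps and LG ends without an anchor
within `end_window` (200 kb) are *reported*, never guessed. Midpoint-
first filling and the lower-position tie-break are this package's
choices; only the gap counts, not the order, are observable in the
published design.

Within ±`window_halfwidth` (50 kb) of each focal point, candidates are
binned by MAF — bins labelled 0.1…0.5 covering 0.01–0.1, 0.101–0.2,
and so on, treated as half-open at 3-decimal precision; MAF < 0.01 is
unbinnable and excluded — and up to `per_bin` (2) SNPs per bin are
selected subject to `min_spacing` (2 kb, pairwise, including the focal
SNP) and `cluster_max` (10, counting the focal SNP). Two decisions
matter here:

* **Only an anchor that is itself an assayed SNP occupies a cluster
  slot and constrains spacing** (`focal_is_snp`, default true for
  GDsnp-type anchors). Secondary anchors place no probe, so they
  neither consume a slot nor repel members.
* **Exact search on small windows, greedy beyond.** The published
  procedure says two SNPs were chosen per bin but not how; choices
  interact through the spacing constraint, so a greedy rule can be
  suboptimal. With ≤ 12 window candidates the package enumerates all
  subsets and maximizes (member count, then number of MAF bins
  represented, then minimum pairwise distance, then the
  lexicographically smallest position set — fully deterministic).
  Larger windows use a deterministic greedy rule: bins in descending
  label order; within a bin the candidate maximizing distance to the
  already-selected set, ties broken by higher design score, then lower
  position. In dense windows the greedy rule virtually always fills
  the cluster, where it is trivially optimal in count.

Candidate-gene clusters relax the 2 kb rule: up to `gene_max_snps` (4)
SNPs per gene are chosen to maximize the minimum pairwise distance —
exhaustively over all C(n, k) subsets for genes with ≤ 20 SNPs, by
farthest-point greedy beyond. Finally SNPs with a manufacturability
(ADT) score strictly below 0.7 are discarded (a missing score is an
error, not a default), and the manifest is assembled with
de-duplication by genomic position under the source precedence
GDsnp > focal_window > candidate_gene > validated. Stage 3 contains no
randomness: identical inputs give byte-identical manifests.

## Validation panel and assay classification

The even-spread selector places grid points per LG — one at each end
(within 200 kb) plus interior points — with per-LG counts apportioned
by physical length (largest remainder) so the total matches `n_even`;
the nearest unclaimed SNP to each grid point is taken, and ends
without any SNP in the window are reported and dropped. Region-dense
selection minimizes the summed squared grid-to-SNP distance
(exhaustively for ≤ 12 candidates, else nearest-per-grid-point).
Accession-specific SNPs are those whose minor allele (smaller summed
read count; ties to the alternate allele) is seen in exactly one
accession.

Assay results are classified per SNP over QC-passing samples (call
rate > 0.8 and GC score > 0.5, strict): *failed* below a 0.5 call
rate; *monomorphic* when MAF < 0.05 **and** heterozygote frequency
< 0.1; *polymorphic with low MAF* when polymorphic but MAF < 0.05;
*polymorphic* otherwise. A structural note: allele-count MAF is always
at least half the heterozygote frequency, so at these exact thresholds
the low-MAF-polymorphic class cannot be populated by assay MAF alone —
it becomes meaningful when the MAF used for stratification comes from
the detection panel, or when `ab_freq_min` is set above
`2 * maf_low`. The classifier implements the assay-MAF definition with
both thresholds configurable.

## Array evaluation

Samples with p50GC strictly below 0.54 are removed (equality is
retained, following the stated removal rule "p50GC < 0.54"). SNPs with
a GenTrain-like score strictly above 0.6 are retained; scores in
[0.3, 0.6] are kept but flagged for review — the published workflow
re-clustered these by eye, which is not reproducible, so the flag is
the machine-readable substitute; lower or missing scores fail. SNPs
with more than 20 missing calls among passing samples are flagged. A
SNP is polymorphic iff at least two genotype classes are observed and
MAF > 0; *high quality* additionally requires MAF > 0.05, call rate
> 0.95 and mean 50% GC > 0.4 (all strict). "Successful beadtype" is
operationalized as any non-failed SNP. Percentages are displayed
half-up (1 dp for the summary tables, 2 dp for classification
proportions) with raw counts always emitted alongside; display
rounding is half-away-from-zero, not banker's.

## Trio phasing and recombination

Clusters span ≤ ~100 kb — an essentially non-recombining physical
distance at ~2 cM/Mb — so child haplotypes are modelled as whole-
cluster copies of parental haplotypes. With A/B-coded calls, each site
independently constrains the four parental slots (father transmitted/
untransmitted, mother transmitted/untransmitted); the per-site solution
sets are enumerated exactly and combined. Missing calls are wildcards.
If every site has a single solution the configuration is unique;
otherwise the combination minimizing the number of distinct haplotypes
is returned (ties by lexicographic order), slots that differ across
solutions are masked with dots, and the cluster is flagged ambiguous.
The canonical unresolvable pattern is father, mother and child all
heterozygous at a site — enumeration shows the child may have received
either parent's either allele, and no minimization can break the tie.
Haplotypes are labelled H1, H2, … in order of first appearance walking
father, mother, then child, which makes labels stable across reruns.

Tracking a crossover between clusters requires knowing which parental
chromosome each cluster haplotype belongs to (the parental linkage
phase). The package takes that phase as an input — the simulator
ledgers it, and in practice it comes from a linkage map or multi-
sibling phasing. Without it, minimum-switch parsimony over a single
trio is degenerate (any assignment achieves zero switches), so the
detector then reports no events and marks the result
`method = "parsimony"`. Ambiguous clusters and clusters where the
parent is homozygous never generate events; events are reported
between consecutive informative clusters.

## The synthetic-data generator

The generator emulates the study conditions end to end: random ACGT
linkage groups with planted ambiguity sites; exon intervals laid down
by an alternating length/gap walk calibrated so coverage lands on the
configured exon fraction (0.29); a copy-number track with occasional
high-copy segments; primary anchors every ~1 cM with cM proportional
to physical position and secondary anchors between them; founder
allele frequencies uniform on the binnable range [0.01, 0.5] so every
MAF bin is populated; diploid genotypes per accession; per-accession
Poisson read depth split binomially between alleles with read error;
and array runs that drop founder haplotypes through a pedigree with
crossovers at the map rate, plus configurable assay failure and forced-
monomorphic classes and quality-score distributions. All randomness
flows from one integer seed through R's RNG; outputs are byte-identical
across runs and platforms.

Two deliberate departures from a purely generative model keep the
truth ledger exact. First, a configurable fraction of candidates
receives exactly one injected rule violation (relocated into an end
margin, next to an ambiguity site, into a high-copy segment, paired 30
bp apart, quality-lowered, support-thinned, or depth-inflated), each
recorded in the ledger. Second, the remaining candidates are made
violation-free *by construction*: single-read allele support is topped
up to the two-read minimum and per-allele depth sums are trimmed back
below the outlier threshold, deterministically. Without the repair,
low-coverage heterozygotes would stochastically trip the read-support
rule and the ledger would no longer be the exact truth set; the cost
is a slight upward bias (~3%) in mean depth, which the calibration
test acknowledges.

What passing tests therefore show: the filters implement their
definitions exactly (100% precision/recall against injections), the
selectors are optimal for their stated objectives on enumerable
windows, and phasing recovers simulated truth wherever it is uniquely
determined. What they do not show: performance on real data — the
generator has no linkage disequilibrium, no alignment artefacts, no
paralogy beyond the toy copy-number track, independent sites rather
than realistic haplotype structure, and uniform rather than empirical
MAF and quality-score spectra.

## Numerical and reporting choices

Published-table arithmetic is reproduced by `consistency_checks()`
from a data file of counts, keeping the reference values out of the
code: per-LG SNP spacing uses truncating (floor) division — the
printed 350 for 350.93 forces that reading — while percentages and
ratios round half-up (1 dp). Two printed percentages do not reproduce
from their own printed numerator and denominator at any standard
rounding: the 19.5% Stage 1 pass rate (2,113,120 / 10,915,756 =
19.4%) and the 79.2% pseudo-testcross share (2,223 / 2,810 = 79.1%);
both are excluded from the machine checks. The evaluation summary's
totals row likewise follows the published table's cluster recount
(1,270 of 1,355 = 93.7%) rather than the accompanying text's 1,190,
which is inconsistent with its own percentage; the package always
reports its own recount on its own data.

Degenerate inputs fail loudly rather than defaulting: fewer than two
candidates for depth statistics, missing ADT scores at the score
filter, all-missing calls at MAF computation, missing parental calls
at segregation typing, Mendelian inconsistency at phasing (naming the
SNP), division by zero in a consistency check (explicit undefined
result), and zero-cluster linkage groups in summaries (NA, not an
error).

## Problem sizes used in verification

The shipped tests and the acceptance script run at sizes chosen to
keep full verification in about a minute while preserving every
structural feature (LG ends, map gaps, clusters, pedigrees):
rule-injection recovery on a 2 × 300 kb genome (~2,050 candidates, 27
accessions), exon-space agreement on 500 intervals × 10,000 probes,
selection optimality on 200 random ≤ 12-candidate windows, gene
spacing on 40 genes of 5–20 SNPs, phasing on 500 trios of 4–10-SNP
clusters plus 60 nine-cluster trios with injected crossovers, MAF
coverage on 4 × 1,000 replicates of 148 samples, and an end-to-end
smoke run on the full default 17 × 1 Mb genome (~59,000 candidates).

## Known limitations

* The cluster selector's greedy path (windows > 12 candidates) is not
  guaranteed optimal; the exact path bounds the enumeration cost.
* Phasing enumerates haplotype-minimization combinations up to a cap
  (4,096); beyond it, ambiguous clusters fall back to a deterministic
  representative and remain flagged.
* Recombination detection needs an external parental phase; it will
  silently find nothing under single-trio parsimony, by design.
* The GoldenGate classifier cannot stratify by detection-panel MAF
  unless that MAF is supplied alongside the matrix (see the structural
  note above).
* Genetic-map handling assumes monotone cM along each LG and linear
  interpolation between primary anchors.
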