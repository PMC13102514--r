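---
title: "Methods and design of t2tkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of t2tkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

t2tkit packages the comparative-genomics computations that become
possible once a plant genome is assembled telomere-to-telomere:
delineating telomeres and centromeric satellite arrays, detecting
inversions between two closely related assemblies, genotyping an
inversion across a resequenced population, and measuring the
population-genetic and repeat-landscape signals associated with it. This
vignette explains the models and estimators, the synthetic-data
generator that stands in for real data in all tests, the tunable
parameters, and the numerical design choices.

All genomic coordinates in the package are 0-based and half-open (the
BED convention); VCF positions are converted on read and write. Interval
algebra (merge, intersect, subtract, covered length) is delegated to
IRanges behind a small data-frame interface, so every module shares one
coordinate convention.

## Telomere detection

`find_telomeres()` looks for maximal tandem runs of the telomere motif —
`CCCTAAA` at 5' ends and its reverse complement `TTTAGGG` at 3' ends, the
canonical plant repeat. A run qualifies if it has at least `min_copies`
exact copies (default 4) and lies within `terminal_window` (default
10 kb) of the respective chromosome end; at most one hit per end is
reported, the qualifying run closest to that end. The two thresholds are
exposed because published telomere spans vary over two orders of
magnitude while the run/terminality criteria behind them are rarely
stated. The detector is strand-symmetric: reverse-complementing a
chromosome swaps 5'/3' hits with mirrored coordinates, and the test
suite asserts exactly that.

Partial or degenerate motif copies are not chained into runs; they
simply terminate a run. With the default minimum of four copies this
makes the detector conservative about isolated degenerate repeats while
leaving real terminal arrays (tens to thousands of copies) untouched.

## Satellite scanning and monomer statistics

`scan_satellite()` reports non-overlapping monomer-sized hits tiling
each array, in both orientations, keeping hits with identity at or above
`min_identity` (default 0.90, the conventional threshold for
centromeric satellite searches). Candidate identity is computed
gap-free: the monomer is laid against the sequence at a candidate start
and identity is `(m - mismatches) / m`. Satellite monomer copies diverge
predominantly by substitution; a copy with a large indel falls below the
threshold rather than being rescued by a gapped alignment. This choice
keeps the exhaustive mode (`mode = "exact"`, every start position
evaluated — the reference implementation for sequences up to ~50 kb) and
the default seeded mode (exact k-mer seeds every 31 bp, 13-mers, then
scoring only at seeded candidates) in exact agreement, which the test
suite checks on simulated arrays. Hits are tiled greedily by descending
identity with ties broken by leftmost start, which recovers the true
copy register on arrays because every in-register copy outranks its
shifted shadows.

Monomer consensus (`build_consensus()`) is a star alignment: a medoid is
chosen from a deterministic subsample by mean pairwise identity, every
monomer is globally aligned to it, bases are projected onto medoid
columns (insertions relative to the medoid are dropped), and each column
takes the majority base with ties resolved in the fixed order
A < C < G < T; gap-majority columns are dropped. This is deterministic
and exact for the ≤ 5%-divergent monomers it is meant for; it is not a
general MSA and inputs whose lengths differ by more than 50% are
rejected with a suggestion to split the class first.

`count_variants()` counts aligned columns with differing bases plus one
per gap opening, so a 2-bp deletion plus a substitution counts as two
variants. `pairwise_identity()` is matches over alignment columns of a
global Needleman–Wunsch alignment (match +1, mismatch −1, gap −1 per
base). `similarity_classes()` summarises pairwise identity within three
strata — same chromosome, different chromosomes of the same genome,
different genomes — after proportional-by-chromosome subsampling to a
cap of 1800 monomers under a fixed seed, scoring a bounded number of
random pairs per stratum.

## Centromere delineation, arm ratios, repositioning

`delineate_centromere()` merges satellite hits separated by less than
`merge_gap` (default 50 kb) into arrays and declares the array
overlapping the densest tandem-repeat window the centromere
("array-anchored"). Chromosomes without satellite hits fall back to the
maximal contiguous run of windows with tandem-repeat density at least
`min_density` (default 0.5, 100-kb windows), mirroring how centromeres
are inferred on chromosomes lacking an intact array
("density-inferred"); chromosomes with neither signal are reported
undetermined rather than erroring. The three parameters replace the
manual boundary curation that genome papers describe but do not
formalise; they are reported in the output so a boundary is always
traceable to its settings. One centromere per chromosome is enforced
(monocentric assumption).

`arm_ratio()` measures both arms from the chromosome ends to the
centromere edges and reports long/short (≥ 1, infinite for telocentric).
`detect_repositioning()` projects the genome-A centromere midpoint into
genome B by linear interpolation between the nearest flanking syntenic
anchors and calls "repositioned" when the projection lands outside the
genome-B centromere extended by a threshold (default 1 Mb — there is no
established numeric criterion, so the threshold is a flag and part of
the output). An inversion call overlapping the projection path is
attached to the call, since centromere shifts and pericentric inversions
co-occur.

## Inversion detection and breakpoints

Syntenic anchors (gene pairs with query and target coordinates) carry an
orientation, either given or inferred from the sign of the
target-coordinate difference to the next anchor. `detect_inversions()`
finds maximal runs of at least `min_anchors` (default 5) reverse
anchors, tolerating up to `max_noise` (default 2) interleaved discordant
anchors between consecutive reverse anchors; longer discordant
stretches split runs. This replaces the visual identification of
"funnel-shaped" dot-plot patterns with an explicit, testable rule; a
brute-force run enumerator in the test suite checks it on random maps.
Call bounds span the first to last reverse anchor, so recovered bounds
are accurate to one anchor spacing by construction — the resolution limit
of any gene-anchor method.

`define_breakpoints()` places a `flank` window (default 40 kb) extending
*outward* from each inversion edge, clipped at chromosome ends with the
clipping recorded. The flanking rule is ambiguous in the field between
outward and centered windows; outward is the default because breakpoint
repeats of interest lie in the sequence the inversion joins, and
`centered = TRUE` provides the alternative.

## Inversion genotyping from coverage and PCA

An accession aligned to the reference carrying one arrangement shows
coverage voids around the breakpoints of the other arrangement.
`covered_fraction()` computes breadth — the fraction of bases at depth ≥
`min_depth` (default 1) — over the inversion, weighting partial bins by
overlap, and `genotype_by_coverage()` calls reference iff breadth
strictly exceeds 0.94, so a breadth of exactly 0.94 is an inverted
call. Breadth at depth ≥ 1 is used rather than mean depth because voids,
not dosage, are the signal; the depth floor is a parameter.

`pca_genotype()` centers and scales the inversion-region genotype
matrix (zero-variance sites dropped, missing genotypes mean-imputed),
takes PC1, and partitions accessions by exact 1-D two-means (all split
points of the sorted scores evaluated — deterministic, unlike iterative
k-means). Cluster labels are oriented by maximum agreement with the
coverage calls when available, otherwise the minority cluster is
labelled inverted. `reconcile_genotypes()` passes concordant calls
through and resolves discordance in favour of the coverage call with an
explicit conflict flag — replacing manual alignment-browser arbitration
with a recorded decision — and reports per-group carrier frequencies of
the final calls.

## Population genetics

Hard filtering follows the standard GATK-style disjunction: a site is
removed when any of QD < 2, QUAL < 30, SOR > 3, FS > 60, MQ < 40,
MQRankSum ≤ −12.5, ReadPosRankSum ≤ −8 fires; missing annotations never
fire a criterion, and per-criterion removal counts are returned. The
rank-sum thresholds deserve a note: pipelines sometimes print them
without the minus sign, a literal reading of which would remove nearly
every variant; the defaults here use the conventional negative bounds,
and any other reading is available by passing a modified threshold list.
Site filtering keeps MAF ≥ 0.03 (inclusive, computed over non-missing
alleles) and missingness ≤ 0.1.

Windowed diversity uses the unbiased per-site estimator
π_site = 2·c_ref·c_alt / (n·(n−1)) over non-missing allele counts,
summed per 50-kb window and divided by the window length (monomorphic
bases contribute zero) — the convention of the standard VCF tooling; a
`denominator = "sites"` option divides by variant sites instead. The
test suite checks the window values against explicit enumeration of
allele pairs.

F_ST is the Weir & Cockerham (1984) two-population estimator: per-site
variance components a (among populations), b (among individuals within
populations) and c (within individuals) from sample sizes, allele
frequencies and observed heterozygosity, combined per window as the
ratio of sums Σa / Σ(a+b+c). Sites monomorphic overall contribute
nothing and windows without usable sites are NA. The estimator is exact
at the textbook extremes (fixed difference → 1; identical composition →
≤ 0) and is verified in the tests against an independently coded
transcription of the variance components. PCA of the genotype matrix
mirrors the usual pipeline: per-site standardisation, mean imputation of
missing genotypes, eigendecomposition; variance fractions are reported
over all computed components and sum to one.

## Breakpoint enrichment permutation test

`permutation_test()` compares the observed occupancy (overlap bases,
each base counted once) of each repeat class within the breakpoint
windows against N length-matched random placements (default N = 1000):
for each breakpoint window one interval of the same length is placed
uniformly at random in the genome, avoiding the mask (centromeres and
telomeres) entirely, start positions weighted by available unmasked
span across chromosomes. With k the number of permutations in which the
observed occupancy strictly exceeds the permuted one, P = (N − k) / N.
Ties therefore count against enrichment — an annotation covering the
whole genome yields P = 1 exactly — and the smallest attainable value is
0, reported together with the fold change (observed over permutation
mean) which carries the magnitude information. A `smoothed` flag gives
the add-one alternative (N − k + 1)/(N + 1) for users who prefer
p-values bounded away from zero; it is not the default because the
plain formula is the field's convention.

Design details: matched intervals are sampled independently per
breakpoint (no joint non-overlap constraint), and each interval's
overlap is summed independently into the permuted occupancy, so the
tie identity above holds exactly even when two sampled intervals
collide. All classes are evaluated against one shared permutation set
per iteration. Breakpoint windows that overlap the mask are matched at
their unmasked (clipped) length with a warning, a fully masked window
contributing an always-empty interval; the observed occupancy is still
computed on the real windows. No multiplicity correction is applied
across classes; results are per class. The whole procedure is
bit-reproducible under its seed, and the tests verify the p-value
against exhaustive enumeration on a toy genome with three valid
placements, plus null calibration (mean p ≈ 0.5 under random
annotation).

## Assembly QC

`error_rate()` is ΣNM / Σaligned bases over mapped records — NM counts
mismatches *and* small indels, and is used as-is rather than
reinterpreted as pure mismatches. Aligned query bases exclude soft
clips. `improper_pair_rate()` is flagged pairs over paired records;
`mapping_and_breadth()` and `n50()` follow their standard definitions
(N50: largest L such that contigs ≥ L sum to at least half the total).
Alignment summaries are consumed as a documented TSV (read id, flags,
aligned bases, NM) rather than BAM, keeping the module light; producing
that TSV from a BAM is a one-line `samtools view | awk` step.

## The synthetic-data generator

Every analysis above is exercised against `simulate_*` generators whose
truth is recorded, so recovery is checkable. The generator emulates:

- **Genomes** (`simulate_genome`): per chromosome, a 5' telomere cap,
  random flank, a centromeric array of 455-bp monomers each
  independently substituted at 2% per base, another flank, and a 3'
  reverse-complement cap; TE annotation intervals in the flanks; one
  real segmental-duplication pair per chromosome written into the
  sequence (2 kb at 2% divergence, satisfying the ≥ 1 kb / ≥ 90%
  identity definition of an SD), plus optional SD copies across the
  inversion breakpoints, emulating the breakpoint-associated
  duplications seen in real comparisons.
- **Inversions** (`apply_inversion`): reverse-complement substitution of
  the segment, truth recording both breakpoints; an involution, as the
  tests assert.
- **Anchor maps** (`simulate_anchor_map`): anchors at regular spacing,
  identity mapping outside inversions and mirrored coordinates with
  reverse orientation inside, with optional noise anchors.
- **Populations** (`simulate_population`): two groups of 45 and 225
  accessions (the design of the motivating resequencing panel) with
  inversion carrier frequencies 0.69 and 0.24. Ancestral allele
  frequencies are Uniform(0.05, 0.95); group frequencies are
  Balding–Nichols beta draws parameterised by the target F_ST — 0.74
  inside the inversion, 0.10 outside. Inside the inversion, genotypes
  are additionally driven by the inversion haplotype: the two
  arrangement classes get frequency vectors p_ref, p_inv solving
  p_group = c·p_inv + (1−c)·p_ref for the group carrier frequencies c,
  projected onto [0, 1] where the solution is infeasible, and carriers
  draw both alleles from p_inv. With carrier frequencies 1 and 0 the
  solve is exact and the group-level F_ST target applies exactly; this
  configuration is used for estimator-recovery benchmarks, while the
  0.69/0.24 design exercises genotyping. Carrier status is assigned by
  exact counts (round(c·n), positions permuted) by default:
  with 45 accessions the binomial standard error of a realised carrier
  frequency (~0.07) would dominate any recovery comparison at the
  ±0.05 level, and conditioning on the realised counts makes recovery
  benchmarks measure the genotyping method rather than sampling noise.
  `carrier_assignment = "binomial"` restores independent Bernoulli
  draws.
- **Coverage** (`simulate_coverage`): Poisson depth per 2-kb bin (mean
  12); carriers get zero-depth voids anchored at both breakpoints
  growing inward to 20% of the inversion plus a 0.8 overall depth
  factor; non-carriers keep uniform coverage, so breadth separates the
  classes cleanly at the 0.94 threshold.
- **Alignment summaries** (`simulate_alignments`): per-read NM ~
  Binomial(length, error rate) with exact fractions of improper pairs
  and unmapped reads.

Everything is deterministic under `sim_config(seed = )`; sub-generators
derive fixed offsets from it.

What the generator does **not** emulate — and hence what passing tests
do and do not show about real data: linkage disequilibrium and
recombination beyond the binary inversion-haplotype model; read-level
sequence data (coverage is generated at bin level, so mappability and
GC biases are absent); satellite higher-order repeat structure and
indel-divergent monomers; gene annotation; and assembly errors other
than the summarised alignment statistics. Recovery results on this
synthetic data demonstrate correctness of the estimators and detectors
under their stated models, not robustness to every artefact of real
sequencing.

Benchmark problem sizes are the package's own choice: Mb-scale
chromosomes, arrays of tens to hundreds of monomer copies, thousands of
SNPs, and 270-accession populations — large enough that every recovery
tolerance is meaningful, small enough that the entire suite and the
acceptance script run in minutes on one CPU. The population design
values (45/225, 0.69/0.24, F_ST 0.74/0.10), the 455-bp monomer length,
the telomere motif, the ≥ 90% identity thresholds, the > 94% coverage
rule, the 40-kb breakpoint flanks, the 50-kb windows, the 1000-iteration
permutation design and the hard-filter expression are the study-design
constants the package is benchmarked against.

## Known limitations

- The satellite scanner's gap-free scoring under-reports copies whose
  divergence is indel-dominated; lower `min_identity` or pre-split such
  classes.
- `detect_inversions()` resolves bounds only to anchor spacing and
  cannot see inversions smaller than `min_anchors` spacings.
- The Weir–Cockerham implementation is the two-population estimator;
  more than two groups require pairwise runs.
- `reconcile_genotypes()` encodes a fixed precedence (coverage wins);
  the conflict flag, not the package, is the audit trail.
- One centromere per chromosome is assumed; holocentric chromosomes are
  out of scope.
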