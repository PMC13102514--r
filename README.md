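# t2tkit

Comparative-genomics toolkit for complete (telomere-to-telomere) plant
genome assemblies, built around the analyses that such assemblies make
possible for the first time: characterising telomeres and centromeric
satellite arrays, detecting chromosomal inversions between closely
related genomes, genotyping those inversions across resequenced
populations, and quantifying the population-genetic and repeat-landscape
signals around them. The motivating system is cowpea (*Vigna
unguiculata*), whose two cultivated subspecies differ by large
pericentric inversions, but every function is organism-agnostic.

It is aimed at researchers who have a pair of high-quality assemblies
plus short-read resequencing data for a population and want a tested,
scriptable version of the usual ad-hoc pipeline.

## What it computes

- **Telomeres** — maximal tandem runs of the telomere motif
  (`CCCTAAA` at 5' ends, its reverse complement `TTTAGGG` at 3' ends)
  within a terminal window (`find_telomeres`).
- **Centromeric satellites** — monomer hits at an identity threshold
  (default ≥ 0.90) tiling each array, in both orientations
  (`scan_satellite`); star-alignment consensus, per-monomer variant
  counts and stratified monomer similarity summaries
  (`build_consensus`, `count_variants`, `similarity_classes`).
- **Centromeres** — satellite arrays merged across gaps and anchored on
  tandem-repeat density, with a density-only fallback
  (`delineate_centromere`); arm ratios and anchor-projected
  repositioning calls between syntenic genomes (`arm_ratio`,
  `detect_repositioning`).
- **Inversions** — runs of reverse-orientation syntenic anchors with
  noise tolerance (`detect_inversions`) and 40-kb breakpoint flank
  windows (`define_breakpoints`).
- **Population genotyping of an inversion** — coverage breadth over the
  inversion per accession (reference genotype iff breadth > 94%),
  inversion-region PCA with two-means clustering on PC1, and
  reconciliation with conflict flags (`covered_fraction`,
  `genotype_by_coverage`, `pca_genotype`, `reconcile_genotypes`).
- **Population genetics** — GATK-style hard filters, MAF/missingness
  filters, 50-kb windowed nucleotide diversity π and Weir–Cockerham
  F<sub>ST</sub> (ratio-of-sums a / (a+b+c)), and genotype PCA
  (`apply_hard_filters`, `maf_missing_filter`, `window_pi`,
  `window_fst`, `population_pca`).
- **Breakpoint enrichment** — permutation test of repeat-class
  occupancy in breakpoint windows against length-matched random
  intervals sampled from the unmasked genome, with
  P = (N − k) / N over N permutations (`permutation_test`).
- **Assembly QC** — NM-tag error rate, improper-pair rate, mapping
  rate, coverage breadth and contig N50 (`qc_report`, `n50`).
- **Synthetic data with known truth** — genomes with telomere caps,
  mutated 455-bp satellite arrays, TE/SD annotations and inversions; a
  two-subspecies population (45 + 225 accessions, inversion carrier
  frequencies 0.69 / 0.24) with Balding–Nichols allele-frequency
  divergence (F<sub>ST</sub> targets 0.74 inside / 0.10 outside the
  inversion); coverage tracks with breakpoint-anchored voids in
  carriers; and alignment summaries (`sim_config`, `simulate_*`).

## Worked example

The demo pipeline simulates everything, runs every stage and compares
the estimates with the simulation truth:

```r
library(t2tkit)
cfg <- sim_config(seed = 42)
report <- run_demo(cfg, n_perm = 500)
print(report)
```

```
End-to-end recovery report (seed 42)
  telomeres detected:        6 / 6
  satellite copies found:    100.0% of 600
  centromere bound error:    0 bp
  inversions detected:       1 (bound error 10,000 bp)
  genotype concordance:      1.0000 (conflicts 0.0000)
  carrier frequencies:       sesquipedalis=0.240, unguiculata=0.689
  F_ST inside / outside:     0.738 / 0.105
  PC1 variance fraction:     0.604
  SD breakpoint enrichment:  p = 0.004 (fold 9.88)
  alignment error rate:      0.01004
  improper-pair rate:        0.05000
  contig N50:                2e+06 bp
```

Reading the output: all six simulated telomeres and all 600 satellite
monomer copies are found, and the centromere boundaries are exact. The
single simulated inversion is recovered with bounds within one anchor
spacing. Genotyping the inversion across 270 simulated accessions from
coverage voids plus inversion-region PCA reproduces the configured
carrier frequencies (0.69 and 0.24) with no conflicts. The windowed
Weir–Cockerham estimator recovers the Balding–Nichols targets (0.74
inside the inversion, 0.10 outside), segmental duplications placed at
the inversion breakpoints come out strongly enriched in the permutation
test, and the alignment QC metrics match the simulated error and
improper-pair rates. Passing `out_dir =` additionally writes FASTA,
BED, VCF and TSV outputs plus a JSON version of the report.

## Vignette

`vignettes/t2tkit-methods.Rmd` documents the models and estimators, the
synthetic-data generator and what it does and does not emulate, the
default parameters and the numerical design choices.
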