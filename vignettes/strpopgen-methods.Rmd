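---
title: "Forensic STR statistics at length and sequence resolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic STR statistics at length and sequence resolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpopgen)
```

## The problem

Forensic STR panels are characterised in a reference population by two
families of statistics. For diploid autosomal markers the per-locus suite —
observed and expected heterozygosity, polymorphism information content
(PIC), match probability (PM) and its complement the power of
discrimination (PD), power of exclusion (PE) and typical paternity index
(TPI) — quantifies how useful each marker is for identification and
paternity testing, and the loci combine multiplicatively into CPE and CPD.
For haploid Y-chromosomal markers the unit of analysis is the whole
haplotype: haplotype diversity (HD), haplotype match probability (HMP) and
discrimination capacity (DC) measure how well a marker set separates male
lineages.

Massively parallel sequencing adds a second resolution to all of this.
Where capillary electrophoresis (CE) reports only a total repeat count
("allele 9", "allele 9.3"), sequencing reads the repeat region itself, so
alleles of identical length but different internal motif structure —
iso-length variants such as `[TCTA]4[TCTG]6` versus `[TCTA]10` — become
distinguishable. Every statistic in this package can therefore be computed
at either *length* level (CE designations) or *sequence* level (bracket
notation), and a central empirical question is how much each statistic
gains from the refinement.

## Allele nomenclature

A sequence allele is an ordered list of motif blocks plus an optional
trailing partial unit shorter than the repeat period. Its CE designation
is the sum of block counts, with a `.k` suffix when `k` bases remain
(`[AGAT]9 AGA` → `9.3`): the microvariant label uses the count of leftover
bases, the standard CE convention. Collapsing to length level is therefore
a deterministic many-to-one map, which gives the key invariants the test
suite leans on: collapsing commutes with every counting operation, and
sequence-level distinct-allele counts can never fall below length-level
counts.

Two restrictions are deliberate. Only the repeat region is modelled —
flanking-sequence variation, which some MPS nomenclatures also track, is
out of scope. And alleles compare equal by their normalized structure, so
whitespace and dialect differences in the input never create spurious
alleles.

## Estimators

All frequency estimation is direct counting: allele frequencies are
integer counts over the observed gene copies (2N per diploid locus over
the samples typed there; per-locus complete cases), haplotype frequencies
are counts over complete male haplotypes. No model smoothing is applied
anywhere.

The per-locus formulas are the standard forensic set:

* `H_exp = GD = g/(g−1) · (1 − Σp²)` — unbiased Nei estimator, with `g`
  the gene count. GD and H_exp are one code path; for Y loci `g` is the
  number of typed males and a multi-copy unit (e.g. DYS385a/b) contributes
  its sorted allele pair as one compound allele.
* `PIC = 1 − Σp² − Σ_{i<j} 2 p_i² p_j²` (Botstein).
* `PM = Σ (observed genotype frequency)²`, `PD = 1 − PM` exactly. PM uses
  observed genotype proportions, not Hardy–Weinberg expectations; the
  observed-frequency convention is the common forensic practice and is
  consistent with direct counting. This is recorded as an assumption: the
  alternative (HWE-expected) convention differs only at the third decimal
  for markers in equilibrium but is not what we compute.
* `PE = h²(1 − 2hH²)`, `TPI = 1/(2(1−h))` with `h = H_obs`, `H = 1 − h`.
  The PE form was pinned numerically against two independent published
  anchor pairs (h = 0.61306 → 0.306843 and h = 0.94586 → 0.889690), which
  no other standard PE variant satisfies simultaneously.
* `CPE = 1 − Π(1−PE_l)` and `CPD = 1 − Π(1−PD_l)`. The residual products
  reach 1e-60 and below on a full panel, so they are accumulated in log
  space (`log1p`/`expm1`) and printed in the `1-5.0779620E-21` style used
  in published tables.
* `HMP = Σp²` over haplotype frequencies, `HD = n(1−HMP)/(n−1)`,
  `DC = distinct/n`. The fraction of unique haplotypes is singletons over
  *distinct* haplotypes (not over males); that is the reading of published
  "of these, X% were unique" statements that reproduces their numbers.

## Hardy–Weinberg testing

`hwe_exact_test()` conditions on the observed allele counts. For
biallelic markers the Levene conditional distribution over heterozygote
counts is enumerated fully; the p-value is the total probability of
arrays no more probable than the observed one (probability-ordering, the
usual exact-test convention), with a `1 + 1e-12` relative guard so
floating-point ties count as ties. For three or more alleles the same
comparison is Monte-Carlo: the 2N gene copies are shuffled and re-paired
(default 17,000 replicates, seeded; the table-level wrapper derives marker
`i`'s seed as `seed + i`), and the p-value uses the `(1 + hits)/(B + 1)`
estimator, which keeps the test valid. Monomorphic markers return p = 1
by convention. Family-wise control is plain Bonferroni, `α/m`.

The exact variant used by any particular published analysis is rarely
stated, so the package asserts calibration properties instead of value
matches: on data simulated in equilibrium the test rejects at the nominal
rate (checked over 2,000 tables against a binomial 99% interval), and
power increases with the inbreeding coefficient used to break equilibrium.

## Population distances

`pairwise_fst()` is the multi-locus Weir–Cockerham (1984) θ: variance
components a, b, c per allele and locus, summed across alleles and loci
before the ratio. A frequency-only fallback (`pairwise_fst_freq()`),
for published tables without genotypes, uses Nei's coancestry Fst with
the Nei–Chesser sample-size correction; the estimator used is recorded in
the matrix metadata. `pairwise_rst()` is Slatkin's Rst from one-way ANOVA
variance components of repeat counts, summed over loci; it is invariant
under affine transforms of the counts, which the suite asserts.

Three conventions to note. Microvariant alleles map to their integer
repeat count for Rst by default (a `microvariant = "exclude"` switch
drops such loci instead), since published analyses rarely state their
convention. Multi-copy Y units are excluded from Rst — there is no single
repeat count per sample. Negative θ/Rst estimates are floored at 0 in the
matrix because MDS and neighbour-joining consume it as a distance, with
the raw estimates retained in the `"raw"` attribute.

## Structure analysis

`classical_mds()` is Torgerson scaling (double-centre, eigendecompose,
scale eigenvectors by √eigenvalue) via `stats::cmdscale`, chosen over
non-metric MDS because it is deterministic and exactly invertible on
Euclidean inputs — the contract the tests check (planted configurations
reproduced to 1e-8). Negative eigenvalues of non-Euclidean inputs are
reported, never used for coordinates; if fewer positive eigenvalues exist
than requested dimensions the embedding truncates with a warning. The
default 2-D projection is the conventional choice for population plots.

`neighbor_joining()` is a from-scratch Saitou–Nei implementation rather
than a wrapper, for one reason: deterministic tie-breaking. When several
pairs minimise the Q-criterion (within 1e-12 relative), the pair whose
subtree labels sort lowest wins, which makes the output invariant to
input row order — a property the reference implementation does not
guarantee and the suite verifies against it on tie-free matrices.
Negative branch lengths from the two-point formulas are floored at 0 with
the deficit moved to the sibling branch (standard practice); raw lengths
are kept in an attribute. On additive matrices the reconstruction is
exact (topology and path lengths to 1e-9, verified over random trees).
Newick serialization writes 6-decimal branch lengths and quotes labels
containing reserved characters.

## The synthetic-population generator

No casework genotypes ship with the package; the generator exists so that
every downstream stage is testable with data whose ground truth is known.
Its defaults emulate a realistic single-population MPS study: 628 samples
(547 male, 81 female), 52 autosomal plus 81 Y marker units of which four
are multi-copy a/b pairs.

* **Allele spectra.** Per-marker allele counts are drawn to match the
  ranges such studies report: autosomal loci 6–25 length alleles (mean
  ≈ 10.7, so a 52-locus panel carries ≈ 554 length alleles), Y loci 1–14
  with ≈ 3% monomorphic. Frequencies are symmetric Dirichlet draws
  (concentration 1), giving the skewed spectra — a few common alleles, a
  tail of rare ones — typical of forensic loci.
* **Iso-length variants.** Each CE allele splits into `1 + Poisson(λ)`
  sequence variants (λ = 0.79 autosomal, 0.40 Y), chosen so the
  sequence:length allele-count ratios sit near the ≈ 1.8 and ≈ 1.4
  reported for such panels; within-allele frequency splits are Dirichlet
  with concentration 5. Collapsing the split recovers the input exactly.
* **Autosomal genotypes.** Two independent gene copies (HWE) unless an
  inbreeding coefficient `f` is set, in which case the second copy
  duplicates the first with probability `f`, giving
  `P(aa) = p² + f·p(1−p)`.
* **Y haplotypes.** Independent loci would badly overstate haplotype
  diversity, so males copy one of 400 founder lineages and each gene copy
  then takes a ±1 single-step mutation with probability 0.002. The
  founder count and rate were chosen once to put the haplotype count for
  547 males in the realistic ~400 range via the uniform-occupancy
  expectation `F(1−(1−1/F)^n)`.
* **Divergence.** Balding–Nichols: daughter-population frequencies are
  Dirichlet draws with parameters `p(1−F)/F`, whose per-allele marginals
  are the Balding–Nichols Beta, so `F` is a known Fst truth for
  parameter-recovery tests.

What the generator does **not** emulate: linkage between autosomal loci,
locus-specific mutation models, allelic dropout/typing error, flanking
variation, and real haplogroup structure beyond the founder model. Tests
passing on synthetic data therefore validate the estimators and their
invariants, not the demographic realism of any particular population.

## Numerical choices and degenerate inputs

Frequencies validate to 1 within 1e-9; Dirichlet draws are floored at
1e-12 and renormalised so no allele is ever exactly 0. TPI raises on
`H_obs = 1`; HD raises for n < 2; a monomorphic marker has GD 0 and HWE
p = 1. Combined-power residuals never underflow because they live in log
space. All seeded functions snapshot and restore the caller's RNG state,
so seeding a draw does not perturb an enclosing simulation.

## Problem sizes used in the checks

The package's own verification runs at sizes chosen to give tight Monte
Carlo error while keeping the full suite comfortably interactive: HWE
calibration over 2,000 five-allele tables of 100 individuals at 1,000
permutations each; θ recovery over 50 replicates of two 500-sample
populations at 15 loci; neighbour-joining over 100 random 4–10-taxon
trees; the refinement-monotonicity sweep on one full-size simulated
cohort (628 samples, 133 markers).

## Known limitations

Rst on mixed microvariant ladders depends on the integer-part convention;
kinship statistics beyond TPI (and θ-corrected match probabilities) are
out of scope; the frequency-only Fst fallback is a different estimator
from genotype-based θ and the two should not be mixed within one matrix;
no significance testing (permutation p-values) is attached to distance
matrices; and published cross-population distances cannot be reproduced
without the third-party reference datasets, so the package asserts
recovery of known simulated truths instead.
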