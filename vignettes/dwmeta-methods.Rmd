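---
title: "Methods: comparing disinfected and non-disinfected drinking-water metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing disinfected and non-disinfected drinking-water metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwmeta)
```

## The problem

Drinking-water distribution systems fall into two management regimes: those
that maintain a chlorine (or chloramine) residual in the distributed water
("disinfected", D) and those that rely on nutrient limitation instead
("non-disinfected", ND). Shotgun metagenomes from such systems are
low-biomass samples, so sequence data are vulnerable to reagent and handling
contamination, and the communities differ both taxonomically and in
functional potential between the two regimes. `dwmeta` implements the
comparison pipeline for this setting: contaminant removal anchored on
sequenced negative controls, taxonomic and functional profiling from
assembly coverage, community dissimilarity at nucleotide and functional
level, environmental fitting, and detection-based analysis of
metagenome-assembled genomes (MAGs).

Every stage operates on plain tables (scaffold coverage, SSU hits, KO
annotations, MAG breadth, water chemistry), so the pipeline is testable
without sequencing data: the package ships a synthetic-study generator that
emulates the upstream assembly/mapping outputs with planted, recoverable
structure.

## Scaffold decontamination

Negative controls (reagent and filter blanks) are sequenced alongside the
samples. For every scaffold of a per-system co-assembly we compare behaviour
under two read sets: sample reads (S) and contaminant reads identified in
the negative controls (C). Two statistics are used:

* relative abundance, $RA_i = \mathrm{cov}_i / \sum_j \mathrm{cov}_j$, where
  the contaminant variant $RA_C$ divides a scaffold's contaminant-read
  coverage by the summed coverage of *all* negative-control reads; and
* normalized coverage deviation, $NCD = \sigma_{\mathrm{depth}} /
  \mu_{\mathrm{depth}}$, a coverage-evenness measure — genuine community
  members are covered evenly, contamination tends to be patchy.

The classification rule is piecewise: a scaffold is **true** if $RA_C = 0$
or if $RA_S > RA_C$ and $NCD_S < NCD_C$; it is **contaminant** if $RA_S = 0$
or if $RA_C > RA_S$ and $NCD_C < NCD_S$. Tuples satisfying neither branch
(e.g. more abundant in samples but *less* evenly covered) are labeled
**ambiguous** and excluded, which is the conservative choice: only scaffolds
that positively pass the true branch enter downstream profiles. Two edge
cases needed decisions the rule itself does not make:

* zero mean depth: $NCD$ is defined as $+\infty$, so an uncovered scaffold
  can never win a "lower NCD" comparison;
* a scaffold covered by neither read set satisfies both zero branches; it is
  resolved to exclusion (labeled contaminant), since an uninformative
  scaffold should not enter abundance profiles.

Both statistics are ratios of coverages, so classification is invariant
under any positive rescaling of all depths — a property the tests assert
directly, alongside agreement with a brute-force re-evaluation of the rule
on random tuples.

Depth standard deviations are carried as per-base population SDs in the
coverage tables; when read sets are pooled across samples, depths add and
variances are treated as additive, $\sigma_{\mathrm{pool}} =
\sqrt{\sum_i \sigma_i^2}$.

## Taxonomic profiles from SSU rRNA

SSU rRNA hits on scaffolds are filtered at $\geq$ 100 bp alignment
(inclusive) and e-value $< 10^{-5}$ (strict), hits on contaminant scaffolds
are dropped, and only the longest SSU gene per scaffold is kept (ties break
lexicographically on the hit identifier, for determinism). Abundance is
RPKM over the sample's SSU-bearing scaffolds:

$$\mathrm{RPKM}_i = \frac{r_i}{(L_i/10^3)\,(N/10^6)}, \qquad
  p_i = \frac{\mathrm{RPKM}_i}{\sum_j \mathrm{RPKM}_j},$$

with the scaffold read count reconstructed from mean depth as $r_i =
\mathrm{cov}_i L_i / \ell$ ($\ell$ = nominal read length, 250 bp default,
matching 2 x 250 bp sequencing). Profiles sum to one per sample and
aggregate additively to any rank; the phylum view can report Proteobacteria
at class level, the usual convention for community barplots.

## KO and module profiles

A (sample, KO) pair is retained only if the KO sits on a scaffold with
strictly more than 1x coverage in that sample *and* the KO passes that
criterion in at least two samples of the same system — singleton detections
within a system are treated as noise. Read counts per KO are reconstructed
from host-scaffold coverage (summing over host scaffolds), and an
RPKM-normalized variant is kept alongside for dissimilarity work.

KEGG modules are parsed from `id TAB definition` lines with the standard
grammar restricted to one nesting level: space-separated blocks (reaction
steps), comma-separated alternatives within a block, `+`-joined complexes
within an alternative. A block is complete when any alternative is fully
present (complexes require all subunits); module completeness is the
fraction of complete blocks. Module abundance in a sample is the **median**
abundance of the module's *detected* member KOs (absent KOs are excluded
from the median rather than counted as zero; a module with no detected
members reports 0 with a `detected = FALSE` flag). Even-count medians take
the mean of the two central values. Differential testing consumes modules
with at most one block missing and completeness $\geq 50\%$ — both bounds
inclusive, so a two-block module with one block missing survives.

## Community dissimilarity

Two complementary distances are computed:

* **MinHash sketch (Mash) distance** on sequence sets. Canonical
  (strand-minimal) k-mers are hashed with a seeded 64-bit mixing function
  (k-mers spanning non-ACGT symbols are skipped) and the `size` smallest
  distinct values form the sketch. The Jaccard index $j$ is estimated from
  the merged-sketch construction and converted to
  $D = -\tfrac{1}{k}\ln\tfrac{2j}{1+j}$, capped at 1. Defaults are k = 21
  and a configurable sketch size; a minimum k-mer multiplicity filter
  (conventionally 2 for reads, off for assemblies) suppresses singleton
  error k-mers. When the sketch holds every distinct k-mer the estimate is
  exact, which is how the tests pin the implementation to a brute-force
  k-mer enumeration oracle at $10^{-12}$ tolerance. Hashes are truncated to
  53 bits so R holds them exactly as doubles; at test scales the collision
  probability is negligible (of order $n^2 2^{-54}$).
* **Bray-Curtis** on KO RPKM profiles, $\sum|x-y| / \sum(x+y)$, zero when
  both profiles are empty.

**BioEnv** relates community structure to water chemistry: every nonempty
subset of candidate variables ($2^n - 1$ subsets; 511 for the nine
chemistry variables carried here) is scored by the Spearman correlation
between community dissimilarities and Euclidean distances over the z-scored
subset. Constant variables are excluded with a warning (z-scoring is
undefined). Spearman uses average ranks for ties.

The **group permutation test** pools the pairwise distances and classes each
pair as within-D, within-ND, or between-group. The statistic is a one-way
F-like among/within ratio over those three classes; the null is built by
reshuffling sample group labels, and $p = (\text{exceedances}+1) /
(n_{\mathrm{perm}}+1)$, exact under exchangeability. The exact statistic
behind a "permutational ANOVA on distance distributions" is a genuinely open
choice (a PERMANOVA on the matrix is the main alternative); the pair-class
F ratio was chosen because it tests precisely the quantity summarized
downstream (within- versus between-group distance levels) and its name is
recorded in the test result's metadata. The suite verifies calibration: with
i.i.d. distances and random labels, the rejection rate at $\alpha = 0.05$
over 500 replicates stays within 3 binomial SEs of 0.05.

Cross-scale comparisons (read-level sample distances versus system-level
assembly distances) average the finer matrix within system pairs before the
Pearson correlation of condensed upper triangles.

## MAG detection and categories

MAGs with completeness $> 50\%$ and redundancy $< 10\%$ (both strict) are
analysed. A MAG is *detected* in a sample when at least 25% of its bases are
covered by one or more reads (inclusive). With detection frequencies pooled
over each group's samples and threshold 20% (inclusive):
D-only (frequent in D, never detected in ND), ND-only (symmetric), both
(frequent in both), other (everything else). Per-sample MAG RPKM,
$\mathrm{reads} / ((N/10^6)(L/10^3))$, is masked (NA) wherever the MAG is
not detected, so spurious cross-mapping never enters abundance summaries.
Genome size is estimated as assembled length times the inverse completeness
fraction.

One caveat the tests document: detection frequency is *not* monotone in the
category structure — raising the breadth threshold can switch a MAG from
"other" to "D-only" by erasing a sporadic ND detection. The tests therefore
assert the true monotonicity (detections only disappear as the threshold
rises) rather than category stability.

## The synthetic-study generator

`study_config()` defaults encode the surveyed design: 7 D and 5 ND systems
(each its own co-assembly), three sampling locations per system, 2 x 250 bp
reads, two sequenced negative controls, nine water-chemistry variables with
chlorine averaging 0.37 mg/l in D (range-matched spread) and **exactly**
zero in ND, and phosphate dosed only in D. Key modelling choices:

* **Abundance model.** Log-normal per taxon with a per-system random effect
  whose SD is larger in ND (`abundance_dispersion`, default 0.7 vs 1.2 log
  units) — the non-disinfected communities are the more variable ones.
  Chlorine-responsive taxa (40% of community taxa by default, split between
  favoured and sensitive) shift log-linearly with the sample's *measured*
  chlorine dose, so chlorine is mechanistically the structure-driving
  variable; temperature and phosphate differ by group but do not drive
  community structure. This is what makes "BioEnv recovers chlorine" a
  falsifiable check rather than a tautology.
* **Coverage.** Scaffold depth is the taxon's relative abundance scaled to a
  `mean_depth` budget (default 10x) with multiplicative log-normal noise
  (SD 0.3; 0 gives deterministic coverage). Depth SDs are stored explicitly
  so NCD is computable without re-simulating reads.
* **Contaminants.** Contaminant taxa receive coverage in every negative
  control and, in pure-contaminant mode (default), none in true samples; a
  `contaminant_leak_rate` lets them bleed into samples for harder tests.
* **MAGs.** Each MAG-backed taxon gets a presence mask matching its intended
  category (D-only, ND-only, both, other in rotation); breadth follows the
  Poisson coverage identity $1 - e^{-\mathrm{cov}}$, which is monotone in
  depth, so intended categories are recoverable exactly in low-noise
  configurations.
* **Modules.** The KO pool is partitioned so some modules draw exclusively
  from KOs planted in chlorine-favoured (or -sensitive) taxa; those modules
  must come out more abundant in the matching group.
* **Sequences.** Per-taxon references are i.i.d. uniform nucleotide strings
  (configurable GC); fragments for sketching are drawn in proportion to
  taxon abundances. This supports sketch-distance testing but has no
  phylogenetic realism — sketch distances between synthetic samples reflect
  shared taxon content only.
* **Randomness.** One root seed; each table draws from a child stream at a
  fixed offset, so adding a table never perturbs the others, and identical
  configurations serialize byte-identically.

What passing tests do *not* show about real data: the generator has no
sequencing error, no assembly artefacts (chimeras, fragmentation correlated
with abundance), no strain-level variation, no compositional coupling
between taxa beyond closure, and negative-control content is purely the
planted contaminants (the real protocol spikes a mock community into blanks
and subtracts it upstream; that subtraction is emulated, not implemented).
Recovery rates on synthetic studies are therefore upper bounds.

## Problem sizes and numerical choices

The test suite runs on small studies (2-3 systems per group, 12-20 taxa);
the oracle checks use 10,000 random classification tuples, 50 sequence
pairs up to 5 kb for exact-Jaccard sketching, all module shapes up to 4
blocks x 3 alternatives, and 500 replicates of 999 permutations for
calibration. The acceptance script runs the full default design (12
systems, 36 samples, ~3,300 scaffolds) with 999 permutations. These sizes
were chosen so the whole suite completes in about a minute while every
check still has discriminating power at its stated tolerance.

Tables serialize through `write.table` at 15 significant digits; the
round-trip tests compare at `1e-12` relative tolerance. Distance matrices
are validated on construction (symmetry, zero diagonal, finite nonnegative
entries). The permutation p-value can never be 0 by construction; the
minimum attainable is $1/(n_{\mathrm{perm}}+1)$.

## Known limitations

* The per-scaffold depth SD is generated, not derived from a read-level
  simulation, so NCD contrasts between true and contaminant scaffolds are
  only as informative as the generator makes them; the pure-contaminant
  recovery checks rely on the zero-branches of the rule, which is also what
  dominates on real negative controls.
* BioEnv is exhaustive and exact but exponential in the variable count; it
  is intended for the ~10-variable chemistry panels of this setting.
* The generator's "other" MAG category plants detections below the 20%
  frequency in D only; real "other" MAGs can be sporadic in both groups.
* Differential module testing (e.g. with DESeq2) and ordination methods
  (dbRDA, variance partitioning) are out of scope; the module profile table
  is shaped as their direct input.
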