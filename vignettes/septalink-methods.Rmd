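---
title: "Methods behind septalink: linkage surveys, muropeptide masses and septal quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind septalink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septalink)
```

`septalink` bundles the three computational analyses that recur when a new
septal peptidoglycan (PG) enzyme is characterised: a gene-neighbourhood
conservation survey, LC-MS mass arithmetic for glycan fragments, and
quantification of septal fluorescence in single cells. This vignette
explains the models and conventions behind each module, the parameters
that matter, what the synthetic-data generators do and do not emulate, and
the design choices made where more than one convention was defensible.

## 1. Gene-neighbourhood linkage

### Family rules

Families are defined purely by functional annotation logic
(`family_rule()`): a gene belongs to a family when it carries at least one
ID from `include_any`, all IDs in `require_all`, and none from
`exclude_any`. This mirrors how homologue sets are assembled from
consistently annotated genome databases without any sequence comparison.
The four built-in rules cover the divergent polysaccharide deacetylase
family (PF04748 / K09798), the amidase activator EnvC (K22719, excluding
the KEGG numbers of the paralogous LytM activators MepM, NlpD and YgeR so
that multi-annotated LytM proteins are not miscounted), the
cofactor-independent phosphoglycerate mutase GpmM (TIGR01307), and AmiC
(K01448 / PF01520 restricted to proteins that also carry the AMIN
targeting domain PF11741). For rules without exclusions, membership is
monotone in the annotation set — adding annotations can never remove a
gene from the family — a property the test suite checks.

### Closest pairs and the distance convention

For two families in one genome, `closest_pair()` minimises over all
cross-family gene pairs on the same contig. "Distance" is not defined
uniquely by convention (gap, midpoint-to-midpoint and start-to-start all
appear in the literature); we use the **count of strictly intervening base
pairs** between the two 1-based inclusive intervals, clamped to 0 when
they overlap or abut. This choice is symmetric, independent of gene
lengths, and matches the operon-scale reading of a "within 2 kb"
threshold. Contigs are treated as linear — annotation-table coordinates
carry no topology information, so no wrap-around distance is attempted —
and pairs spanning different contigs are never formed: genomes carrying
both families only on different contigs count in `n_with_both` but not
`n_with_pair`. A single gene matching both rules is not paired with
itself. With multiple homologues the minimum is taken over the full
cross-product with a deterministic lexicographic tie-break on
`(gene_a_id, gene_b_id)`, so results are independent of row order (also
tested, by permutation).

`linkage_survey()` aggregates the per-genome observations into counts that
satisfy `n_same_strand <= n_with_pair <= n_with_both <=
min(n_with_a, n_with_b)`; strand-concordance and within-threshold
fractions are reported relative to `n_with_pair` and are `NA` when no
genome contributes a pair. iTOL `DATASET_SIMPLEBAR` export allows the
per-genome counts to be displayed along any tree whose leaves are genome
IDs; mismatches between tree and table are surfaced as warnings rather
than errors because partial overlap is the norm with large trees.

### What the genome generator emulates

`simulate_genomes()` lays out single-contig genomes left-to-right with
gamma-distributed gene lengths (mean 900 bp) and exponential intergenic
gaps (mean 150 bp) — roughly bacterial gene density. A genome carries both
surveyed families with probability 0.8; a carried pair is an adjacent
operon pair with probability 0.8, separated by a short exponential gap
(mean 300 bp, i.e. essentially always under 2 kb) and strand-concordant
with probability 0.9; unlinked members sit at independent loci with
concordance 0.5. These defaults express the qualitative study conditions —
most co-occurring pairs linked, linked pairs overwhelmingly
strand-concordant — at magnitudes where parameter recovery is non-trivial.
A small fraction (3%) of background genes carries decoy annotations,
including the LytM exclusion IDs and near-miss combinations (K22719 plus
an exclusion; an amidase ID without the AMIN domain), so the rule logic is
genuinely exercised. The generator does **not** attempt realistic genome
architecture: no operonic clustering beyond the planted pair, no
multi-contig assemblies, no taxonomic structure. Recovery tests therefore
show that the survey measures what was planted, not that real genomes
look like this.

Two notes on recovery semantics. The overall strand-concordance fraction
estimates a mixture (0.8 × 0.9 + 0.2 × 0.5), so the planted linked-pair
concordance is recovered on the truth-flagged linked subset. Conversely
the within-2-kb fraction is recovered overall: unlinked pairs fall within
2 kb only incidentally (~2% bias at the default genome size, well inside
the 3-binomial-SD recovery band used by the tests).

## 2. Muropeptide mass arithmetic

Glycan fragments are ordered chains of six sugar units (GlcNAc, MurNAc,
their deacetylated forms GlcN and MurN, and the 1,6-anhydro forms of the
muramic acids). The elemental formula of a chain is the sum of the free
monosaccharide formulas minus one H2O per glycosidic bond; borohydride
reduction of the reducing end adds H2 (2.0156501 Da), and an anhydro unit
at the reducing end cannot be reduced (its 1,6-anhydro ring has no free
aldehyde) — attempting to is an invariant error. Monoisotopic element
masses are used throughout (H 1.00782503, C 12 exactly, N 14.00307401,
O 15.99491462; proton 1.00727646).

Two identities anchor the module and are asserted to 1e-6 Da in the
tests: every deacetylation (GlcNAc to GlcN, MurNAc to MurN, anhMurNAc to
anhMurN, free or in-chain) removes exactly C2H2O = 42.0105646 Da, and
`fragment_formula` is additive over chain concatenation up to one water.
The diagnostic anhydro-disaccharides released by lytic transglycosylase
digestion of denuded strands compute to 478.1799 Da (GlcNAc-MurNAcAnh)
and 436.1693 Da (GlcN-MurNAcAnh); their singly protonated ions, 479.187
and 437.177 Th, are the unit-resolution m/z 479/437 peak pair whose
appearance/disappearance diagnoses deacetylase activity. Positive-mode
[M+H]+ with charge 1 is the default everywhere because these fragments
are small; higher charge states can be enabled per call (`z_max`).

`assign_peaks()` matches observed peaks to a candidate panel within a ppm
tolerance and flags the minimum-|error| match as best; as the tolerance
goes to zero only exact matches survive. `find_deacetylation_pairs()`
scans all peak pairs for an m/z difference equal to the acetyl mass within
a ppm tolerance referenced to the heavier peak. `relative_peak_areas()`
implements the amidase-assay readout — each sample area as a percentage of
the same peak in a no-enzyme control — with an explicit contract for
edge cases: sample-absent peaks report 0% (fully digested), control-absent
peaks are flagged and never scaled, and non-positive control areas are
errors.

The default simulated panel (`default_fragment_panel()`) contains 20
fragments chosen so all neutral masses are pairwise distinct by more than
1 Da (isomeric compositions such as GlcNAc-MurN vs GlcN-MurNAc share a
formula and are represented once); with 5 ppm Gaussian m/z noise and a
10 ppm tolerance, every assigned peak must therefore recover its true
identity — a peak drawn beyond the tolerance (about 4.5% of draws) stays
unassigned rather than being misassigned, and the tests treat accuracy
among assignments and assignment coverage as separate checks.

## 3. Single-cell septal quantification

### Medial axis

The pipeline consumes a fluorescence image plus an integer label mask
(segmentation itself, e.g. by Omnipose, is out of scope). For each cell,
`extract_cell_axis()` builds a pole-to-pole centerline: Zhang-Suen
homotopic thinning **anchored at the local maxima of the Euclidean
distance transform** (plain thinning erodes blunt line ends, collapsing
short diagonal rods before their ridge forms; anchoring makes the result
a medial-axis transform), pruning to the longest geodesic path through
the skeleton graph (double-sweep diameter, deterministic tie-breaks),
moving-average smoothing, resampling to ~1 px arc spacing, and extension
along the end tangents to the cell boundary. Cells touching the image
border, smaller than 20 px, or without an elongation axis (a disc's
pruned skeleton is shorter than its radius) are excluded with a recorded
reason, never silently dropped. Nearest-pixel membership tests use
`floor(x + 0.5)` rather than `round()` because banker's rounding of
exact-half coordinates would make membership depend on crop offsets.

### Profiles, demographs, morphometrics

The axial profile sums `width_px = 5` bilinear samples along the local
perpendicular at each axis position, restricted to samples inside the
cell; no background subtraction is applied before normalisation (the
normalisation operates on raw sums; subtract beforehand if your imaging
requires it). Normalisation is `I_norm_i = I_i * n / sum(I)` where `n` is
the profile length, giving every profile unit mean — the identity
`sum(I_norm) = n` is enforced to 1e-9 across all simulated cells.
Demographs stack normalised profiles resampled onto 100 relative-position
bins, rows sorted by ascending cell length (the field's convention; the
sort order is not dictated by the measurement itself). Cell length is the
axis arc length times the pixel size; width is twice the distance
transform averaged over the central half of the axis, so the tapering
pole caps do not bias the width of the cylindrical body.

### The midcell statistic

`midcell_intensity()` measures the mean intensity of a perpendicular band
3 axis positions thick at the axial midpoint and subtracts the same
measurement at the quarter position as a cytoplasmic background. The
quarter measurement is taken as the mean of the 25% and 75% positions —
a symmetric background estimate; a single-sided mode is available
(`quarter = "single"`). Band means (rather than sums) are used; the
subsequent control normalisation cancels the difference. Per biological
replicate, values are divided by the median of the control group
(`normalize_by_control()`), yielding "relative midcell intensity" whose
control median is 1 by construction; this cancels replicate-to-replicate
intensity scale (illumination, exposure) exactly, which the tests verify
by rescaling. Group comparisons use the two-sided Mann-Whitney U test
with tie correction (`stats::wilcox.test`, normal approximation) — the
appropriate nonparametric choice since midcell intensities are skewed
mixtures of dividing and non-dividing cells.

### What the cell generator emulates

`simulate_cells()` draws spherocylinders with Gaussian length
(3.0 ± 0.6 µm, truncated at 1.8) and width (1.0 ± 0.05 µm) at 0.065 µm/px
(100x objective on a small-pixel camera; 0.1 µm/px reproduces the EMCCD
scale used for septal-intensity imaging — pass `pixel_size = 0.1`). The
signal channel is a uniform cytoplasmic level (200 photons) plus a
Gaussian midcell band of axial sigma 0.1 µm whose amplitude is
`(enrichment - 1)` times the cytoplasmic level, so the band peak equals
`enrichment x cytoplasm` and the midcell-minus-quarter statistic equals
`(enrichment - 1) x cytoplasm` up to band-averaging; Poisson photon noise
and Gaussian read noise (SD 2) are added over a 10-photon offset. Cells
are placed on a jittered grid with random orientation: the grid spacing
guarantees the generator's own invariants (no overlaps, no border
contact) deterministically, which we preferred over rejection sampling of
free placements since the downstream statistics are indifferent to the
spatial point pattern. The generator makes no attempt at a realistic
point-spread function, phase background, cell curvature or division-site
constriction — so passing recovery tests demonstrate correctness of the
measurement pipeline, not robustness to real segmentation artefacts.

## Numerical choices and problem sizes

All randomness flows from a single integer seed per generator call
(`withr::with_seed`), making every dataset byte-reproducible; truth
records accompany each dataset so recovery tests never re-derive planted
values. The test suite sizes its simulations for a single CPU: the
closest-pair implementation is checked against an exhaustive brute-force
oracle on 1000 random genomes; linkage recovery uses 500 genomes with
3-binomial-SD acceptance bands; the profile identity runs on 200 cells;
the Mann-Whitney power check uses 20 runs of 50 cells per group
(enrichment 2.0 vs 1.0, p < 0.01 required in at least 95% of runs) and
the type-I-error check 200 runs of 30 cells per group at nominal
alpha = 0.05 with an acceptance band of [0.02, 0.10].

## Known limitations

* The linkage module consumes existing annotations; it performs no
  homology search and no tree inference.
* Mass arithmetic covers glycan chains only — stem peptides, MS/MS
  fragment ions, isotope envelopes and adducts other than protonation are
  out of scope; chromatogram peak areas are inputs, not derived from raw
  traces.
* The cell module is 2-D and single-timepoint; masks are trusted as
  given, and strongly bent or branched cells are excluded rather than
  traced.
* The printed unit-resolution m/z values are the only instrument-scale
  quantities asserted exactly; sub-0.1 Da agreement with any particular
  published chromatogram annotation depends on that instrument's
  calibration and rounding conventions.
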