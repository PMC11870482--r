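# septalink

Desk-scale analysis tools for studying septal peptidoglycan (PG) hydrolysis
and its regulators in bacteria. When a new septal enzyme is characterised —
for example a deacetylase acting on the "denuded" glycan strands that
amidases produce while splitting the division septum — three computational
questions recur, and `septalink` answers each with tested, reusable code:

1. **Is the gene genetically linked to a known regulator?**
   Genes are classified into families purely from PFAM/KEGG/TIGRFAM
   annotations (e.g. divergent polysaccharide deacetylase = `PFAM:PF04748`
   or `KEGG:K09798`; the amidase activator EnvC = `KEGG:K22719` minus the
   other LytM-activator KEGG numbers). For every genome carrying both
   families, the same-chromosome gene pair with the fewest intervening base
   pairs is selected, and the survey reports how often that closest pair is
   strand-concordant and lies within an operon-scale distance (2 kb by
   default). Per-genome counts export as iTOL `DATASET_SIMPLEBAR` files for
   display along a phylogenetic tree.

2. **Did the enzyme chemically modify the cell wall?**
   Monoisotopic masses of PG glycan fragments are computed from elemental
   formulas (free units minus one H2O per glycosidic bond, +H2 if
   borohydride-reduced). N-deacetylation removes an acetyl group, a loss of
   C2H2O = 42.0105646 Da; the package assigns LC-MS peaks to fragment
   panels at ppm tolerance, detects peak pairs separated by the acetyl
   shift, and quantifies HPLC peak areas relative to no-enzyme controls
   (the standard amidase-assay readout). The diagnostic anhydro-
   disaccharides GlcNAc-MurNAcAnh (C19H30N2O12, 478.1799 Da) and its
   deacetylated product GlcN-MurNAcAnh (C17H28N2O11, 436.1693 Da) give
   singly protonated ions at m/z 479.19 and 437.18.

3. **Where does the protein sit in the cell?**
   From fluorescence images plus integer label masks (as produced by a
   segmenter such as Omnipose), the package extracts each cell's medial
   axis, computes the axial intensity profile I_i (sum of 5 perpendicular
   samples per position), normalises it as
   `I_norm_i = I_i * n / sum(I)` (unit mean), stacks profiles into
   length-sorted demographs, measures cell length and width, and computes
   the midcell statistic: mean intensity of a 3-px band at the axial
   midpoint minus the same band at the quarter positions, normalised to a
   control group's per-replicate median ("relative midcell intensity") and
   compared between groups with a two-sided Mann-Whitney U test.

Seeded synthetic-data generators — annotated genomes with planted operon
linkage, rod-shaped cells with a planted Gaussian septal band, LC-MS peak
lists and assay area tables — stand in for the annotation database, the
microscope and the mass spectrometer, and each records a machine-readable
truth file so every analysis can be validated by parameter recovery.

## Worked example

```r
library(septalink)
rules <- builtin_rules()

# 1. linkage survey on 200 simulated genomes
sg <- simulate_genomes(genome_sim_params(n_genomes = 200, seed = 11))
linkage_survey(sg$genomes, rules$SddA, rules$EnvC)
#> <linkage_summary> SddA vs EnvC over 200 genomes
#>   with SddA: 189   with EnvC: 182   with both: 171   with same-contig pair: 171
#>   same strand: 135 (78.9%)   within 2000 bp: 81.3%   median distance: 315 bp

# 2. the deacetylation mass shift between the two diagnostic peaks
glycan_fragment(c("GlcN", "anhMurNAc"))
#> <glycan_fragment> GlcN-anhMurNAc
#>   C17H28N2O11  436.1693 Da, [M+H]+ 437.1766
peaks <- tibble::tibble(mz = c(437.1766, 479.1872), intensity = c(3200, 11800))
find_deacetylation_pairs(peaks, tolerance_ppm = 10)
#> # A tibble: 1 x 4
#>   mz_light mz_heavy delta_mz deacetylated_candidate
#>      <dbl>    <dbl>    <dbl>                  <dbl>
#> 1     437.     479.     42.0                   437.

# 3. midcell quantification of simulated cells with a 2x septal band
sim <- simulate_cells(cell_sim_params(n_cells = 40, enrichment = 2, seed = 5))
res <- analyze_cells(sim$gfp, sim$mask)
head(res$cells, 3)
#>   cell_id     n length_um width_um midcell_raw quarter_raw value
#> 1       1    39      2.49    1.06         372.        205.  167.
#> 2       2    59      3.77    0.949        371.        209.  162.
#> 3       3    36      2.28    0.999        368.        206.  162.
```

The survey shows the two families adjacent (median gap 315 bp, 81% within
2 kb) and mostly strand-concordant, as expected for an operon pair; the
mass block identifies the 42.011 Da acetyl loss linking the 437/479 peak
pair; and the midcell values (~165 photons above the cytoplasmic
background at a planted 2x enrichment over a 200-photon cytoplasm) recover
the planted septal band. Comparing those 40 values against a flat
(enrichment 1) group gives Mann-Whitney U = 1600, p = 1.4e-14.

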