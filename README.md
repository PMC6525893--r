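# pvdreb

Tools for categorizing the DREB (dehydration-responsive
element-binding) subfamily of AP2/ERF transcription factors in a plant
genome and characterizing candidate genes downstream: genomic placement
relative to SNP markers, nucleotide diversity of resequenced alleles,
and abiotic-stress expression from qPCR. The package is aimed at plant
molecular biologists working from a reference genome's domain
annotations, a SNP array's coordinates, Sanger resequencing panels and
qPCR plates — the standard desk inputs of a gene-family
characterization study — and at anyone who wants those analyses
scripted, seeded and testable instead of spread across desktop tools.

## What it computes

**Classification.** ERF-family candidates are proteins with exactly one
AP2 domain (one AP2 + one B3 = RAV; two or more AP2 = AP2 family). DREB
candidates among them carry valine at the 14th position of the AP2
domain (glutamate at the 19th is recorded, not enforced — V14 is the
decisive binding residue). Subgroups A-1..A-6 are assigned on a
neighbor-joining tree (p-distance, Saitou–Nei agglomeration, bootstrap
bipartition supports) from labeled reference proteins: each query takes
the label of the smallest label-homogeneous clade containing it and a
reference, falling back to the nearest labeled leaf by path length.
Nine published conserved motifs (CM1–CM3 core, CM6/CM8/CM10/CM13/CM14
subgroup signatures) are scanned by Hamming distance and validated
against the expected subgroup layout.

**Genome mapping.** Tandem duplicates are same-chromosome gene pairs
within 100 kb separated by at most five gene loci. Each gene's nearest
SNP minimizes |TSS − position|; assignments are deduplicated to the
nonredundant marker set with shared markers flagged.

**Diversity.** SNPs are alignment columns with two or more unmasked
non-gap alleles (bases below quality 20 are masked); maximal gap runs
are INDELs (in-frame when the span is divisible by 3). Per site,
PIC = 1 − Σᵢ pᵢ² over allele frequencies. Haplotypes are complete-case
allele tuples across sites. Codon-aligned ORF pairs yield
synonymous/nonsynonymous substitution counts, inserted/deleted residue
counts and longest residue runs. Genotype matrices feed an
allele-mismatch distance and classical PCoA.

**Expression.** Per-well amplification efficiency E = 10^slope from the
best log-linear window of 4–6 cycles (accepted when 1.8 ≤ E ≤ 2.0 and
r ≥ 0.995), Cq at a common per-gene threshold, concentration
C = E^(ΔCq), relative expression RE = C_target / geomean(C_references)
(equal to 2^−ΔΔCq when E = 2), and a fixed-reallocation randomization
test (2000 reallocations, add-one two-sided p).

Seeded generators (`gen_protein_family`, `gen_genotype_panel`,
`gen_amplification_curves`, `gen_gene_map`) emulate every input with a
recorded truth, so the whole pipeline runs offline.

## Worked example

```r
library(pvdreb)

## classification: a synthetic family with the published subgroup sizes
fam  <- gen_protein_family(seed = 1)           # 54 members + refs + decoys
crit <- apply_dreb_criteria(fam$proteins, fam$domains)
attr(classify_family(fam$proteins, fam$domains), "counts")
#> ERF_candidate           RAV    AP2_family         other
#>            66             3             5             3
head(crit$audit[crit$audit$retained, c("protein_id", "residue14",
                                       "residue19", "status")], 3)
#>   protein_id residue14 residue19       status
#> 1   PV_A1_01         V         E canonical_VE
#> 2   PV_A1_02         V         E canonical_VE
#> 3   PV_A1_03         V         E canonical_VE

## diversity: an 11-vs-6 two-pool panel with one diagnostic SNP and a
## 9-nt in-frame insertion
gp <- gen_genotype_panel(seed = 1)
call_variants(gp$panel)[, c("position", "span", "type", "alleles", "pic")]
#>   position span  type      alleles       pic
#> 1       33    1   SNP     G=11/C=6 0.4567474
#> 2      151    9 INDEL ins=11/del=6 0.4567474
count_haplotypes(gp$panel, call_variants(gp$panel))$n_haplotypes
#> [1] 2
consequences(gp$orf_andean, gp$orf_mesoamerican)
#> consequence_report: 0 nonsynonymous / 1 synonymous substitutions;
#> 3 residue(s) inserted, 0 deleted

## expression: a planted 3-cycle Cq shift at E = 2 is an 8-fold ratio
g <- gen_amplification_curves(true_e  = c(TARGET = 2, REF1 = 2, REF2 = 2),
                              delta_cq = c(TARGET = 3, REF1 = 0, REF2 = 0),
                              noise_sd = 0, cq_sd = 0, seed = 1)
run_expression(g$plate, "TARGET", c("REF1", "REF2"),
               n_perm = 2000, seed = 1)$result
#> expression_result: TARGET RE = 7.909 (log2 = 2.983), p = 0.1024
```

The PIC value 0.4567 is 1 − (11/17)² − (6/17)² for the 11/6 allele
split; the haplotype count 2 reflects the single pool-diagnostic site;
the three inserted residues are the glutamines encoded by the 9-nt
in-frame insertion; RE ≈ 8 = 2³ recovers the planted Cq shift, and the
p-value sits at the granularity floor of a 3-vs-3 replicate design
(see the methods vignette).

## Layout

- `R/` — io (`read_sequences`, `read_gene_table`, ...), classification
  (`classify_family`, `apply_dreb_criteria`), phylogeny
  (`neighbor_joining`, `bootstrap_support`, `assign_subgroups`), motifs
  (`scan_motif`, `validate_signatures`), mapping
  (`find_tandem_duplicates`, `nearest_snp`, `deduplicate_markers`),
  diversity (`call_variants`, `pic`, `count_haplotypes`,
  `consequences`, `genetic_distance`, `pcoa`), qPCR (`fit_efficiency`,
  `relative_expression`, `randomization_test`, `rwc`,
  `catalase_rate`), generators (`gen_*`), and stage orchestrators
  (`run_classify`, `run_map`, `run_diversity`, `run_expression`).
- `vignettes/pvdreb-methods.Rmd` — the models, parameter choices,
  numerical conventions and limitations.
- `tests/testthat/` — unit, property and end-to-end tests with
  independent brute-force oracles.
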