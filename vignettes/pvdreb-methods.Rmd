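---
title: "Methods: categorizing DREB genes and quantifying their diversity and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: categorizing DREB genes and quantifying their diversity and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvdreb)
```

# Scope

`pvdreb` reimplements, as tested R functions, the computational workflow
used to categorize the DREB (dehydration-responsive element-binding)
subfamily of AP2/ERF transcription factors in a plant genome and to
characterize candidate genes downstream: genomic placement relative to
SNP markers, nucleotide diversity of resequenced alleles, and
stress-response expression from qPCR. Every stage consumes plain-text
inputs (FASTA/FASTQ, headered TSV/CSV, newick) and is driven by seeded
generators that emulate each input type, so the full pipeline runs and
is testable offline.

Deliberately out of scope: BLAST-based ortholog search (reference labels
are inputs), HMM domain detection (domain annotations are inputs,
e.g. from PFAM/SMART), de novo motif discovery, progressive multiple
alignment (aligned panels are inputs), GO annotation, microarray
intensity processing, and plotting beyond coordinate tables.

# Classification (criteria 1, 3, 4, 5)

**Family classification.** AP2/ERF proteins are classed from their
annotated domain content: one AP2 domain and no B3 domain makes an ERF
candidate, one AP2 plus one B3 a RAV protein, two or more AP2 domains
an AP2-family protein. `classify_family()` applies these rules and
reports per-class counts.

**Residue rule.** DREB proteins carry valine at the 14th and usually
glutamic acid at the 19th position of the AP2 domain, whereas ERF
proteins typically carry alanine and aspartate there. Positions are
indexed 1-based from the annotated domain start, which matters when
mixing annotation sources whose domain starts differ by a few residues.
Retention is keyed on V14 alone: known DREB proteins exist with
glutamine at position 19, so E19 is recorded
(`canonical_VE` / `V_with_variant_19`) but never used as a hard filter.

**Phylogeny.** Distances between aligned peptides are p-distances
(mismatches over gap-free compared columns; a Poisson-corrected variant
is available via `model = "poisson"`). Trees are built by the standard
Saitou–Nei neighbor-joining agglomeration. Numerical conventions, all
chosen for determinism:

* ties in the Q-criterion are broken by the lexicographically smallest
  index pair, and the freshly merged cluster is appended after the
  remaining ones;
* negative branch lengths are clamped to zero with the deficit moved to
  the sibling branch (the convention popular desktop phylogeny software
  uses), and the number of clamped branches is reported;
* additive distance matrices are reproduced exactly by tree path
  lengths (tested to 1e-9), and topologies agree with an independent NJ
  implementation on random matrices.

**Bootstrap.** Alignment columns are resampled with replacement; the
support of an internal edge is the fraction of replicate NJ trees
containing the same bipartition, stored in `[0, 1]` as internal node
labels. Taxa are put in canonical (sorted) order before resampling so
supports cannot depend on input order through index-based tie breaks.
The pipeline default is 1000 replicates; tests use 5–100 because the
statistical behavior under test (diagnostic columns giving support
near 1, determinism under a fixed seed) is already visible there.

**Subgroup assignment.** The source analyses cut the tree into
subgroups A-1..A-6 by eye against labeled reference proteins; no formal
rule was published. The package's explicit formalization: a query takes
the label of the smallest clade (bipartition side) containing it and at
least one reference, provided that clade's references are
label-homogeneous; otherwise the nearest labeled leaf by path length
decides, with ties broken by the smallest mean path distance to the
tied label's references and then lexicographic label order. The rule is
deterministic given the tree and labels.

**Motifs.** Nine conserved motifs (CM) with published consensus strings
are built in: CM1/CM2/CM3/CM7 inside the AP2 domain, CM6 (A-2 marker),
CM8 (A-5), CM10 and CM13 (A-6), and CM14 (N-terminal in A-2,
C-terminal in A-4). The remaining motifs of the original 14-motif set
have no public consensus and can be supplied as a TSV. Scanning is a
Hamming-distance window scan; the default mismatch budget is
`floor(length / 5)` (20% divergence), configurable per motif — the
original study used probabilistic motif discovery, which prints only
consensus strings, so a consensus scan with a divergence budget is the
reproducible equivalent. A hit's position class is N-terminal when its
relative start position (start over number of possible windows) is
below 0.5. `validate_signatures()` checks the published layout
(CM1–CM3 everywhere; CM6 exactly in A-2; CM8/CM10/CM13 nowhere outside
their subgroups; CM14 position classes) and lists each violation.

# Genomic mapping

Two genes are tandem duplicates when they lie on the same chromosome
within 100 kb and are separated by at most five annotated gene loci
(both thresholds configurable). The gene anchor for all distance rules
is the stored transcription start coordinate; intervening loci are
counted from the full annotation, not just the focal genes. The
nearest SNP to each gene is the same-chromosome marker minimizing the
unsigned TSS distance (ties: smaller coordinate, then lexicographic
id). `deduplicate_markers()` collapses assignments to distinct SNP ids
and flags markers serving two or more genes, mirroring the published
54-assignments-to-51-markers reduction.

# Diversity

**Variant calling.** A panel is an equal-length alignment with sample
ids and gene-pool labels. A column is a SNP when at least two distinct
non-gap alleles remain among included samples after masking bases with
quality below 20 (the published Sanger-quality cutoff; panels without
qualities are taken at face value). Maximal per-sample gap runs form
INDELs, with `frame_preserving` set when the span is divisible by 3.
Outgroup samples are excluded from allele counting via
`exclude_samples`, mirroring how the tepary-bean outgroup was kept out
of the common-bean comparisons.

**PIC.** The published formula is printed as `1 − Σ(1 − p_i²)`, which
is algebraically degenerate (negative whenever there are two or more
alleles); the package implements the gene-diversity form
`1 − Σ p_i²` that the printed expression almost certainly intends, and
keeps the literal form behind `strict_formula = TRUE` for audit. The
published per-gene average PIC values cannot be recomputed from public
data (the genotype matrices are unpublished), and the single-SNP value
0.475 is inconsistent with an 11/6 split under any standard estimator
(which gives 0.457); the package therefore treats those averages as
non-reproducible and does not target them.

**Haplotypes.** A haplotype is the tuple of alleles a sample carries
across the variant sites; samples missing any allele (gap or masked
base at a SNP, partial gap pattern at an INDEL) are dropped
(complete-case), matching how haplotype counters treat incomplete
sequences.

**Consequences.** Two ORF alleles are globally aligned at the
nucleotide level (affine gap penalties chosen to keep a single
insertion contiguous); codons comparable in both frames are translated
under the standard genetic code and classified synonymous or
nonsynonymous; in-frame gap runs are converted to inserted/deleted
residue counts, and any gap run not divisible by 3 flags a frameshift.
The longest single-residue runs per translation expose poly-amino-acid
tract changes such as a glutamine tract growing from 4 to 7 units
after a 9-nt insertion. Note the source text prints that insertion's
sequence as 10 nt while calling it 9 bp and three glutamines; the
package reports whatever span is observed in the alignment, and its
generator plants the 9-nt, three-codon version consistent with the
residue counts.

**Distance and ordination.** Genotype distance is the pairwise-complete
allele-mismatch fraction (the exact variant used by the original
spreadsheet macro is unpublished, so the simplest allele-sharing form
is the default). PCoA is classical metric scaling (square, double
center, eigendecompose); negative eigenvalues are reported and never
used, and Euclidean inputs are reproduced to 1e-8.

# qPCR expression

**Model.** Each well's fluorescence curve is baseline-corrected by the
mean of cycles 1–8, and the per-cycle amplification factor `E` is
`10^slope` of the best log-linear window of 4–6 consecutive cycles
(window-of-linearity practice; the source software's window length is
unpublished). A fit is accepted when `1.8 ≤ E ≤ 2.0` and the window
correlation is at least 0.995 — the published acceptance thresholds.

**Window selection.** Candidate windows must lie in the exponential
phase: above a noise floor (the larger of 10 standard deviations of
the corrected baseline cycles and 0.01% of the curve maximum) and
below 5% of the curve maximum. Points near the baseline carry a
relative error from baseline subtraction that inflates the slope;
points near the plateau are curved downward. Among candidates, windows
whose correlation is within four times the best window's distance from
`r = 1` are treated as statistically equivalent, and the longest, then
highest-signal, then earliest window wins. This banded rule was chosen
over a strict per-window argmax because, under multiplicative noise,
the strict rule prefers short low-signal windows and measurably biases
recovery (mean absolute error 0.020/0.085 at 1%/5% noise on generator
curves, versus 0.011/0.028 for the banded rule, which also recovers
noiseless curves to better than 1e-3).

**Cq and relative expression.** Cq is where the window's regression
line crosses a threshold placed at the window's geometric midpoint (a
fixed user threshold is also accepted). Because Cq values are only
comparable at a common threshold, the expression stage re-derives every
well's Cq at the gene-wise geometric-mean threshold before comparing
conditions. Per gene, the expression concentration is
`C = E^(mean Cq_control − mean Cq_treated)`; relative expression is
`RE = C_target / geometric mean of C_references`, reported both as a
ratio and as `log2(RE)` (published fold changes are stated in log2
units, and the ratio-vs-log ambiguity in such statements is why both
are always reported). With `E = 2` everywhere this reduces exactly to
the classical `2^−ΔΔCq`.

**Randomization test.** Significance uses a fixed-reallocation
randomization test: control/treated labels are reallocated among whole
replicate samples, jointly across genes (a sample's Cq moves with it in
every gene), keeping group sizes fixed; the two-sided p-value uses the
add-one estimator `(1 + #{|perm| ≥ |obs|}) / (1 + n_perm)` with 2000
reallocations by default, so p is never zero. An `exhaustive = TRUE`
mode enumerates all balanced reallocations for small designs and is
the oracle the sampled mode is tested against.

A granularity caveat worth knowing: with the triplicate design used on
the plates, only `C(6,3) = 20` balanced reallocations exist, the
observed statistic and its complement are always among them, and the
smallest attainable two-sided p is about 0.1 — the test is valid but
conservative at that scale. The package's type-I calibration is
therefore run at 6 control + 6 treated replicates (924 reallocations,
near-uniform p under the null), where the empirical rejection rate at
α = 0.05 over 1000 seeded null simulations falls within [0.03, 0.07].

**Physiology helpers.** `rwc()` is the exact relative-water-content
formula `100 (FW − DW)/(TW − DW)`; `catalase_rate()` converts the
least-squares absorbance slope over a timed series to
µmol·min⁻¹·mg⁻¹ protein via Beer–Lambert. The extinction coefficient
is a required input (assay-specific; none is baked in).

# Synthetic data: what it emulates and what it does not

All generators are pure functions of their arguments plus a seed and
return a machine-readable truth record; recovery tests always compare
against the recorded truth, never against re-derived values.

* `gen_protein_family()` plants, per subgroup, an AP2 domain (19-residue
  prefix carrying V14/E19, then CM3/CM2/CM1) and the subgroup signature
  motifs at fixed positions, on top of subgroup ancestors diverged by
  point substitution (3% within subgroups by default). Defaults
  reproduce the published subgroup sizes 17/8/1/10/10/8 (54 members)
  plus labeled references and RAV/AP2-family/domain-less decoys. Motif
  plants overwrite fixed windows so peptides stay equal-length and can
  feed the distance stage without alignment.
* `gen_genotype_panel()` builds a 474-bp ORF shared by 11 Mesoamerican
  and 6 Andean samples (the resequencing panel sizes), plants
  pool-diagnostic SNPs (avoiding stop codons), the 9-nt in-frame
  glutamine insertion carried by one pool, optionally an outgroup with
  private alleles, and a genotype matrix whose diagnostic fraction
  separates the pools.
* `gen_amplification_curves()` produces logistic-plateau curves whose
  early exponential phase amplifies by the planted `E`, with
  multiplicative log-normal noise (1% by default, matching how
  plateau-phase noise scales) and replicate Cq scatter.
* `gen_gene_map()` lays out focal genes in 1-Mb blocks: tandem pairs
  satisfying both thresholds, distractor pairs violating exactly one,
  shared-SNP pairs placed beyond tandem range, and background loci.

None of the generators simulate realistic molecular evolution: no
substitution model, no codon-usage bias, no recombination, no
quality-by-position decay, no pipetting structure in the plates.
Passing recovery tests therefore demonstrates that the algorithms
recover planted structure under the stated noise models — not that
they are robust to every artifact of real Sanger traces, BeadChip
intensities or plate chemistry.

# Problem sizes and runtime choices

The shipped tests run the full family (54 + references) through
classification with small bootstrap counts, 200 seeded curves for
efficiency recovery, 1000 null simulations of 2000 reallocations for
calibration, and oracle comparisons at a few hundred genes/SNPs —
sizes at which every statistical property under test is already
expressed, keeping the whole suite in a few minutes on one CPU. The
genome-wide published counts (184 AP2-containing unigenes, 157
single-AP2, the 54 loci, the real marker distances) depend on external
proteome and BeadChip downloads and are intentionally not recomputed.

# Known limitations

* Subgroup assignment depends on reference coverage: a subgroup with no
  reference in the tree can never be assigned.
* The nearest-SNP rule uses the TSS only; a SNP inside a gene body but
  far from the TSS is treated no differently from an intergenic one.
* `consequences()` assumes both sequences are ORFs starting in frame 0;
  it flags but does not resolve frameshifts, and truncates translation
  at internal stops with a warning.
* The efficiency estimator assumes a sigmoid curve with a flat early
  baseline; chemistry with drifting baselines needs the fixed-threshold
  mode and external baseline handling.
* The tandem rule is pairwise only; chains of three or more nearby
  paralogs are reported as their qualifying pairs, with no transitive
  grouping.
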