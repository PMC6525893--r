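# Stage orchestrators chaining the modules end to end. Outputs are a
# pure function of (inputs, parameters, seed); when `out_dir` is given,
# every file carries a provenance comment (package version, seed, key
# parameters).

provenance_line <- function(seed, params) {
  paste0("pvdreb ", as.character(packageVersion("pvdreb")),
         " | seed=", seed, " | ",
         paste(names(params), unlist(params), sep = "=", collapse = " "))
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the classification stage (criteria 1, 3, 4, 5)
#'
#' Chains domain filtering, the V14 residue rule, p-distance +
#' neighbor-joining with bootstrap supports, reference-anchored
#' subgroup assignment and motif signature validation over the retained
#' DREB candidates.
#'
#' @param proteins a [seq_set] of peptides (queries and labeled
#'   references, all aligned-length or independently scannable).
#' @param domains domain annotation data frame.
#' @param reference_labels named character vector mapping reference ids
#'   to subgroup labels (required).
#' @param candidate_ids optional allow-list (criterion 2/4 surrogate).
#' @param motifs motif definition table (default [builtin_motifs]).
#' @param bootstrap bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param out_dir optional output directory for TSV/newick reports.
#' @return A list: `audit`, `retained`, `tree` (with supports),
#'   `assignments`, `profile`, `violations`.
#' @export
run_classify <- function(proteins, domains, reference_labels,
                         candidate_ids = NULL, motifs = builtin_motifs(),
                         bootstrap = 1000, seed = 1, out_dir = NULL) {
  if (is.null(reference_labels) || length(reference_labels) == 0)
    stop("[phylo] missing reference labels for subgroup assignment")
  crit <- stage_error("domain_filter",
                      apply_dreb_criteria(proteins, domains, candidate_ids))
  retained <- crit$retained
  if (length(retained) == 0) stop("[domain_filter] no proteins retained")
  tree_ids <- union(retained, intersect(names(reference_labels),
                                        names(proteins)))
  aln <- seq_set(proteins$sequences[tree_ids])
  tree <- stage_error("phylo",
                      bootstrap_support(aln, n_replicates = bootstrap,
                                        seed = seed))
  assignments <- stage_error("phylo",
                             assign_subgroups(tree, reference_labels))
  retained_queries <- setdiff(retained, names(reference_labels))
  assignments <- assignments[assignments$query %in% retained_queries, ,
                             drop = FALSE]
  retained_set <- seq_set(proteins$sequences[retained_queries])
  prof <- stage_error("motifs", motif_profile(retained_set, motifs))
  violations <- stage_error("motifs",
                            validate_signatures(prof, assignments))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- provenance_line(seed, list(stage = "classify",
                                       bootstrap = bootstrap))
    write_tsv(crit$audit, file.path(out_dir, "audit.tsv"), prov)
    write_tsv(assignments, file.path(out_dir, "assignments.tsv"), prov)
    write_tsv(prof$hits, file.path(out_dir, "motif_hits.tsv"), prov)
    write_tsv(violations, file.path(out_dir, "violations.tsv"), prov)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
  }
  list(audit = crit$audit, retained = retained, tree = tree,
       assignments = assignments, profile = prof,
       violations = violations)
}

#' Run the genome-mapping stage
#'
#' Tandem-duplicate detection and nearest-SNP assignment with
#' deduplication over a set of focal genes.
#'
#' @param genes gene locus data frame (all annotated loci).
#' @param snps SNP marker data frame.
#' @param focal_ids focal gene ids.
#' @param max_distance_bp,max_intervening tandem thresholds (defaults
#'   100 kb / 5 loci).
#' @param out_dir optional output directory.
#' @return A list: `tandem_pairs`, `assignments`, `snp_ids`,
#'   `n_nonredundant`.
#' @export
run_map <- function(genes, snps, focal_ids, max_distance_bp = 100000,
                    max_intervening = 5, out_dir = NULL) {
  tandem <- stage_error("genome_map",
                        find_tandem_duplicates(genes, focal_ids,
                                               max_distance_bp,
                                               max_intervening))
  assign <- stage_error("genome_map", nearest_snp(genes, snps, focal_ids))
  dedup <- deduplicate_markers(assign)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- provenance_line(NA, list(stage = "map",
                                     max_distance_bp = max_distance_bp,
                                     max_intervening = max_intervening))
    write_tsv(tandem, file.path(out_dir, "tandem_pairs.tsv"), prov)
    write_tsv(dedup$assignments,
              file.path(out_dir, "marker_assignments.tsv"), prov)
  }
  list(tandem_pairs = tandem, assignments = dedup$assignments,
       snp_ids = dedup$snp_ids, n_nonredundant = dedup$n_nonredundant)
}

#' Run the diversity stage
#'
#' Variant calling with PIC, haplotype counting, optional codon-level
#' consequence calling between two ORF alleles, and PCoA of a genotype
#' matrix.
#'
#' @param panel an [aligned_panel].
#' @param genotypes optional samples x markers genotype matrix for
#'   genetic distance + PCoA.
#' @param orf_pair optional character vector of two ungapped ORFs for
#'   [consequences].
#' @param min_quality base-quality mask threshold (default 20).
#' @param exclude_samples samples excluded from allele counting (e.g.
#'   the outgroup).
#' @param n_axes PCoA axes (default 2).
#' @param out_dir optional output directory.
#' @return A list: `variants`, `haplotypes`, `consequences` (or NULL),
#'   `pcoa` (or NULL).
#' @export
run_diversity <- function(panel, genotypes = NULL, orf_pair = NULL,
                          min_quality = 20,
                          exclude_samples = character(0), n_axes = 2,
                          out_dir = NULL) {
  variants <- stage_error("diversity",
                          call_variants(panel, min_quality,
                                        exclude_samples))
  if (nrow(variants) == 0) stop("[diversity] no variant sites in panel")
  haps <- stage_error("diversity",
                      count_haplotypes(panel, variants, min_quality,
                                       exclude_samples))
  cons <- if (!is.null(orf_pair))
    stage_error("diversity", consequences(orf_pair[1], orf_pair[2]))
  pc <- if (!is.null(genotypes))
    stage_error("diversity", pcoa(genetic_distance(genotypes), n_axes))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- provenance_line(NA, list(stage = "diversity",
                                     min_quality = min_quality))
    write_tsv(variants, file.path(out_dir, "variants.tsv"), prov)
    write_tsv(haps$haplotypes, file.path(out_dir, "haplotypes.tsv"), prov)
    if (!is.null(pc))
      write_tsv(data.frame(sample = rownames(pc$coordinates),
                           pc$coordinates),
                file.path(out_dir, "pcoa.tsv"), prov)
  }
  list(variants = variants, haplotypes = haps, consequences = cons,
       pcoa = pc)
}

#' Run the expression stage
#'
#' Per-gene efficiency fitting from amplification curves (or
#' precomputed Cq values), relative expression against the
#' reference-gene geometric mean and the fixed-reallocation
#' randomization test.
#'
#' @param plate plate data frame (see [read_plate]): either per-cycle
#'   fluorescence rows or precomputed `cq` rows.
#' @param target target gene name.
#' @param references reference gene names.
#' @param n_perm randomization-test permutations (default 2000).
#' @param seed integer seed.
#' @param efficiency optional named per-gene efficiencies; when absent
#'   they are estimated per well and averaged per gene.
#' @param out_dir optional output directory.
#' @return A list: `fits` (per-well efficiency fits, or NULL when Cq
#'   values were supplied), `cq` (Cq table), `result`
#'   (`expression_result` with p-value).
#' @export
run_expression <- function(plate, target, references, n_perm = 2000,
                           seed = 1, efficiency = NULL, out_dir = NULL) {
  fits <- NULL
  if ("cq" %in% names(plate)) {
    cq <- plate[, c("gene", "sample", "condition", "cq")]
  } else {
    stage_error("qpcr", {
      wells <- unique(plate$well)
      fits <- lapply(wells, function(w) {
        d <- plate[plate$well == w, ]
        d <- d[order(d$cycle), ]
        fit <- fit_efficiency(d$fluorescence)
        data.frame(well = w, gene = d$gene[1], sample = d$sample[1],
                   condition = d$condition[1],
                   efficiency = fit$efficiency, slope = fit$slope,
                   intercept = fit$intercept, r = fit$r, cq = fit$cq,
                   threshold = fit$threshold, accepted = fit$accepted,
                   stringsAsFactors = FALSE)
      })
      fits <- do.call(rbind, fits)
      # Cq values are only comparable at a common threshold: re-derive
      # each well's Cq from its window regression line at the gene-wise
      # geometric-mean threshold
      for (g in unique(fits$gene)) {
        sel <- fits$gene == g
        thr <- exp(mean(log(fits$threshold[sel])))
        fits$threshold[sel] <- thr
        fits$cq[sel] <- (log10(thr) - fits$intercept[sel]) /
          fits$slope[sel]
      }
    })
    cq <- fits[, c("gene", "sample", "condition", "cq")]
    if (is.null(efficiency))
      efficiency <- tapply(fits$efficiency, fits$gene, mean)
  }
  if (is.null(efficiency))
    stop("[qpcr] efficiencies required when plate supplies Cq values")
  result <- stage_error("qpcr",
                        randomization_test(cq, target, references,
                                           efficiency, n_perm = n_perm,
                                           seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- provenance_line(seed, list(stage = "expression",
                                       n_perm = n_perm))
    if (!is.null(fits))
      write_tsv(fits, file.path(out_dir, "efficiency_fits.tsv"), prov)
    write_tsv(data.frame(gene = result$target, re = result$re,
                         log2_re = result$log2_re,
                         p_value = result$p_value),
              file.path(out_dir, "expression.tsv"), prov)
  }
  list(fits = fits, cq = cq, result = result)
}
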