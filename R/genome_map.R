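# Tandem-duplication detection and nearest-SNP assignment. The gene
# anchor for both rules is the stored TSS coordinate; distances are
# unsigned, with upstream/downstream reported as a sign column only.

#' Detect tandemly duplicated gene pairs
#'
#' Two focal genes are called tandem duplicates when they lie on the
#' same chromosome within `max_distance_bp` of each other (TSS to TSS)
#' and are separated by at most `max_intervening` annotated gene loci.
#' Intervening loci are counted from the full gene table, not only the
#' focal genes.
#'
#' @param genes gene locus data frame (`gene_id`, `chromosome`,
#'   `strand`, `tss`); must contain every annotated locus so that
#'   intervening genes can be counted.
#' @param focal_ids gene ids to test pairwise (must all be in `genes`).
#' @param max_distance_bp maximum TSS separation (default 100 kb).
#' @param max_intervening maximum number of gene loci strictly between
#'   the pair (default 5).
#' @return A data frame of unordered pairs: `gene_a`, `gene_b`
#'   (`gene_a < gene_b` lexicographically), `chromosome`,
#'   `distance_bp`, `n_intervening`.
#' @export
find_tandem_duplicates <- function(genes, focal_ids,
                                   max_distance_bp = 100000,
                                   max_intervening = 5) {
  missing_ids <- setdiff(focal_ids, genes$gene_id)
  if (length(missing_ids))
    stop("focal id(s) missing from gene table: ",
         paste(missing_ids, collapse = ", "))
  focal <- genes[match(focal_ids, genes$gene_id), , drop = FALSE]
  out <- list()
  for (chr in unique(focal$chromosome)) {
    f <- focal[focal$chromosome == chr, , drop = FALSE]
    f <- f[order(f$gene_id), , drop = FALSE]
    if (nrow(f) < 2) next
    all_tss <- genes$tss[genes$chromosome == chr]
    all_ids <- genes$gene_id[genes$chromosome == chr]
    for (i in seq_len(nrow(f) - 1)) {
      for (j in (i + 1):nrow(f)) {
        d <- abs(f$tss[i] - f$tss[j])
        if (d > max_distance_bp) next
        lo <- min(f$tss[i], f$tss[j]); hi <- max(f$tss[i], f$tss[j])
        between <- all_tss > lo & all_tss < hi &
          !(all_ids %in% c(f$gene_id[i], f$gene_id[j]))
        n_between <- sum(between)
        if (n_between > max_intervening) next
        out[[length(out) + 1L]] <- data.frame(
          gene_a = f$gene_id[i], gene_b = f$gene_id[j],
          chromosome = chr, distance_bp = d, n_intervening = n_between,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene_a = character(0), gene_b = character(0),
               chromosome = character(0), distance_bp = numeric(0),
               n_intervening = integer(0))
}

#' Nearest SNP marker to each gene's transcription start site
#'
#' For every focal gene, finds the same-chromosome SNP minimizing the
#' unsigned distance to the TSS. Ties are broken by the smaller SNP
#' coordinate, then lexicographic `snp_id`. Genes on chromosomes
#' without SNPs get an `NA` assignment with a warning.
#'
#' @param genes gene locus data frame.
#' @param snps SNP marker data frame (`snp_id`, `chromosome`,
#'   `position`).
#' @param focal_ids gene ids to assign.
#' @return A data frame: `gene_id`, `snp_id`, `distance_bp`, `sign`
#'   (`+1` when the SNP is downstream of the TSS coordinate, `-1`
#'   upstream, `0` on top of it), `shared` (set by
#'   [deduplicate_markers], `NA` here).
#' @export
nearest_snp <- function(genes, snps, focal_ids) {
  missing_ids <- setdiff(focal_ids, genes$gene_id)
  if (length(missing_ids))
    stop("focal id(s) missing from gene table: ",
         paste(missing_ids, collapse = ", "))
  focal <- genes[match(focal_ids, genes$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = focal$gene_id, snp_id = NA_character_,
                    distance_bp = NA_real_, sign = NA_real_,
                    shared = NA, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(focal))) {
    s <- snps[snps$chromosome == focal$chromosome[k], , drop = FALSE]
    if (nrow(s) == 0L) {
      warning("no SNP on chromosome ", focal$chromosome[k],
              " for gene ", focal$gene_id[k])
      next
    }
    d <- abs(s$position - focal$tss[k])
    ord <- order(d, s$position, s$snp_id)
    best <- ord[1]
    out$snp_id[k] <- s$snp_id[best]
    out$distance_bp[k] <- d[best]
    out$sign[k] <- sign(s$position[best] - focal$tss[k])
  }
  out
}

#' Deduplicate nearest-SNP assignments
#'
#' Collapses marker assignments to the distinct set of SNP ids and
#' flags every assignment whose SNP is the nearest marker to two or
#' more genes.
#'
#' @param assignments data frame from [nearest_snp].
#' @return A list with `snp_ids` (distinct non-NA SNP ids),
#'   `n_nonredundant`, and `assignments` (input with the `shared` flag
#'   filled in).
#' @export
deduplicate_markers <- function(assignments) {
  ok <- !is.na(assignments$snp_id)
  tab <- table(assignments$snp_id[ok])
  assignments$shared[ok] <- tab[assignments$snp_id[ok]] >= 2
  list(snp_ids = sort(names(tab)), n_nonredundant = length(tab),
       assignments = assignments)
}
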