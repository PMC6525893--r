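# Criteria 1 and 3 of the five-criteria DREB categorization scheme:
# single-AP2-domain family classification and the 14th/19th residue rule.
#
# Domain positions are 1-based from the annotated domain start. PFAM and
# SMART annotations can place the AP2 start a few residues apart; the
# residue rule indexes into whatever start the supplied annotation uses,
# so mixed-source annotation tables should be harmonized upstream.

#' Classify proteins into AP2/ERF families from domain annotations
#'
#' Applies the family definitions used throughout the AP2/ERF
#' literature: exactly one AP2 domain and no B3 domain makes an ERF
#' candidate; one AP2 plus one B3 is a RAV protein; two or more AP2
#' domains is an AP2-family protein; everything else is `other`.
#'
#' @param proteins a [seq_set] of peptides.
#' @param domains domain annotation data frame with columns
#'   `protein_id`, `domain_name`, `start`, `end` (1-based inclusive).
#'   Proteins absent from the table count as having zero domains.
#' @return A data frame (one row per protein): `protein_id`, `n_ap2`,
#'   `other_domains` (comma-separated), `class`. The per-class counts
#'   are attached as attribute `"counts"`.
#' @export
classify_family <- function(proteins, domains) {
  stopifnot(inherits(proteins, "seq_set"))
  ids <- names(proteins)
  unknown <- setdiff(domains$protein_id, ids)
  if (length(unknown))
    stop("domain table references unknown protein(s): ",
         paste(unique(unknown), collapse = ", "))
  plen <- nchar(proteins$sequences)
  oob <- domains$end > plen[match(domains$protein_id, ids)]
  if (any(oob))
    stop("domain out of sequence bounds for protein(s): ",
         paste(unique(domains$protein_id[oob]), collapse = ", "))
  is_ap2 <- toupper(domains$domain_name) == "AP2"
  is_b3 <- toupper(domains$domain_name) == "B3"
  n_ap2 <- vapply(ids, function(i)
    sum(is_ap2 & domains$protein_id == i), integer(1))
  has_b3 <- vapply(ids, function(i)
    any(is_b3 & domains$protein_id == i), logical(1))
  other <- vapply(ids, function(i)
    paste(unique(domains$domain_name[domains$protein_id == i & !is_ap2]),
          collapse = ","), character(1))
  class <- ifelse(n_ap2 >= 2, "AP2_family",
           ifelse(n_ap2 == 1 & has_b3, "RAV",
           ifelse(n_ap2 == 1, "ERF_candidate", "other")))
  out <- data.frame(protein_id = ids, n_ap2 = n_ap2,
                    other_domains = other, class = class,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(
    class, levels = c("ERF_candidate", "RAV", "AP2_family", "other")))
  out
}

#' Check the V14/E19 residue rule on an AP2 domain
#'
#' DREB proteins carry valine at the 14th and (usually) glutamic acid at
#' the 19th position of the AP2 domain, against alanine/aspartate in ERF
#' proteins. Valine at 14 is the decisive site for retention; the 19th
#' residue is recorded but tolerated when variant (a glutamine-at-19
#' DREB is known).
#'
#' @param sequence peptide sequence (character scalar).
#' @param start,end 1-based inclusive AP2 domain coordinates.
#' @return A list with `residue14`, `residue19`, `status` (one of
#'   `canonical_VE`, `V_with_variant_19`, `excluded_non_V14`) and
#'   `retained` (TRUE iff residue 14 is V).
#' @export
check_residue_rule <- function(sequence, start, end) {
  if (end - start + 1 < 19)
    stop("AP2 domain shorter than 19 residues (", end - start + 1, ")")
  if (start + 18 > nchar(sequence))
    stop("domain extends past end of sequence")
  r14 <- substr(sequence, start + 13L, start + 13L)
  r19 <- substr(sequence, start + 18L, start + 18L)
  status <- if (r14 != "V") "excluded_non_V14"
            else if (r19 == "E") "canonical_VE"
            else "V_with_variant_19"
  list(residue14 = r14, residue19 = r19, status = status,
       retained = r14 == "V")
}

#' Apply the DREB retention criteria and build an audit table
#'
#' Retains proteins that (criterion 1) carry exactly one AP2 domain and
#' no B3 domain, (criterion 3) have valine at AP2-domain position 14,
#' and (optionally) appear in a phylogeny-derived allow-list standing in
#' for criteria 2/4.
#'
#' @param proteins a [seq_set] of peptides.
#' @param domains domain annotation data frame (see [classify_family]).
#' @param candidate_ids optional character vector of allowed ids.
#' @return A list with `retained` (character vector of protein ids) and
#'   `audit` (data frame: `protein_id`, `n_ap2`, `class`, `residue14`,
#'   `residue19`, `status`, `retained`, `failed_criterion`).
#' @export
apply_dreb_criteria <- function(proteins, domains, candidate_ids = NULL) {
  fam <- classify_family(proteins, domains)
  n <- nrow(fam)
  audit <- data.frame(protein_id = fam$protein_id, n_ap2 = fam$n_ap2,
                      class = fam$class,
                      residue14 = NA_character_, residue19 = NA_character_,
                      status = NA_character_, retained = FALSE,
                      failed_criterion = NA_character_,
                      stringsAsFactors = FALSE)
  is_ap2 <- toupper(domains$domain_name) == "AP2"
  for (k in seq_len(n)) {
    id <- audit$protein_id[k]
    if (audit$class[k] != "ERF_candidate") {
      audit$failed_criterion[k] <- "criterion1_single_AP2"
      next
    }
    d <- domains[is_ap2 & domains$protein_id == id, , drop = FALSE]
    rule <- check_residue_rule(proteins$sequences[[id]], d$start[1], d$end[1])
    audit$residue14[k] <- rule$residue14
    audit$residue19[k] <- rule$residue19
    audit$status[k] <- rule$status
    if (!rule$retained) {
      audit$failed_criterion[k] <- "criterion3_non_V14"
      next
    }
    if (!is.null(candidate_ids) && !(id %in% candidate_ids)) {
      audit$failed_criterion[k] <- "not_in_candidate_list"
      next
    }
    audit$retained[k] <- TRUE
  }
  list(retained = audit$protein_id[audit$retained], audit = audit)
}
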