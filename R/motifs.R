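# Criterion 5: consensus-motif scanning and subgroup signature rules.
#
# Only the nine conserved motifs (CM) with a published consensus are
# built in; CM4/CM5/CM9/CM11/CM12 have no public consensus and CM15 is
# excluded as redundant with CM4. Users may scan extra motifs by
# supplying their own definition table.

#' Built-in conserved-motif definitions
#'
#' The nine published consensus motifs of the DREB subfamily. CM1, CM2,
#' CM3 and CM7 lie within the AP2 domain; CM6 marks subgroup A-2, CM8
#' marks A-5, CM10 and CM13 mark A-6, and CM14 occurs N-terminally in
#' A-2 and C-terminally in A-4.
#'
#' @param max_mismatch_fraction mismatches tolerated per motif as a
#'   fraction of its length (floored); default 0.2.
#' @return A data frame: `motif_id`, `consensus`, `max_mismatch`.
#' @export
builtin_motifs <- function(max_mismatch_fraction = 0.2) {
  consensus <- c(
    CM1  = "RIWLGTFPTPEMAARAYDVAAYCLKG",
    CM2  = "WGKWVCEIR",
    CM3  = "GGPENRHCVYRGVRQR",
    CM6  = "KKVPAKGWKKGCMRGK",
    CM7  = "EPRKK",
    CM8  = "DMSADSIRKKATQVGARVDALQTALHHH",
    CM10 = "LNHLTPPQVHQIQAQIQIQKQ",
    CM13 = "YWEDDSDHFNLQKYPSYEIDW",
    CM14 = "HSKGDGSKSVADTLAKWKEYNAQL")
  data.frame(motif_id = names(consensus), consensus = unname(consensus),
             max_mismatch = floor(nchar(consensus) * max_mismatch_fraction),
             stringsAsFactors = FALSE)
}

#' Read a user motif definition table
#'
#' Expects columns `motif_id`, `consensus`, `max_mismatch`.
#'
#' @param path TSV or CSV file path.
#' @return A validated motif data frame.
#' @export
read_motif_table <- function(path) {
  df <- read_table_auto(path)
  check_cols(df, c("motif_id", "consensus", "max_mismatch"), "motif")
  df$max_mismatch <- check_numeric_col(df, "max_mismatch", "motif")
  if (any(nchar(df$consensus) == 0)) stop("motif table: empty consensus")
  if (any(df$max_mismatch >= nchar(df$consensus)))
    stop("motif table: max_mismatch must be < consensus length")
  df
}

#' Scan a peptide for a consensus motif
#'
#' Reports every window whose Hamming distance to the consensus is at
#' most `max_mismatch`; the best hit (fewest mismatches, then leftmost)
#' is flagged primary.
#'
#' @param sequence peptide sequence (character scalar).
#' @param consensus motif consensus string.
#' @param max_mismatch tolerated mismatches per window.
#' @return A data frame: `start` (1-based), `mismatches`,
#'   `relative_position` (`start / (L - m + 1)`), `primary`. Zero rows
#'   (with a warning) when the protein is shorter than the motif.
#' @export
scan_motif <- function(sequence, consensus, max_mismatch = 0L) {
  L <- nchar(sequence)
  m <- nchar(consensus)
  empty <- data.frame(start = integer(0), mismatches = integer(0),
                      relative_position = numeric(0), primary = logical(0))
  if (L < m) {
    warning("protein shorter than motif; no scan performed")
    return(empty)
  }
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cm <- strsplit(consensus, "", fixed = TRUE)[[1]]
  nwin <- L - m + 1L
  # mismatch count per window: sum of per-offset mismatch indicators
  mis <- integer(nwin)
  for (k in seq_len(m))
    mis <- mis + (s[k:(k + nwin - 1L)] != cm[k])
  hits <- which(mis <= max_mismatch)
  if (length(hits) == 0L) return(empty)
  out <- data.frame(start = hits, mismatches = mis[hits],
                    relative_position = hits / nwin,
                    primary = FALSE)
  out$primary[order(out$mismatches, out$start)[1]] <- TRUE
  out
}

#' Motif presence/absence profile across proteins
#'
#' Scans every protein for every motif; presence is recorded with the
#' primary hit's position class (N-terminal when the relative position
#' of the hit is below 0.5, C-terminal otherwise).
#'
#' @param proteins a [seq_set] of peptides.
#' @param motifs motif definition data frame ([builtin_motifs] by
#'   default).
#' @return A list with `profile` (character matrix, proteins x motifs,
#'   entries `"absent"`, `"N-terminal"`, `"C-terminal"`) and `hits`
#'   (data frame of primary hits: `protein_id`, `motif_id`, `start`,
#'   `mismatches`, `relative_position`, `position_class`).
#' @export
motif_profile <- function(proteins, motifs = builtin_motifs()) {
  stopifnot(inherits(proteins, "seq_set"))
  ids <- names(proteins)
  prof <- matrix("absent", length(ids), nrow(motifs),
                 dimnames = list(ids, motifs$motif_id))
  hits <- list()
  for (i in seq_along(ids)) {
    for (k in seq_len(nrow(motifs))) {
      h <- suppressWarnings(
        scan_motif(proteins$sequences[[i]], motifs$consensus[k],
                   motifs$max_mismatch[k]))
      if (nrow(h) == 0L) next
      p <- h[h$primary, , drop = FALSE]
      cls <- if (p$relative_position < 0.5) "N-terminal" else "C-terminal"
      prof[i, k] <- cls
      hits[[length(hits) + 1L]] <- data.frame(
        protein_id = ids[i], motif_id = motifs$motif_id[k],
        start = p$start, mismatches = p$mismatches,
        relative_position = p$relative_position, position_class = cls,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(protein_id = character(0), motif_id = character(0),
               start = integer(0), mismatches = integer(0),
               relative_position = numeric(0),
               position_class = character(0))
  list(profile = prof, hits = hits)
}

#' Validate subgroup motif signature rules
#'
#' Checks the published signature rules against a motif profile and
#' subgroup assignments: CM1/CM2/CM3 must occur in every DREB protein;
#' CM6 occurs only (and in all) A-2 proteins; CM8 only in A-5; CM10 and
#' CM13 only in A-6; CM14, when present, is N-terminal in A-2 and
#' C-terminal in A-4.
#'
#' @param profile the `profile` matrix from [motif_profile] (or the
#'   list returned by it).
#' @param assignments data frame with columns `query` and `label`
#'   (e.g. from [assign_subgroups]) covering the profiled proteins.
#' @return A data frame of violations: `protein_id`, `motif_id`,
#'   `rule`, `subgroup`, `observed`. Zero rows when all rules hold.
#' @export
validate_signatures <- function(profile, assignments) {
  if (is.list(profile) && !is.matrix(profile)) profile <- profile$profile
  ids <- rownames(profile)
  lab <- setNames(assignments$label, assignments$query)
  if (!all(ids %in% names(lab)))
    stop("assignments do not cover all profiled proteins")
  lab <- lab[ids]
  viol <- list()
  add <- function(pid, motif, rule, subgroup, observed)
    viol[[length(viol) + 1L]] <<- data.frame(
      protein_id = pid, motif_id = motif, rule = rule,
      subgroup = subgroup, observed = observed, stringsAsFactors = FALSE)
  present <- function(motif) profile[, motif] != "absent"
  for (motif in intersect(c("CM1", "CM2", "CM3"), colnames(profile))) {
    for (pid in ids[!present(motif)])
      add(pid, motif, "core_motif_missing", lab[[pid]], "absent")
  }
  exclusive <- list(CM6 = "A-2", CM8 = "A-5", CM10 = "A-6", CM13 = "A-6")
  for (motif in intersect(names(exclusive), colnames(profile))) {
    home <- exclusive[[motif]]
    for (pid in ids[present(motif) & lab != home])
      add(pid, motif, "exclusivity", lab[[pid]], profile[pid, motif])
  }
  if ("CM6" %in% colnames(profile)) {
    for (pid in ids[!present("CM6") & lab == "A-2"])
      add(pid, "CM6", "subgroup_motif_missing", "A-2", "absent")
  }
  if ("CM14" %in% colnames(profile)) {
    for (pid in ids[present("CM14")]) {
      want <- switch(lab[[pid]], "A-2" = "N-terminal",
                     "A-4" = "C-terminal", NA_character_)
      if (!is.na(want) && profile[pid, "CM14"] != want)
        add(pid, "CM14", "position_class", lab[[pid]],
            profile[pid, "CM14"])
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(protein_id = character(0), motif_id = character(0),
               rule = character(0), subgroup = character(0),
               observed = character(0))
}
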