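# Variant discovery in aligned panels, diversity statistics (PIC,
# haplotypes), codon-level consequence calling, allele-sharing genetic
# distance and principal coordinate analysis.

#' Construct an aligned sequence panel
#'
#' Equal-length (gapped) sequences with sample ids, gene-pool labels
#' and optional per-base qualities.
#'
#' @param sequences named character vector of aligned sequences.
#' @param pools named character vector of gene-pool labels covering all
#'   samples (conventionally `"Andean"`, `"Mesoamerican"`,
#'   `"outgroup"`).
#' @param quality optional named list of integer quality vectors.
#' @return An object of class `aligned_panel`.
#' @export
aligned_panel <- function(sequences, pools, quality = NULL) {
  ss <- seq_set(sequences, quality)
  if (length(unique(nchar(sequences))) != 1)
    stop("panel sequences must be aligned to equal length")
  if (!all(names(sequences) %in% names(pools)))
    stop("pools must label every sample")
  structure(list(sequences = ss$sequences, quality = ss$quality,
                 pools = pools[names(sequences)]),
            class = "aligned_panel")
}

#' @export
print.aligned_panel <- function(x, ...) {
  cat("aligned_panel:", length(x$sequences), "samples x",
      nchar(x$sequences[[1]]), "columns;",
      paste(names(table(x$pools)), table(x$pools), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Polymorphic information content of a variant site
#'
#' The gene-diversity form `1 - sum(p_i^2)` over allele frequencies:
#' 0 for a monomorphic site, `(k - 1) / k` at equifrequency of k
#' alleles. `strict_formula = TRUE` evaluates the literal expression
#' `1 - sum(1 - p_i^2)` instead (an algebraically degenerate variant
#' that turns negative for two or more alleles), for auditing studies
#' that print that form.
#'
#' @param p allele frequencies (summing to 1) or allele counts
#'   (normalized internally).
#' @param strict_formula evaluate the degenerate literal form.
#' @return A single numeric value.
#' @export
pic <- function(p, strict_formula = FALSE) {
  if (length(p) == 0) stop("empty allele set")
  if (any(p < 0)) stop("negative allele frequency")
  tot <- sum(p)
  if (tot == 0) stop("empty allele set")
  if (abs(tot - 1) > 1e-9) p <- p / tot
  if (strict_formula) 1 - sum(1 - p^2) else 1 - sum(p^2)
}

# quality matrix aligned to the sequence matrix; Inf where absent
panel_quality_matrix <- function(panel, m) {
  q <- matrix(Inf, nrow(m), ncol(m), dimnames = dimnames(m))
  if (!is.null(panel$quality))
    for (id in rownames(m)) q[id, ] <- panel$quality[[id]]
  q
}

#' Call SNP and INDEL variants from an aligned panel
#'
#' A column is a SNP when at least two distinct non-gap alleles remain
#' among included samples after masking bases with quality below
#' `min_quality`. Maximal runs of gap columns in any included sample
#' form INDELs (span = run length). Excluded samples (e.g. an outgroup)
#' contribute no alleles.
#'
#' @param panel an [aligned_panel].
#' @param min_quality quality threshold; bases strictly below it are
#'   masked (default 20). Panels without qualities are taken at face
#'   value.
#' @param exclude_samples sample ids to drop from allele counting.
#' @param coding whether the panel is a coding alignment (sets
#'   `in_coding`).
#' @return A data frame, one row per variant site: `position` (1-based
#'   first alignment column), `end`, `span`, `type` (`"SNP"` or
#'   `"INDEL"`), `alleles` (`"allele=count"` pairs, `/`-separated),
#'   `n_alleles`, `pic`, `in_coding`, `frame_preserving` (INDELs only:
#'   span divisible by 3).
#' @export
call_variants <- function(panel, min_quality = 20,
                          exclude_samples = character(0),
                          coding = TRUE) {
  stopifnot(inherits(panel, "aligned_panel"))
  incl <- setdiff(names(panel$sequences), exclude_samples)
  if (length(incl) == 0) stop("all samples excluded")
  m <- as_char_matrix(panel$sequences[incl])
  q <- panel_quality_matrix(panel, m)
  gap <- m == "-" | m == "."
  masked <- q < min_quality
  rows <- list()
  emit <- function(position, end, type, counts) {
    counts <- sort(counts, decreasing = TRUE)
    rows[[length(rows) + 1L]] <<- data.frame(
      position = position, end = end, span = end - position + 1L,
      type = type,
      alleles = paste(names(counts), counts, sep = "=", collapse = "/"),
      n_alleles = length(counts),
      pic = pic(as.numeric(counts)),
      in_coding = coding,
      frame_preserving = if (type == "INDEL")
        (end - position + 1L) %% 3L == 0L else NA,
      stringsAsFactors = FALSE)
  }
  for (col in seq_len(ncol(m))) {
    use <- !gap[, col] & !masked[, col]
    if (!any(use)) next
    counts <- table(m[use, col])
    if (length(counts) >= 2) emit(col, col, "SNP", c(counts))
  }
  # maximal gap runs per sample, deduplicated across samples
  spans <- unique(do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    r <- rle(gap[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  })))
  if (!is.null(spans) && nrow(spans)) {
    spans <- spans[order(spans[, 1], spans[, 2]), , drop = FALSE]
    for (k in seq_len(nrow(spans))) {
      s <- spans[k, 1]; e <- spans[k, 2]
      pat <- apply(gap[, s:e, drop = FALSE], 1, function(g)
        if (all(g)) "del" else if (!any(g)) "ins" else NA_character_)
      counts <- table(pat[!is.na(pat)])
      if (length(counts) == 0) next
      emit(s, e, "INDEL", c(counts))
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    out[order(out$position, out$type), , drop = FALSE]
  } else
    data.frame(position = integer(0), end = integer(0), span = integer(0),
               type = character(0), alleles = character(0),
               n_alleles = integer(0), pic = numeric(0),
               in_coding = logical(0), frame_preserving = logical(0))
}

#' Count haplotypes across variant sites
#'
#' A haplotype is the tuple of alleles a sample carries across the
#' variant sites; samples with any missing allele (gap or
#' quality-masked base at a SNP site, partial gap pattern at an INDEL
#' site) are dropped (complete-case).
#'
#' @param panel an [aligned_panel].
#' @param sites variant data frame from [call_variants] (at least one
#'   row).
#' @param min_quality quality mask threshold, as in [call_variants].
#' @param exclude_samples sample ids excluded from the count.
#' @return A list with `n_haplotypes`, `haplotypes` (data frame:
#'   `haplotype`, `n_samples`, `samples`), and `membership` (named
#'   haplotype per complete sample).
#' @export
count_haplotypes <- function(panel, sites, min_quality = 20,
                             exclude_samples = character(0)) {
  stopifnot(inherits(panel, "aligned_panel"))
  if (nrow(sites) == 0) stop("need at least one variant site")
  incl <- setdiff(names(panel$sequences), exclude_samples)
  m <- as_char_matrix(panel$sequences[incl])
  q <- panel_quality_matrix(panel, m)
  gap <- m == "-" | m == "."
  masked <- q < min_quality
  allele_at <- function(i, k) {
    s <- sites$position[k]; e <- sites$end[k]
    if (sites$type[k] == "SNP") {
      if (gap[i, s] || masked[i, s]) NA_character_ else m[i, s]
    } else {
      g <- gap[i, s:e]
      if (all(g)) "del" else if (!any(g)) "ins" else NA_character_
    }
  }
  allele_mat <- vapply(seq_len(nrow(sites)), function(k)
    vapply(seq_along(incl), function(i) allele_at(i, k), character(1)),
    character(length(incl)))
  allele_mat <- matrix(allele_mat, nrow = length(incl))
  complete <- !apply(allele_mat, 1, anyNA)
  tuples <- apply(allele_mat, 1, paste, collapse = ":")
  if (!any(complete)) stop("no samples complete at all sites")
  tuples <- tuples[complete]
  names(tuples) <- incl[complete]
  tab <- table(tuples)
  haplotypes <- data.frame(
    haplotype = names(tab), n_samples = as.integer(tab),
    samples = vapply(names(tab), function(h)
      paste(sort(names(tuples)[tuples == h]), collapse = ","),
      character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(n_haplotypes = nrow(haplotypes), haplotypes = haplotypes,
       membership = tuples)
}

translate_orf <- function(nt) {
  nt <- toupper(gsub("[-.]", "", nt))
  n3 <- nchar(nt) %/% 3L
  codons <- substring(nt, 3L * seq_len(n3) - 2L, 3L * seq_len(n3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    if (stop_at[1] < n3)
      warning("internal stop codon; translation truncated")
    aa <- aa[seq_len(stop_at[1] - 1L)]
  }
  paste(aa, collapse = "")
}

longest_runs <- function(protein) {
  if (nchar(protein) == 0)
    return(setNames(integer(0), character(0)))
  r <- rle(strsplit(protein, "", fixed = TRUE)[[1]])
  tapply(r$lengths, r$values, max)
}

#' Codon-level consequences between two ORF alleles
#'
#' Globally aligns two coding sequences at the nucleotide level,
#' classifies every substituted comparable codon as synonymous or
#' nonsynonymous under the standard genetic code, counts residues
#' inserted/deleted by in-frame INDELs, and reports the longest
#' single-residue runs in each translation (e.g. a glutamine tract
#' lengthened by an in-frame poly-Q insertion).
#'
#' @param orf_a,orf_b coding sequences starting at frame 0 (character
#'   scalars, no gaps).
#' @return A list of class `consequence_report`: `substitutions` (data
#'   frame: `codon`, `codon_a`, `codon_b`, `aa_a`, `aa_b`,
#'   `nonsynonymous`), `n_nonsynonymous`, `n_synonymous`,
#'   `inserted_residues`, `deleted_residues` (b relative to a),
#'   `frameshift`, `aa_runs` (data frame: `residue`, `run_a`, `run_b`),
#'   `translation_a`, `translation_b`.
#' @export
consequences <- function(orf_a, orf_b) {
  orf_a <- toupper(orf_a); orf_b <- toupper(orf_b)
  if (grepl("[-.]", orf_a) || grepl("[-.]", orf_b))
    stop("ORFs must be ungapped coding sequences")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(orf_a), Biostrings::DNAString(orf_b),
    type = "global", substitutionMatrix = submat,
    gapOpening = 6, gapExtension = 0.2)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap_a <- a == "-"; gap_b <- b == "-"
  run_lengths <- function(g) { r <- rle(g); r$lengths[r$values] }
  ins_runs <- run_lengths(gap_a)  # present in b only
  del_runs <- run_lengths(gap_b)  # present in a only
  frameshift <- any(c(ins_runs, del_runs) %% 3L != 0L)
  inserted_residues <- sum(ins_runs[ins_runs %% 3L == 0L]) %/% 3L
  deleted_residues <- sum(del_runs[del_runs %% 3L == 0L]) %/% 3L
  pos_a <- cumsum(!gap_a); pos_b <- cumsum(!gap_b)
  both <- !gap_a & !gap_b
  subs <- list()
  n_codons_a <- sum(!gap_a) %/% 3L
  for (k in seq_len(n_codons_a)) {
    cols <- which(both & pos_a >= 3L * k - 2L & pos_a <= 3L * k)
    if (length(cols) != 3L) next
    pb <- pos_b[cols]
    if (pb[1] %% 3L != 1L || any(diff(pb) != 1L)) next
    ca <- paste(a[cols], collapse = "")
    cb <- paste(b[cols], collapse = "")
    if (ca == cb) next
    aa_a <- unname(Biostrings::GENETIC_CODE[ca])
    aa_b <- unname(Biostrings::GENETIC_CODE[cb])
    subs[[length(subs) + 1L]] <- data.frame(
      codon = k, codon_a = ca, codon_b = cb, aa_a = aa_a, aa_b = aa_b,
      nonsynonymous = !identical(aa_a, aa_b), stringsAsFactors = FALSE)
  }
  subs <- if (length(subs)) do.call(rbind, subs) else
    data.frame(codon = integer(0), codon_a = character(0),
               codon_b = character(0), aa_a = character(0),
               aa_b = character(0), nonsynonymous = logical(0))
  tr_a <- translate_orf(orf_a)
  tr_b <- translate_orf(orf_b)
  runs_a <- longest_runs(tr_a); runs_b <- longest_runs(tr_b)
  residues <- sort(union(names(runs_a), names(runs_b)))
  aa_runs <- data.frame(
    residue = residues,
    run_a = as.integer(ifelse(residues %in% names(runs_a),
                              runs_a[residues], 0L)),
    run_b = as.integer(ifelse(residues %in% names(runs_b),
                              runs_b[residues], 0L)),
    stringsAsFactors = FALSE)
  structure(list(
    substitutions = subs,
    n_nonsynonymous = sum(subs$nonsynonymous),
    n_synonymous = sum(!subs$nonsynonymous),
    inserted_residues = inserted_residues,
    deleted_residues = deleted_residues,
    frameshift = frameshift,
    aa_runs = aa_runs,
    translation_a = tr_a, translation_b = tr_b),
    class = "consequence_report")
}

#' @export
print.consequence_report <- function(x, ...) {
  cat("consequence_report:", x$n_nonsynonymous, "nonsynonymous /",
      x$n_synonymous, "synonymous substitutions;",
      x$inserted_residues, "residue(s) inserted,",
      x$deleted_residues, "deleted",
      if (x$frameshift) "(FRAMESHIFT)" else "", "\n")
  invisible(x)
}

#' Allele-sharing genetic distance between genotyped samples
#'
#' Simple mismatch distance: for each pair of samples, the fraction of
#' markers typed in both at which the genotypes differ
#' (pairwise-complete).
#'
#' @param genotypes samples x markers matrix (any atomic type; `NA` =
#'   missing call).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
genetic_distance <- function(genotypes) {
  g <- as.matrix(genotypes)
  n <- nrow(g)
  if (n < 2) stop("need at least 2 samples")
  ids <- rownames(g)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(ok))
        stop("no shared typed markers between '", ids[i], "' and '",
             ids[j], "'")
      d[i, j] <- d[j, i] <- mean(g[i, ok] != g[j, ok])
    }
  }
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Squares and double-centers the distance matrix and eigendecomposes
#' it; axes are ordered by eigenvalue. Negative eigenvalues are
#' reported but never used. Euclidean inputs are reproduced exactly by
#' the embedded pairwise distances.
#'
#' @param dm symmetric distance matrix (or `dist`).
#' @param n_axes number of coordinate axes requested (default 2);
#'   truncated with a warning when fewer positive eigenvalues exist.
#' @return A list: `coordinates` (samples x axes), `explained`
#'   (fraction of positive eigenvalue mass per returned axis),
#'   `eigenvalues`, `n_negative_eigenvalues`.
#' @export
pcoa <- function(dm, n_axes = 2) {
  d <- as.matrix(dm)
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  fit <- suppressWarnings(
    cmdscale(stats::as.dist(d), k = max(1L, min(n - 1L, n_axes)),
             eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-8
  n_pos <- sum(eig > tol)
  pts <- fit$points
  if (n_pos < n_axes)
    warning("only ", n_pos, " positive eigenvalue(s); returning ",
            n_pos, " informative axis/axes, zero-padded to ", n_axes)
  coords <- matrix(0, n, n_axes,
                   dimnames = list(ids, paste0("Axis", seq_len(n_axes))))
  take <- min(n_axes, ncol(pts), n_pos)
  if (take > 0) coords[, seq_len(take)] <- pts[, seq_len(take)]
  pos_mass <- sum(pmax(eig, 0))
  explained <- if (pos_mass > 0)
    pmax(eig[seq_len(n_axes)], 0) / pos_mass else rep(0, n_axes)
  explained[is.na(explained)] <- 0
  list(coordinates = coords, explained = explained, eigenvalues = eig,
       n_negative_eigenvalues = sum(eig < -tol))
}
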