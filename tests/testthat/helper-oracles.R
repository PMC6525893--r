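# Independent brute-force oracles and small fixture builders used
# across the suite. These deliberately avoid the package's own code
# paths (plain loops, no shared helpers).

# full-scan nearest SNP: per gene, walk every SNP row
oracle_nearest_snp <- function(genes, snps, focal_ids) {
  out <- list()
  for (g in focal_ids) {
    row <- genes[genes$gene_id == g, ]
    best_id <- NA_character_; best_d <- Inf; best_pos <- Inf
    for (k in seq_len(nrow(snps))) {
      if (snps$chromosome[k] != row$chromosome) next
      d <- abs(snps$position[k] - row$tss)
      better <- d < best_d ||
        (d == best_d && snps$position[k] < best_pos) ||
        (d == best_d && snps$position[k] == best_pos &&
           snps$snp_id[k] < best_id)
      if (better) {
        best_id <- snps$snp_id[k]; best_d <- d
        best_pos <- snps$position[k]
      }
    }
    out[[g]] <- data.frame(gene_id = g, snp_id = best_id,
                           distance_bp = if (is.finite(best_d)) best_d
                           else NA_real_)
  }
  do.call(rbind, out)
}

# exhaustive window enumeration for motif scanning
oracle_scan <- function(sequence, consensus, max_mismatch) {
  s <- strsplit(sequence, "")[[1]]
  m <- strsplit(consensus, "")[[1]]
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  if (length(s) < length(m)) return(hits)
  for (start in 1:(length(s) - length(m) + 1)) {
    mm <- 0L
    for (k in seq_along(m))
      if (s[start + k - 1] != m[k]) mm <- mm + 1L
    if (mm <= max_mismatch)
      hits <- rbind(hits, data.frame(start = start, mismatches = mm))
  }
  hits
}

oracle_pic <- function(counts) {
  p <- counts / sum(counts)
  total <- 0
  for (x in p) total <- total + x * x
  1 - total
}

# random amino-acid / nucleotide strings
rand_protein <- function(n)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                 "Q","R","S","T","V","W","Y"), n, TRUE), collapse = "")
rand_dna <- function(n)
  paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")

# random open reading frame (sense codons only), length in codons
rand_orf_test <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  paste(sample(names(gc)[gc != "*"], n_codons, TRUE), collapse = "")
}

# a protein with an AP2 domain whose 14th/19th residues are chosen
protein_with_domain <- function(r14 = "V", r19 = "E", len = 120,
                                start = 30, domlen = 60) {
  s <- rand_protein(len)
  substr(s, start + 13, start + 13) <- r14
  substr(s, start + 18, start + 18) <- r19
  list(seq = s, start = start, end = start + domlen - 1)
}

# simple aligned panel: one column polymorphic, 11 vs 6 split
panel_11_6 <- function(len = 40, col = 20, seed = 99) {
  set.seed(seed)
  base <- rand_dna(len)
  a <- base; substr(a, col, col) <- "G"
  b <- base; substr(b, col, col) <- "A"
  ids <- c(sprintf("MES_%02d", 1:11), sprintf("AND_%02d", 1:6))
  seqs <- setNames(c(rep(a, 11), rep(b, 6)), ids)
  pools <- setNames(rep(c("Mesoamerican", "Andean"), c(11, 6)), ids)
  aligned_panel(seqs, pools)
}
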