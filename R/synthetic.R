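# Seeded generators producing inputs with the statistical structure the
# pipeline assumes, each with a machine-readable truth record. All
# generators are reproducible from their arguments plus `seed`.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

SENSE_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

overwrite_at <- function(s, at, piece) {
  substr(s, at, at + nchar(piece) - 1L) <- piece
  s
}

mutate_aa <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  v[hit] <- sample(AA20, length(hit), replace = TRUE)
  paste(v, collapse = "")
}

#' Generate a synthetic AP2/ERF protein family with planted truth
#'
#' Builds one random ancestor peptide per DREB subgroup and derives
#' members by point substitution, then plants (overwriting fixed
#' windows, so all peptides stay the same length): one AP2 domain whose
#' first 19 residues carry V at position 14 and E at 19 (violated with
#' probability `violation_rate`, planting a non-V residue), the core
#' motifs CM3/CM2/CM1 inside the domain plus CM7 just before it, and
#' the subgroup signature motifs (CM6 and N-terminal CM14 for A-2,
#' C-terminal CM14 for A-4, CM8 for A-5, CM10+CM13 for A-6). Labeled
#' reference peptides per subgroup, plus RAV, AP2-family and
#' domain-less decoys, complete the classification inputs.
#'
#' @param n_per_subgroup named integer vector of member counts for
#'   subgroups A-1..A-6; the default reproduces the subgroup sizes of
#'   the common-bean DREB subfamily (17/8/1/10/10/8).
#' @param n_refs_per_subgroup labeled references per subgroup.
#' @param protein_length peptide length (>= 240).
#' @param violation_rate probability a member is planted with a non-V
#'   residue at domain position 14.
#' @param within_divergence per-residue substitution probability from
#'   the subgroup ancestor.
#' @param n_rav,n_ap2_family,n_other decoy counts (one AP2 + one B3;
#'   two or more AP2; no annotated domain).
#' @param seed integer seed.
#' @return A list: `proteins` ([seq_set]), `domains` (annotation data
#'   frame), `reference_labels` (named character), `truth` (data
#'   frame: `protein_id`, `subgroup`, `class`, `v14`,
#'   `retained_expected`), and `config`.
#' @export
gen_protein_family <- function(n_per_subgroup = c("A-1" = 17, "A-2" = 8,
                                                  "A-3" = 1, "A-4" = 10,
                                                  "A-5" = 10, "A-6" = 8),
                               n_refs_per_subgroup = 2,
                               protein_length = 250,
                               violation_rate = 0,
                               within_divergence = 0.03,
                               n_rav = 3, n_ap2_family = 5, n_other = 3,
                               seed = 1) {
  stopifnot(protein_length >= 240, violation_rate >= 0,
            violation_rate <= 1)
  set.seed(seed)
  motifs <- setNames(builtin_motifs()$consensus, builtin_motifs()$motif_id)
  dom_start <- 100L
  dom_len <- 19L + nchar(motifs["CM3"]) + nchar(motifs["CM2"]) +
    nchar(motifs["CM1"])  # 19-residue prefix + CM3 + CM2 + CM1 = 70
  dom_end <- dom_start + dom_len - 1L
  plant_positions <- list(
    "A-2" = c(CM6 = 10L, CM14 = 40L),
    "A-4" = c(CM14 = protein_length - nchar(motifs[["CM14"]]) + 1L - 10L),
    "A-5" = c(CM8 = protein_length - nchar(motifs[["CM8"]]) + 1L - 5L),
    "A-6" = c(CM10 = 30L,
              CM13 = protein_length - nchar(motifs[["CM13"]]) + 1L - 5L))
  subgroups <- names(n_per_subgroup)
  ancestors <- setNames(
    vapply(subgroups, function(g) rand_aa(protein_length), character(1)),
    subgroups)
  build_member <- function(subgroup, violate) {
    s <- mutate_aa(ancestors[[subgroup]], within_divergence)
    prefix <- substr(s, dom_start, dom_start + 18L)
    substr(prefix, 14L, 14L) <- if (violate)
      sample(setdiff(AA20, "V"), 1L) else "V"
    substr(prefix, 19L, 19L) <- "E"
    s <- overwrite_at(s, dom_start, prefix)
    s <- overwrite_at(s, dom_start + 19L, motifs[["CM3"]])
    s <- overwrite_at(s, dom_start + 19L + nchar(motifs["CM3"]),
                      motifs[["CM2"]])
    s <- overwrite_at(s, dom_start + 19L + nchar(motifs["CM3"]) +
                        nchar(motifs["CM2"]), motifs[["CM1"]])
    s <- overwrite_at(s, dom_start - nchar(motifs["CM7"]) - 1L,
                      motifs[["CM7"]])
    for (m in names(plant_positions[[subgroup]]))
      s <- overwrite_at(s, plant_positions[[subgroup]][[m]], motifs[[m]])
    s
  }
  seqs <- character(0); truth <- list(); domains <- list()
  ref_labels <- character(0)
  add_domain <- function(id, name, start, end)
    domains[[length(domains) + 1L]] <<- data.frame(
      protein_id = id, domain_name = name, start = start, end = end,
      stringsAsFactors = FALSE)
  for (g in subgroups) {
    tag <- gsub("-", "", g)
    for (i in seq_len(n_per_subgroup[[g]])) {
      id <- sprintf("PV_%s_%02d", tag, i)
      violate <- runif(1) < violation_rate
      seqs[id] <- build_member(g, violate)
      add_domain(id, "AP2", dom_start, dom_end)
      truth[[id]] <- data.frame(
        protein_id = id, subgroup = g, class = "ERF_candidate",
        v14 = !violate, retained_expected = !violate,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_refs_per_subgroup)) {
      id <- sprintf("REF_%s_%02d", tag, i)
      seqs[id] <- build_member(g, FALSE)
      add_domain(id, "AP2", dom_start, dom_end)
      ref_labels[id] <- g
      truth[[id]] <- data.frame(
        protein_id = id, subgroup = g, class = "ERF_candidate",
        v14 = TRUE, retained_expected = NA, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_rav)) {
    id <- sprintf("RAV_%02d", i)
    seqs[id] <- rand_aa(protein_length)
    add_domain(id, "AP2", dom_start, dom_end)
    add_domain(id, "B3", dom_end + 11L, dom_end + 70L)
    truth[[id]] <- data.frame(protein_id = id, subgroup = NA, class = "RAV",
                              v14 = NA, retained_expected = FALSE,
                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_ap2_family)) {
    id <- sprintf("AP2F_%02d", i)
    seqs[id] <- rand_aa(protein_length)
    n_dom <- sample(2:4, 1)
    for (k in seq_len(n_dom))
      add_domain(id, "AP2", 5L + (k - 1L) * 62L, 5L + (k - 1L) * 62L + 59L)
    truth[[id]] <- data.frame(protein_id = id, subgroup = NA,
                              class = "AP2_family", v14 = NA,
                              retained_expected = FALSE,
                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_other)) {
    id <- sprintf("OTH_%02d", i)
    seqs[id] <- rand_aa(protein_length)
    truth[[id]] <- data.frame(protein_id = id, subgroup = NA,
                              class = "other", v14 = NA,
                              retained_expected = FALSE,
                              stringsAsFactors = FALSE)
  }
  list(proteins = seq_set(seqs),
       domains = do.call(rbind, domains),
       reference_labels = ref_labels,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       config = list(n_per_subgroup = n_per_subgroup,
                     n_refs_per_subgroup = n_refs_per_subgroup,
                     protein_length = protein_length,
                     violation_rate = violation_rate,
                     within_divergence = within_divergence,
                     domain = c(dom_start, dom_end), seed = seed))
}

rand_orf <- function(n_codons)
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")

#' Generate a two-gene-pool aligned panel with planted variants
#'
#' Emulates a resequenced-locus panel: a random ORF shared by two gene
#' pools, pool-diagnostic SNPs planted at recorded alignment columns,
#' an optional in-frame 9-nt glutamine-codon insertion (CAA CAG CAA)
#' carried by the Mesoamerican pool inside a 4-glutamine tract (so the
#' Andean translation has a 4-Q run and the Mesoamerican a 7-Q run),
#' and an optional outgroup with private alleles. A genotype matrix
#' consistent with a two-pool structure accompanies the panel.
#'
#' @param n_mesoamerican,n_andean samples per pool (defaults 11 and 6,
#'   the resequencing panel sizes).
#' @param n_codons ORF length in codons before insertion (default 158,
#'   i.e. 474 bp).
#' @param n_diagnostic_snps pool-diagnostic SNP columns planted.
#' @param indel plant the 9-nt in-frame insertion.
#' @param outgroup add one outgroup sample with private alleles.
#' @param n_outgroup_private private outgroup alleles.
#' @param n_markers genotype matrix width (default 43).
#' @param marker_divergence fraction of pool-diagnostic markers in the
#'   genotype matrix (default 0.5).
#' @param seed integer seed.
#' @return A list: `panel` ([aligned_panel]), `orf_andean`,
#'   `orf_mesoamerican` (ungapped ORFs), `genotypes` (samples x
#'   markers), `truth` (planted SNP columns, INDEL span, diagnostic
#'   marker indices, pools), `config`.
#' @export
gen_genotype_panel <- function(n_mesoamerican = 11, n_andean = 6,
                               n_codons = 158, n_diagnostic_snps = 1,
                               indel = TRUE, outgroup = FALSE,
                               n_outgroup_private = 2, n_markers = 43,
                               marker_divergence = 0.5, seed = 1) {
  set.seed(seed)
  n_diag_markers <- round(marker_divergence * n_markers)
  if (n_diag_markers > n_markers) stop("divergence exceeds marker count")
  q_codon <- 50L
  base <- rand_orf(n_codons)
  # 4-glutamine tract, flanked by non-Q codons
  base <- overwrite_at(base, 3L * (q_codon - 2L) - 2L, "GGT")
  base <- overwrite_at(base, 3L * (q_codon - 1L) - 2L,
                       paste(rep("CAA", 4L), collapse = ""))
  base <- overwrite_at(base, 3L * (q_codon + 3L) - 2L, "GGA")
  ins_seq <- "CAACAGCAA"  # Q Q Q, in frame
  ins_after <- 3L * q_codon  # inside the Q tract
  and_orf <- base
  mes_orf <- paste0(substr(base, 1L, ins_after), ins_seq,
                    substring(base, ins_after + 1L))
  if (!indel) mes_orf <- and_orf
  # aligned panel: Andean rows carry gaps over the insertion span
  and_aln <- if (indel)
    paste0(substr(base, 1L, ins_after), strrep("-", 9L),
           substring(base, ins_after + 1L)) else and_orf
  mes_aln <- mes_orf
  L <- nchar(mes_aln)
  ind_span <- if (indel) c(ins_after + 1L, ins_after + 9L) else NULL
  # pool-diagnostic SNP columns, outside the INDEL span
  avail <- setdiff(seq_len(L), if (indel) ind_span[1]:ind_span[2])
  avail <- setdiff(avail, c(33L))
  snp_cols <- if (n_diagnostic_snps >= 1)
    c(33L, sample(avail, n_diagnostic_snps - 1L)) else integer(0)
  alt_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  # substitute without creating an in-frame stop codon
  alt_base_safe <- function(orf, col) {
    ref <- substr(orf, col, col)
    cod0 <- (col - 1L) %/% 3L
    for (alt in sample(setdiff(c("A", "C", "G", "T"), ref))) {
      cand <- overwrite_at(orf, col, alt)
      codon <- substr(cand, 3L * cod0 + 1L, 3L * cod0 + 3L)
      if (Biostrings::GENETIC_CODE[[codon]] != "*") return(alt)
    }
    stop("no stop-free substitution at column ", col)
  }
  mes_alleles <- character(0)
  for (col in snp_cols) {
    # mesoamerican alignment rows carry no gaps: columns map 1:1 to the
    # mesoamerican ORF
    alt <- alt_base_safe(mes_orf, col)
    mes_aln <- overwrite_at(mes_aln, col, alt)
    mes_orf <- overwrite_at(mes_orf, col, alt)
    mes_alleles <- c(mes_alleles, alt)
  }
  ids_mes <- sprintf("MES_%02d", seq_len(n_mesoamerican))
  ids_and <- sprintf("AND_%02d", seq_len(n_andean))
  seqs <- c(setNames(rep(mes_aln, n_mesoamerican), ids_mes),
            setNames(rep(and_aln, n_andean), ids_and))
  pools <- c(setNames(rep("Mesoamerican", n_mesoamerican), ids_mes),
             setNames(rep("Andean", n_andean), ids_and))
  out_private <- integer(0)
  if (outgroup) {
    og <- and_aln
    avail_og <- setdiff(avail, snp_cols)
    avail_og <- avail_og[substr(rep(og, length(avail_og)), avail_og,
                                avail_og) != "-"]
    out_private <- sort(sample(avail_og, n_outgroup_private))
    for (col in out_private)
      og <- overwrite_at(og, col, alt_base(substr(og, col, col)))
    seqs["OUTGROUP"] <- og
    pools["OUTGROUP"] <- "outgroup"
  }
  panel <- aligned_panel(seqs, pools)
  # genotype matrix: diagnostic markers split the pools, the rest are
  # shared low-frequency variation
  samples <- names(seqs)
  geno <- matrix(0L, length(samples), n_markers,
                 dimnames = list(samples,
                                 sprintf("M%03d", seq_len(n_markers))))
  diag_idx <- sort(sample(n_markers, n_diag_markers))
  for (j in seq_len(n_markers)) {
    if (j %in% diag_idx) {
      geno[, j] <- ifelse(pools == "Mesoamerican", 1L, 0L)
      if (outgroup) geno["OUTGROUP", j] <- sample(0:1, 1L)
    } else {
      geno[, j] <- rbinom(length(samples), 1L, 0.2)
    }
  }
  list(panel = panel, orf_andean = and_orf, orf_mesoamerican = mes_orf,
       genotypes = geno,
       truth = list(snp_columns = snp_cols,
                    mesoamerican_alleles = mes_alleles,
                    indel_span = ind_span,
                    indel_length = if (indel) 9L else 0L,
                    outgroup_private_columns = out_private,
                    diagnostic_markers = diag_idx, pools = pools),
       config = list(n_mesoamerican = n_mesoamerican, n_andean = n_andean,
                     n_codons = n_codons,
                     n_diagnostic_snps = n_diagnostic_snps, indel = indel,
                     outgroup = outgroup, n_markers = n_markers,
                     marker_divergence = marker_divergence, seed = seed))
}

#' Generate synthetic qPCR amplification curves with known truth
#'
#' Logistic-plateau curves `F(c) = plateau / (1 + exp(-k (c - m))) +
#' baseline` whose early exponential phase amplifies by the planted
#' factor `E = exp(k)` per cycle. Treated samples cross threshold
#' `delta_cq` cycles earlier than controls. Noise is multiplicative
#' log-normal on the signal component; replicate-to-replicate Cq
#' scatter is controlled by `cq_sd`.
#'
#' @param genes gene names; the first is conventionally the target.
#' @param true_e named per-gene amplification factors (default 1.9).
#' @param delta_cq named per-gene control-minus-treated Cq shifts
#'   (default 0 for all but can plant e.g. `c(TARGET = 3)`).
#' @param n_replicates replicates per gene and condition (default 3,
#'   the plate design used here).
#' @param n_cycles cycles per curve (default 40).
#' @param noise_sd log-normal noise standard deviation (default 0.01,
#'   i.e. 1 percent).
#' @param cq_sd replicate Cq scatter in cycles (default 0.05).
#' @param mid_control logistic midpoint cycle for controls (default
#'   25).
#' @param plateau,baseline curve scale parameters.
#' @param seed integer seed.
#' @return A list: `plate` (long data frame: `well`, `gene`, `sample`,
#'   `condition`, `cycle`, `fluorescence`), `truth` (per-gene `e`,
#'   `delta_cq`, per-well midpoint), `config`.
#' @export
gen_amplification_curves <- function(genes = c("TARGET", "REF1", "REF2"),
                                     true_e = setNames(rep(1.9,
                                       length(genes)), genes),
                                     delta_cq = setNames(rep(0,
                                       length(genes)), genes),
                                     n_replicates = 3, n_cycles = 40,
                                     noise_sd = 0.01, cq_sd = 0.05,
                                     mid_control = 25, plateau = 10000,
                                     baseline = 100, seed = 1) {
  set.seed(seed)
  rows <- list(); mids <- list()
  well <- 0L
  for (g in genes) {
    k <- log(true_e[[g]])
    for (cond in c("control", "treated")) {
      m0 <- if (cond == "control") mid_control else
        mid_control - delta_cq[[g]]
      for (r in seq_len(n_replicates)) {
        well <- well + 1L
        m <- m0 + rnorm(1, 0, cq_sd)
        cyc <- seq_len(n_cycles)
        signal <- plateau / (1 + exp(-k * (cyc - m)))
        noise <- if (noise_sd > 0) exp(rnorm(n_cycles, 0, noise_sd)) else 1
        rows[[well]] <- data.frame(
          well = sprintf("W%03d", well), gene = g, sample = r,
          condition = cond, cycle = cyc,
          fluorescence = signal * noise + baseline,
          stringsAsFactors = FALSE)
        mids[[well]] <- data.frame(
          well = sprintf("W%03d", well), gene = g, sample = r,
          condition = cond, midpoint = m, stringsAsFactors = FALSE)
      }
    }
  }
  list(plate = do.call(rbind, rows),
       truth = list(e = true_e, delta_cq = delta_cq,
                    midpoints = do.call(rbind, mids)),
       config = list(genes = genes, n_replicates = n_replicates,
                     n_cycles = n_cycles, noise_sd = noise_sd,
                     cq_sd = cq_sd, mid_control = mid_control,
                     plateau = plateau, baseline = baseline, seed = seed))
}

#' Generate a synthetic gene/SNP map with planted structure
#'
#' Lays out focal genes in 1-Mb blocks across chromosomes: singleton
#' genes each with a dedicated nearby SNP, tandem pairs satisfying both
#' duplication thresholds, distractor pairs violating exactly one
#' threshold (too far, or too many intervening loci), and shared-SNP
#' pairs whose two genes (placed beyond tandem range) are both nearest
#' to one SNP. Background loci fill the intervening positions.
#'
#' @param n_focal total focal genes (default 54).
#' @param n_tandem_pairs planted tandem pairs (default 6).
#' @param n_shared_snps SNPs each serving two genes (default 3).
#' @param n_distractor_distance pairs 150 kb apart (fail distance).
#' @param n_distractor_intervening pairs with 7 intervening loci (fail
#'   intervening count).
#' @param n_chromosomes chromosomes to spread blocks over (default 11).
#' @param seed integer seed.
#' @return A list: `genes`, `snps` (annotation data frames),
#'   `focal_ids`, `truth` (`tandem_pairs`, `nearest` per focal gene,
#'   `shared_snp_ids`, `n_nonredundant`), `config`.
#' @export
gen_gene_map <- function(n_focal = 54, n_tandem_pairs = 6,
                         n_shared_snps = 3, n_distractor_distance = 3,
                         n_distractor_intervening = 3,
                         n_chromosomes = 11, seed = 1) {
  set.seed(seed)
  n_paired <- 2L * (n_tandem_pairs + n_shared_snps +
                    n_distractor_distance + n_distractor_intervening)
  n_single <- n_focal - n_paired
  if (n_single < 0)
    stop("n_focal too small for the requested planted pairs")
  genes <- list(); snps <- list(); nearest <- list()
  tandem <- list(); shared_ids <- character(0)
  gi <- 0L; si <- 0L; bgi <- 0L; block <- 0L
  new_gene <- function(chr, tss) {
    gi <<- gi + 1L
    id <- sprintf("GENE_%03d", gi)
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = id, chromosome = chr, strand = sample(c("+", "-"), 1L),
      tss = tss, stringsAsFactors = FALSE)
    id
  }
  new_bg <- function(chr, tss) {
    bgi <<- bgi + 1L
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = sprintf("BG_%03d", bgi), chromosome = chr,
      strand = sample(c("+", "-"), 1L), tss = tss,
      stringsAsFactors = FALSE)
  }
  new_snp <- function(chr, pos) {
    si <<- si + 1L
    id <- sprintf("SNP_%03d", si)
    snps[[length(snps) + 1L]] <<- data.frame(
      snp_id = id, chromosome = chr, position = pos,
      stringsAsFactors = FALSE)
    id
  }
  next_block <- function() {
    block <<- block + 1L
    list(chr = sprintf("Chr%02d", (block - 1L) %% n_chromosomes + 1L),
         base = 1e6 * (1L + (block - 1L) %/% n_chromosomes))
  }
  record_nearest <- function(gene, snp, dist)
    nearest[[length(nearest) + 1L]] <<- data.frame(
      gene_id = gene, snp_id = snp, distance_bp = dist,
      stringsAsFactors = FALSE)
  for (i in seq_len(n_single)) {
    b <- next_block()
    g <- new_gene(b$chr, b$base)
    off <- sample(2000:50000, 1L)
    s <- new_snp(b$chr, b$base + off)
    record_nearest(g, s, off)
    new_bg(b$chr, b$base + 300000)
  }
  for (i in seq_len(n_tandem_pairs)) {
    b <- next_block()
    g1 <- new_gene(b$chr, b$base)
    g2 <- new_gene(b$chr, b$base + 50000)
    for (k in 1:3) new_bg(b$chr, b$base + 10000 * k)
    s1 <- new_snp(b$chr, b$base + 3000)
    s2 <- new_snp(b$chr, b$base + 50000 + 3000)
    record_nearest(g1, s1, 3000); record_nearest(g2, s2, 3000)
    tandem[[length(tandem) + 1L]] <- data.frame(
      gene_a = min(g1, g2), gene_b = max(g1, g2), chromosome = b$chr,
      distance_bp = 50000, n_intervening = 3L, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_shared_snps)) {
    b <- next_block()
    g1 <- new_gene(b$chr, b$base)
    g2 <- new_gene(b$chr, b$base + 200000)
    s <- new_snp(b$chr, b$base + 90000)
    record_nearest(g1, s, 90000); record_nearest(g2, s, 110000)
    shared_ids <- c(shared_ids, s)
  }
  for (i in seq_len(n_distractor_distance)) {
    b <- next_block()
    g1 <- new_gene(b$chr, b$base)
    g2 <- new_gene(b$chr, b$base + 150000)
    for (k in 1:2) new_bg(b$chr, b$base + 40000 * k)
    s1 <- new_snp(b$chr, b$base + 4000)
    s2 <- new_snp(b$chr, b$base + 150000 + 4000)
    record_nearest(g1, s1, 4000); record_nearest(g2, s2, 4000)
  }
  for (i in seq_len(n_distractor_intervening)) {
    b <- next_block()
    g1 <- new_gene(b$chr, b$base)
    g2 <- new_gene(b$chr, b$base + 80000)
    for (k in 1:7) new_bg(b$chr, b$base + 10000 * k)
    s1 <- new_snp(b$chr, b$base + 2500)
    s2 <- new_snp(b$chr, b$base + 80000 + 2500)
    record_nearest(g1, s1, 2500); record_nearest(g2, s2, 2500)
  }
  genes <- do.call(rbind, genes)
  snps <- do.call(rbind, snps)
  nearest <- do.call(rbind, nearest)
  focal_ids <- genes$gene_id[grepl("^GENE_", genes$gene_id)]
  tandem <- if (length(tandem)) do.call(rbind, tandem) else
    data.frame(gene_a = character(0), gene_b = character(0),
               chromosome = character(0), distance_bp = numeric(0),
               n_intervening = integer(0))
  list(genes = genes, snps = snps, focal_ids = focal_ids,
       truth = list(tandem_pairs = tandem, nearest = nearest,
                    shared_snp_ids = shared_ids,
                    n_nonredundant = n_focal - n_shared_snps),
       config = list(n_focal = n_focal, n_tandem_pairs = n_tandem_pairs,
                     n_shared_snps = n_shared_snps,
                     n_distractor_distance = n_distractor_distance,
                     n_distractor_intervening = n_distractor_intervening,
                     n_chromosomes = n_chromosomes, seed = seed))
}
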