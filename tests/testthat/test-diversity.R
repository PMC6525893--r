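test_that("SNP calling sees only unmasked non-gap alleles", {
  p <- aligned_panel(c(a = "ACGTACGT", b = "ACGAACGT"),
                     c(a = "Andean", b = "Mesoamerican"))
  v <- call_variants(p)
  expect_identical(nrow(v), 1L)
  expect_identical(v$position, 4L)
  expect_identical(v$type, "SNP")
  # a discordant base below the quality threshold is masked: no SNP
  q <- list(a = rep(40L, 8), b = c(40L, 40L, 40L, 15L, rep(40L, 4)))
  pq <- aligned_panel(c(a = "ACGTACGT", b = "ACGAACGT"),
                      c(a = "Andean", b = "Mesoamerican"), quality = q)
  expect_identical(nrow(call_variants(pq, min_quality = 20)), 0L)
  expect_identical(nrow(call_variants(pq, min_quality = 10)), 1L)
  expect_error(call_variants(p, exclude_samples = c("a", "b")),
               "excluded")
})

test_that("gap runs become INDELs with span and frame flags", {
  p <- aligned_panel(
    c(m1 = "ACGTTTGGGCCCAAA", m2 = "ACGTTTGGGCCCAAA",
      a1 = "ACG---------AAA", a2 = "ACG---------AAA"),
    setNames(c("Mesoamerican", "Mesoamerican", "Andean", "Andean"),
             c("m1", "m2", "a1", "a2")))
  v <- call_variants(p)
  ind <- v[v$type == "INDEL", ]
  expect_identical(nrow(ind), 1L)
  expect_identical(ind$span, 9L)
  expect_true(ind$frame_preserving)
  expect_setequal(strsplit(ind$alleles, "/")[[1]],
                  c("ins=2", "del=2"))
  # a 4-column gap is frame-breaking
  p2 <- aligned_panel(c(x = "ACGTACGTAC", y = "ACG----TAC"),
                      c(x = "Andean", y = "Mesoamerican"))
  v2 <- call_variants(p2)
  expect_false(v2$frame_preserving[v2$type == "INDEL"])
})

test_that("excluded outgroup samples contribute no alleles", {
  gp <- gen_genotype_panel(outgroup = TRUE, n_outgroup_private = 3,
                           seed = 5)
  with_og <- call_variants(gp$panel)
  no_og <- call_variants(gp$panel, exclude_samples = "OUTGROUP")
  priv <- gp$truth$outgroup_private_columns
  expect_true(all(priv %in% with_og$position))
  expect_false(any(priv %in% no_og$position))
  expect_setequal(no_og$position[no_og$type == "SNP"],
                  gp$truth$snp_columns)
})

test_that("PIC matches the direct gene-diversity formula", {
  expect_equal(pic(c(0.5, 0.5)), 0.5)
  expect_equal(pic(c(17)), 0)
  expect_equal(pic(c(11, 6)), 1 - (11 / 17)^2 - (6 / 17)^2)
  expect_equal(round(pic(c(11, 6)), 4), 0.4567)
  # the printed-form audit flag is the degenerate expression
  expect_equal(pic(c(0.5, 0.5), strict_formula = TRUE), -0.5)
  expect_error(pic(numeric(0)), "empty")
  set.seed(8)
  for (i in 1:20) {
    counts <- sample(1:30, sample(2:5, 1))
    expect_equal(pic(counts), oracle_pic(counts))
  }
  # PIC of a pool-diagnostic SNP is 2pq
  gp <- gen_genotype_panel(seed = 10)
  v <- call_variants(gp$panel)
  snp <- v[v$type == "SNP", ]
  p <- 11 / 17
  expect_equal(snp$pic, 2 * p * (1 - p))
})

test_that("haplotype counting is complete-case over sites", {
  p <- panel_11_6()
  v <- call_variants(p)
  h <- count_haplotypes(p, v)
  expect_identical(h$n_haplotypes, 2L)
  expect_identical(sort(h$haplotypes$n_samples), c(6L, 11L))
  # two independent biallelic sites with all four combinations
  seqs <- c(s1 = "AATT", s2 = "AATA", s3 = "CATT", s4 = "CATA")
  p4 <- aligned_panel(seqs, setNames(rep("Andean", 4), names(seqs)))
  v4 <- call_variants(p4)
  expect_identical(count_haplotypes(p4, v4)$n_haplotypes, 4L)
  # a monomorphic site collapses everything to one haplotype
  mono <- data.frame(position = 2L, end = 2L, span = 1L, type = "SNP")
  expect_identical(count_haplotypes(p4, mono)$n_haplotypes, 1L)
  # bound: haplotypes <= product of allele counts and <= samples
  expect_lte(count_haplotypes(p4, v4)$n_haplotypes,
             prod(v4$n_alleles))
  expect_lte(count_haplotypes(p4, v4)$n_haplotypes, length(seqs))
})

test_that("codon consequences classify substitutions correctly", {
  set.seed(15)
  orf <- rand_orf_test(100)
  # plant AAG at codon 30 and CTT at codon 90
  a <- orf
  substr(a, 88, 90) <- "AAG"; substr(a, 268, 270) <- "CTT"
  b <- a
  substr(b, 88, 90) <- "ATG"; substr(b, 268, 270) <- "CTC"
  cc <- consequences(a, b)
  expect_identical(cc$n_nonsynonymous, 1L)
  expect_identical(cc$n_synonymous, 1L)
  sub <- cc$substitutions[cc$substitutions$nonsynonymous, ]
  expect_identical(sub$aa_a, "K")
  expect_identical(sub$aa_b, "M")
  expect_false(cc$frameshift)
  # substitution counts are symmetric in the arguments
  cc_rev <- consequences(b, a)
  expect_identical(cc_rev$n_nonsynonymous, cc$n_nonsynonymous)
  expect_identical(cc_rev$n_synonymous, cc$n_synonymous)
})

test_that("in-frame insertions count residues and lengthen runs", {
  gp <- gen_genotype_panel(seed = 23)
  cc <- consequences(gp$orf_andean, gp$orf_mesoamerican)
  expect_identical(cc$inserted_residues, 3L)
  expect_identical(cc$deleted_residues, 0L)
  q <- cc$aa_runs[cc$aa_runs$residue == "Q", ]
  expect_identical(q$run_a, 4L)
  expect_identical(q$run_b, 7L)
  expect_false(cc$frameshift)
  # a non-multiple-of-3 gap flags a frameshift
  a <- gp$orf_andean
  b <- paste0(substr(a, 1, 90), "AC", substring(a, 91))
  # the shifted frame hits a stop downstream: truncation is warned
  expect_warning(cc_fs <- consequences(a, b), "internal stop")
  expect_true(cc_fs$frameshift)
  expect_error(consequences("AC-T", "ACGT"), "ungapped")
})

test_that("genetic distance is a pairwise-complete mismatch fraction", {
  g <- rbind(s1 = c(0, 0, 1, 1), s2 = c(0, 0, 1, 1),
             s3 = c(1, 1, 0, 0))
  d <- genetic_distance(g)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 1)
  expect_identical(d, t(d))
  g2 <- rbind(s1 = c(0, NA, 1), s2 = c(0, 1, NA))
  expect_equal(genetic_distance(g2)["s1", "s2"], 0)
  g3 <- rbind(s1 = c(0, NA), s2 = c(NA, 1))
  expect_error(genetic_distance(g3), "shared")
})

test_that("PCoA reproduces Euclidean geometry and orders axes", {
  set.seed(19)
  pts <- matrix(rnorm(8 * 3), 8, 3,
                dimnames = list(paste0("s", 1:8), NULL))
  d <- as.matrix(dist(pts))
  out <- pcoa(d, n_axes = 3)
  emb <- as.matrix(dist(out$coordinates))
  expect_equal(emb, d, tolerance = 1e-8)
  expect_true(all(diff(out$explained) <= 1e-12))
  # all-zero distances give all-zero coordinates
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(outz <- pcoa(z), "positive eigenvalue")
  expect_true(all(outz$coordinates == 0))
  # collinear points: axis 1 recovers the order
  x <- c(a = 0, b = 1, c = 3)
  d1 <- abs(outer(x, x, "-"))
  expect_warning(out1 <- pcoa(d1, n_axes = 2), "positive eigenvalue")
  ord <- names(sort(out1$coordinates[, 1]))
  expect_true(identical(ord, c("a", "b", "c")) ||
                identical(ord, c("c", "b", "a")))
})

test_that("two-pool genotypes separate on PCoA axis 1", {
  gp <- gen_genotype_panel(seed = 27)
  out <- pcoa(genetic_distance(gp$genotypes))
  ax1 <- out$coordinates[, 1]
  pools <- gp$truth$pools[rownames(out$coordinates)]
  rng_a <- range(ax1[pools == "Andean"])
  rng_m <- range(ax1[pools == "Mesoamerican"])
  expect_true(rng_a[2] < rng_m[1] || rng_m[2] < rng_a[1])
})
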