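test_that("p-distance counts mismatches over gap-free columns", {
  expect_equal(p_distance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  expect_equal(p_distance(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "A-AA", b = "ATAA"))["a", "b"], 0)
  expect_error(p_distance(c(a = "AAA", b = "AAAA")), "ragged")
  expect_error(p_distance(c(a = "--AA", b = "TT--")), "comparable")
  # Poisson correction
  d <- p_distance(c(a = "AAAA", b = "AAAT"), model = "poisson")
  expect_equal(d["a", "b"], -log(0.75))
})

test_that("neighbor joining solves the additive 4-taxon example", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  tree <- neighbor_joining(d)
  expect_identical(nrow(tree$edge), 5L)  # 2n - 3
  paths <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(paths, d, tolerance = 1e-12)
  # AB|CD split with pendant branches 1,2,3,4 and internal branch 1
  tip_len <- setNames(
    tree$edge.length[match(seq_along(tree$tip.label), tree$edge[, 2])],
    tree$tip.label)
  expect_equal(tip_len[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4))
  internal <- tree$edge.length[tree$edge[, 2] > length(tree$tip.label)]
  expect_equal(internal, 1)
})

test_that("three taxa resolve by the three-point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  tree <- neighbor_joining(d)
  expect_identical(nrow(tree$edge), 3L)
  expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
})

test_that("NJ reproduces random additive matrices exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:8, 1)
    gen <- ape::rtree(n, rooted = FALSE)
    gen$edge.length <- runif(nrow(gen$edge), 0.1, 2)
    d <- ape::cophenetic.phylo(gen)
    tree <- neighbor_joining(d)
    paths <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
    expect_equal(paths, d, tolerance = 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tree)), 0)
  }
})

test_that("NJ agrees with the ape reference on noisy matrices", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(5:8, 1)
    x <- matrix(runif(n * n, 0.1, 1), n)
    x <- (x + t(x)) / 2; diag(x) <- 0
    rownames(x) <- colnames(x) <- paste0("t", seq_len(n))
    mine <- neighbor_joining(x)
    ref <- ape::nj(stats::as.dist(x))
    expect_equal(as.numeric(ape::dist.topo(mine, ape::unroot(ref))), 0)
  }
})

test_that("bootstrap supports behave and are seed-deterministic", {
  # two maximally distinct clades with many diagnostic columns
  set.seed(3)
  left <- rand_dna(200)
  right <- paste(rev(strsplit(rand_dna(200), "")[[1]]), collapse = "")
  mut <- function(s, k) {
    for (i in sample(nchar(s), k)) {
      old <- substr(s, i, i)
      substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
    s
  }
  aln <- c(L1 = left, L2 = mut(left, 4), L3 = mut(left, 4),
           R1 = right, R2 = mut(right, 4), R3 = mut(right, 4))
  tree <- bootstrap_support(aln, n_replicates = 100, seed = 7)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  expect_gte(max(sup, na.rm = TRUE), 0.99)
  # determinism
  tree2 <- bootstrap_support(aln, n_replicates = 100, seed = 7)
  expect_identical(tree$node.label, tree2$node.label)
  # single replicate: supports are 0 or 1
  tree1 <- bootstrap_support(aln, n_replicates = 1, seed = 1)
  sup1 <- suppressWarnings(as.numeric(tree1$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 1)))
})

test_that("bipartition supports are invariant to taxon input order", {
  set.seed(9)
  aln <- setNames(replicate(6, rand_dna(80)), paste0("s", 1:6))
  t1 <- bootstrap_support(aln, n_replicates = 50, seed = 4)
  t2 <- bootstrap_support(aln[sample(6)], n_replicates = 50, seed = 4)
  key_support <- function(phy) {
    ntip <- length(phy$tip.label)
    sets <- lapply(1:(ntip + phy$Nnode), function(i) NULL)
    for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
    eo <- ape::reorder.phylo(phy, "postorder")$edge
    for (k in seq_len(nrow(eo)))
      sets[[eo[k, 1]]] <- c(sets[[eo[k, 1]]], sets[[eo[k, 2]]])
    tips <- sort(phy$tip.label)
    out <- c()
    for (node in (ntip + 1):(ntip + phy$Nnode)) {
      side <- sets[[node]]
      if (length(side) < 2 || length(side) > ntip - 2) next
      if (tips[1] %in% side) side <- setdiff(tips, side)
      out[paste(sort(side), collapse = "|")] <-
        phy$node.label[node - ntip]
    }
    out[order(names(out))]
  }
  expect_identical(key_support(t1), key_support(t2))
})

test_that("subgroup assignment follows the clade and tie rules", {
  # query sister to two A-2 references
  tree <- ape::read.tree(
    text = "((Q:0.1,(R2a:0.1,R2b:0.1):0.05):0.5,(R1a:0.1,R1b:0.1):0.5,X:1);")
  labels <- c(R2a = "A-2", R2b = "A-2", R1a = "A-1", R1b = "A-1")
  got <- assign_subgroups(tree, labels)
  expect_identical(got$label[got$query == "Q"], "A-2")
  expect_identical(got$method[got$query == "Q"], "clade")
  # equidistant references with equal means: lexicographic label wins
  star <- ape::read.tree(text = "(Q:1,Ra:1,Rb:1);")
  got2 <- assign_subgroups(star, c(Ra = "A-4", Rb = "A-1"))
  expect_identical(got2$label[got2$query == "Q"], "A-1")
  expect_identical(got2$method[got2$query == "Q"], "nearest")
  expect_error(assign_subgroups(star, c(Z = "A-1")), "no labeled")
})

test_that("assignment is deterministic and references stay put", {
  fam <- gen_protein_family(n_per_subgroup = c("A-1" = 3, "A-2" = 3,
                                               "A-5" = 3),
                            seed = 8)
  tree <- neighbor_joining(p_distance(fam$proteins$sequences[
    grepl("^(PV|REF)_", names(fam$proteins))]))
  a1 <- assign_subgroups(tree, fam$reference_labels)
  a2 <- assign_subgroups(tree, fam$reference_labels)
  expect_identical(a1, a2)
  expect_false(any(names(fam$reference_labels) %in% a1$query))
})
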