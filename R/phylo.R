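# Criterion 4: distances, neighbor-joining, bootstrap supports and
# reference-anchored subgroup assignment (A-1..A-6).
#
# The tree container is ape's "phylo"; newick serialization goes through
# ape. The distance and agglomeration logic itself is implemented here.

as_char_matrix <- function(alignment) {
  seqs <- if (inherits(alignment, "seq_set")) alignment$sequences
          else alignment
  if (length(seqs) < 2) stop("need at least 2 sequences")
  L <- nchar(seqs)
  if (length(unique(L)) != 1)
    stop("ragged alignment: sequences differ in length")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

pdist_from_matrix <- function(m) {
  n <- nrow(m)
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0L)
        stop("no comparable columns between '", rownames(m)[i],
             "' and '", rownames(m)[j], "'")
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / nc
    }
  }
  d
}

#' Proportion distance between aligned sequences
#'
#' Pairwise p-distance: mismatches over compared columns, skipping
#' columns where either sequence carries a gap (`-` or `.`).
#'
#' @param alignment a [seq_set] or named character vector of equal
#'   length (aligned) sequences.
#' @param model `"p"` for the raw proportion or `"poisson"` for the
#'   Poisson-corrected distance `-log(1 - p)`.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  d <- pdist_from_matrix(as_char_matrix(alignment))
  if (model == "poisson") {
    if (any(d >= 1)) stop("Poisson correction undefined at p = 1")
    d <- -log(1 - d)
  }
  d
}

# lexicographically-first (i, j) minimizing Q; strict < keeps first
min_q_pair <- function(D, R, m) {
  best <- Inf; bi <- 1L; bj <- 2L
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      q <- (m - 2) * D[i, j] - R[i] - R[j]
      if (q < best - 1e-12) { best <- q; bi <- i; bj <- j }
    }
  }
  c(bi, bj)
}

fmt_bl <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration: at each step the pair minimizing
#' the Q criterion is joined, with the usual branch-length formulas;
#' ties in Q are broken by the smallest index pair and the freshly
#' joined cluster is appended after the remaining ones. Negative branch
#' lengths are clamped to zero with the deficit moved to the sibling
#' branch; the number of clamped branches is attached as attribute
#' `"clamped"`. Additive distances are reproduced exactly by tree path
#' lengths.
#'
#' @param dm symmetric numeric matrix with row/column names (or a
#'   `dist` object) of pairwise distances.
#' @return An unrooted [ape::phylo] tree (basal trifurcation, `2n - 3`
#'   edges).
#' @export
neighbor_joining <- function(dm) {
  D <- as.matrix(dm)
  labs <- rownames(D)
  n <- nrow(D)
  if (is.null(labs)) stop("distance matrix needs row names")
  if (n < 3) stop("neighbor-joining needs at least 3 taxa")
  if (any(abs(D - t(D)) > 1e-9)) stop("distance matrix not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(grepl("[(),:;]", labs))) stop("taxon labels unsafe for newick")
  frag <- labs
  clamped <- 0L
  while (nrow(D) > 3) {
    m <- nrow(D)
    R <- rowSums(D)
    ij <- min_q_pair(D, R, m)
    i <- ij[1]; j <- ij[2]
    vi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0; clamped <- clamped + 1L }
    if (vj < 0) { vi <- vi + vj; vj <- 0; clamped <- clamped + 1L }
    newfrag <- paste0("(", frag[i], ":", fmt_bl(vi), ",",
                      frag[j], ":", fmt_bl(vj), ")")
    keep <- setdiff(seq_len(m), c(i, j))
    dnew <- 0.5 * (D[i, keep] + D[j, keep] - D[i, j])
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew),
               c(dnew, 0))
    frag <- c(frag[keep], newfrag)
    rownames(D) <- colnames(D) <- NULL
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- c(v1, v2, v3)
  if (any(v < 0)) { clamped <- clamped + sum(v < 0); v <- pmax(v, 0) }
  nwk <- paste0("(", frag[1], ":", fmt_bl(v[1]), ",",
                frag[2], ":", fmt_bl(v[2]), ",",
                frag[3], ":", fmt_bl(v[3]), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# tip labels descending from every node under the stored (arbitrary)
# rooting of the phylo object
node_tip_sets <- function(phy) {
  n <- length(phy$tip.label)
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    sets[[eo[k, 1]]] <- c(sets[[eo[k, 1]]], sets[[eo[k, 2]]])
  sets
}

# canonical keys of the non-trivial bipartitions of an unrooted tree:
# each side is flipped, if needed, so it excludes the alphabetically
# first taxon, then sorted and pasted
bipartition_keys <- function(phy) {
  tips <- sort(phy$tip.label)
  n <- length(tips)
  sets <- node_tip_sets(phy)
  keys <- character(0)
  for (node in (n + 1):(n + phy$Nnode)) {
    side <- sets[[node]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' per replicate, and scores every internal edge of the full-alignment
#' tree by the fraction of replicate trees containing the same
#' bipartition. Supports (in `[0, 1]`) are stored as internal-node
#' labels; the basal node, which corresponds to no edge, is labeled
#' `NA`.
#'
#' @param alignment a [seq_set] or named character vector of aligned
#'   sequences.
#' @param n_replicates number of bootstrap replicates (the pipeline
#'   default is 1000).
#' @param seed integer seed; results are reproducible given
#'   `(alignment, n_replicates, seed)`.
#' @param model distance model passed to [p_distance].
#' @return An [ape::phylo] tree with numeric-valued `node.label`
#'   supports.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1,
                              model = "p") {
  stopifnot(n_replicates >= 1)
  m <- as_char_matrix(alignment)
  # canonical taxon order: supports must not depend on input order
  # (index-based tie-breaks in NJ would otherwise leak through)
  m <- m[order(rownames(m)), , drop = FALSE]
  L <- ncol(m)
  if (L < 4) warning("alignment has fewer than 4 columns; supports unstable")
  pd <- function(mat, mdl) {
    d <- pdist_from_matrix(mat)
    if (mdl == "poisson") d <- -log(1 - d)
    d
  }
  tree <- neighbor_joining(pd(m, model))
  keys0 <- bipartition_keys(tree)
  counts <- setNames(numeric(length(keys0)), keys0)
  set.seed(seed)
  used <- 0L
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_tree <- tryCatch(neighbor_joining(pd(m[, cols, drop = FALSE], model)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    used <- used + 1L
    hit <- intersect(bipartition_keys(rep_tree), keys0)
    counts[hit] <- counts[hit] + 1
  }
  if (used < n_replicates)
    warning(n_replicates - used, " replicate(s) failed (all-gap pair) ",
            "and were skipped")
  support <- counts / max(used, 1L)
  # map supports back onto internal nodes
  ntip <- length(tree$tip.label)
  tips_sorted <- sort(tree$tip.label)
  sets <- node_tip_sets(tree)
  labs <- rep(NA_character_, tree$Nnode)
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    side <- sets[[node]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (tips_sorted[1] %in% side) side <- setdiff(tips_sorted, side)
    labs[node - ntip] <- fmt_bl(support[[paste(sort(side), collapse = "|")]])
  }
  tree$node.label <- labs
  attr(tree, "n_replicates_used") <- used
  tree
}

#' Assign query taxa to subgroups from labeled reference taxa
#'
#' Each unlabeled tip is assigned the label of the smallest clade
#' (bipartition side) that contains it together with at least one
#' reference and whose references all carry the same label. When the
#' smallest reference-containing clade mixes labels, the query falls
#' back to the nearest labeled leaf by path length; distance ties are
#' broken by the smallest mean path distance to the tied label's
#' references, then by lexicographic label order.
#'
#' @param tree an [ape::phylo] tree containing both queries and
#'   references.
#' @param reference_labels named character vector: names are reference
#'   tip ids, values subgroup labels (e.g. `"A-1"` .. `"A-6"`).
#' @return A data frame: `query`, `label`, `method`
#'   (`"clade"`/`"nearest"`), `n_refs`, `supporting_refs`
#'   (comma-separated), `mean_ref_distance`.
#' @export
assign_subgroups <- function(tree, reference_labels) {
  stopifnot(inherits(tree, "phylo"))
  refs <- intersect(names(reference_labels), tree$tip.label)
  if (length(refs) == 0) stop("no labeled references present in the tree")
  labels <- reference_labels[refs]
  queries <- setdiff(tree$tip.label, refs)
  dmat <- ape::cophenetic.phylo(tree)
  ntip <- length(tree$tip.label)
  sets <- node_tip_sets(tree)
  # all bipartition sides (both orientations) plus the full tip set
  sides <- list()
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    s <- sets[[node]]
    if (length(s) >= 2 && length(s) <= ntip - 1) {
      sides[[length(sides) + 1L]] <- s
      comp <- setdiff(tree$tip.label, s)
      if (length(comp) >= 2) sides[[length(sides) + 1L]] <- comp
    }
  }
  sides[[length(sides) + 1L]] <- tree$tip.label
  out <- data.frame(query = queries, label = NA_character_,
                    method = NA_character_, n_refs = NA_integer_,
                    supporting_refs = NA_character_,
                    mean_ref_distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(queries)) {
    q <- queries[k]
    cand <- Filter(function(s) q %in% s && any(refs %in% s), sides)
    sizes <- vapply(cand, length, integer(1))
    ord <- order(sizes, vapply(cand, function(s)
      paste(sort(s), collapse = "|"), character(1)))
    smallest <- cand[[ord[1]]]
    srefs <- intersect(refs, smallest)
    slabs <- unique(labels[srefs])
    if (length(slabs) == 1) {
      out$label[k] <- slabs
      out$method[k] <- "clade"
      out$n_refs[k] <- length(srefs)
      out$supporting_refs[k] <- paste(sort(srefs), collapse = ",")
      out$mean_ref_distance[k] <- mean(dmat[q, srefs])
      next
    }
    # nearest labeled leaf, with the documented tie-breaks
    dref <- dmat[q, refs]
    dmin_by_label <- tapply(dref, labels, min)
    dmean_by_label <- tapply(dref, labels, mean)
    best <- min(dref)
    tied <- names(dmin_by_label)[dmin_by_label <= best + 1e-12]
    if (length(tied) > 1) {
      mm <- dmean_by_label[tied]
      tied <- tied[mm <= min(mm) + 1e-12]
      tied <- sort(tied)
    }
    lab <- tied[1]
    lrefs <- refs[labels == lab]
    out$label[k] <- lab
    out$method[k] <- "nearest"
    out$n_refs[k] <- length(lrefs)
    out$supporting_refs[k] <-
      paste(sort(lrefs[dref[lrefs] <= min(dref[lrefs]) + 1e-12]),
            collapse = ",")
    out$mean_ref_distance[k] <- mean(dref[lrefs])
  }
  out
}
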