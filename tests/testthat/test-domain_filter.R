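make_family <- function(specs) {
  # specs: list of list(id, domains = data.frame(name, start, end))
  seqs <- character(0); dom <- list()
  set.seed(11)
  for (sp in specs) {
    seqs[sp$id] <- rand_protein(300)
    if (!is.null(sp$domains))
      for (k in seq_len(nrow(sp$domains)))
        dom[[length(dom) + 1]] <- data.frame(
          protein_id = sp$id, domain_name = sp$domains$name[k],
          start = sp$domains$start[k], end = sp$domains$end[k])
  }
  list(proteins = seq_set(seqs),
       domains = if (length(dom)) do.call(rbind, dom) else
         data.frame(protein_id = character(0),
                    domain_name = character(0),
                    start = numeric(0), end = numeric(0)))
}

test_that("family classes follow the AP2/B3 domain-count rules", {
  fam <- make_family(list(
    list(id = "erf", domains = data.frame(name = "AP2", start = 30,
                                          end = 89)),
    list(id = "rav", domains = data.frame(name = c("AP2", "B3"),
                                          start = c(30, 120),
                                          end = c(89, 200))),
    list(id = "ap2", domains = data.frame(name = rep("AP2", 3),
                                          start = c(10, 80, 150),
                                          end = c(69, 139, 209))),
    list(id = "none", domains = NULL)))
  cls <- classify_family(fam$proteins, fam$domains)
  got <- setNames(cls$class, cls$protein_id)
  expect_identical(got[["erf"]], "ERF_candidate")
  expect_identical(got[["rav"]], "RAV")
  expect_identical(got[["ap2"]], "AP2_family")
  expect_identical(got[["none"]], "other")
  expect_identical(as.integer(attr(cls, "counts")), rep(1L, 4))
})

test_that("domain rows out of bounds or unknown proteins error", {
  fam <- make_family(list(
    list(id = "p1", domains = data.frame(name = "AP2", start = 280,
                                         end = 340))))
  expect_error(classify_family(fam$proteins, fam$domains), "bounds")
  fam2 <- make_family(list(
    list(id = "p1", domains = data.frame(name = "AP2", start = 30,
                                         end = 89))))
  bad <- rbind(fam2$domains,
               data.frame(protein_id = "ghost", domain_name = "AP2",
                          start = 1, end = 60))
  expect_error(classify_family(fam2$proteins, bad), "unknown")
})

test_that("the V14/E19 rule keys retention on valine only", {
  p <- protein_with_domain("V", "E")
  r <- check_residue_rule(p$seq, p$start, p$end)
  expect_identical(r$status, "canonical_VE")
  expect_true(r$retained)
  p <- protein_with_domain("A", "D")
  r <- check_residue_rule(p$seq, p$start, p$end)
  expect_identical(r$status, "excluded_non_V14")
  expect_false(r$retained)
  p <- protein_with_domain("V", "Q")  # the glutamine-at-19 case is kept
  r <- check_residue_rule(p$seq, p$start, p$end)
  expect_identical(r$status, "V_with_variant_19")
  expect_true(r$retained)
  expect_error(check_residue_rule(p$seq, p$start, p$start + 10),
               "shorter")
})

test_that("57 single-AP2 candidates with 3 planted non-V14 retain 54", {
  set.seed(5)
  specs <- lapply(1:57, function(i)
    list(id = sprintf("C%02d", i),
         domains = data.frame(name = "AP2", start = 30, end = 89)))
  fam <- make_family(specs)
  seqs <- fam$proteins$sequences
  for (i in seq_along(seqs)) {
    substr(seqs[i], 43, 43) <- if (i <= 3) "A" else "V"
    substr(seqs[i], 48, 48) <- "E"
  }
  fam$proteins <- seq_set(seqs)
  res <- apply_dreb_criteria(fam$proteins, fam$domains)
  expect_length(res$retained, 54)
  expect_identical(sum(res$audit$failed_criterion == "criterion3_non_V14",
                       na.rm = TRUE), 3L)
  # audit partition: every protein is retained or has a failing criterion
  expect_identical(sum(res$audit$retained) +
                     sum(!is.na(res$audit$failed_criterion)),
                   nrow(res$audit))
})

test_that("the allow-list intersects retention and is audited", {
  set.seed(6)
  specs <- lapply(1:5, function(i)
    list(id = sprintf("C%d", i),
         domains = data.frame(name = "AP2", start = 30, end = 89)))
  fam <- make_family(specs)
  seqs <- fam$proteins$sequences
  for (i in seq_along(seqs)) substr(seqs[i], 43, 43) <- "V"
  fam$proteins <- seq_set(seqs)
  res <- apply_dreb_criteria(fam$proteins, fam$domains,
                             candidate_ids = c("C1", "C2", "C4", "C5"))
  expect_false("C3" %in% res$retained)
  expect_identical(
    res$audit$failed_criterion[res$audit$protein_id == "C3"],
    "not_in_candidate_list")
})

test_that("retention matches planted truth on generated families", {
  fam <- gen_protein_family(violation_rate = 0.15, seed = 21)
  res <- apply_dreb_criteria(fam$proteins, fam$domains)
  members <- fam$truth[!is.na(fam$truth$retained_expected), ]
  expect_setequal(intersect(res$retained, members$protein_id),
                  members$protein_id[members$retained_expected])
  # retained is a subset of the ERF candidates
  cand <- res$audit$protein_id[res$audit$class == "ERF_candidate"]
  expect_true(all(res$retained %in% cand))
})

test_that("proteins lacking AP2 annotation all fail criterion 1", {
  fam <- make_family(list(list(id = "x1"), list(id = "x2")))
  res <- apply_dreb_criteria(fam$proteins, fam$domains)
  expect_length(res$retained, 0)
  expect_true(all(res$audit$failed_criterion == "criterion1_single_AP2"))
})
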