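test_that("a perfect doubling curve fits E = 2 with r = 1", {
  fit <- fit_efficiency(10 * 2^(1:20), baseline_cycles = NULL)
  expect_equal(fit$efficiency, 2, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-10)
})

test_that("noiseless generator curves are recovered to 3 decimals", {
  g <- gen_amplification_curves(noise_sd = 0, cq_sd = 0, seed = 1)
  f <- g$plate$fluorescence[g$plate$well == "W001"]
  fit <- fit_efficiency(f)
  expect_equal(fit$efficiency, 1.9, tolerance = 5e-4)
  expect_true(fit$accepted)
})

test_that("planted efficiencies are recovered under 1 percent noise", {
  errs <- vapply(1:40, function(s) {
    g <- gen_amplification_curves(genes = "G", true_e = c(G = 1.9),
                                  n_replicates = 1, noise_sd = 0.01,
                                  cq_sd = 0, seed = s)
    fit_efficiency(g$plate$fluorescence)$efficiency - 1.9
  }, numeric(1))
  expect_lte(mean(abs(errs)), 0.02)
  expect_lte(max(abs(errs)), 0.1)
})

test_that("flat curves raise a no-exponential-phase error", {
  set.seed(2)
  expect_error(fit_efficiency(rnorm(40, 100, 1)), "no exponential phase")
  expect_error(fit_efficiency(rep(1, 10)), "15 cycles")
})

test_that("relative expression follows the concentration-ratio formula", {
  cq3 <- function(tcq) data.frame(
    gene = rep(c("T", "R1", "R2"), each = 6),
    condition = rep(rep(c("control", "treated"), each = 3), 3),
    sample = rep(1:3, 6),
    cq = c(rep(25, 3), rep(25 - tcq, 3), rep(25, 12)))
  E2 <- c(T = 2, R1 = 2, R2 = 2)
  expect_equal(relative_expression(cq3(3), "T", c("R1", "R2"), E2)$re, 8)
  expect_equal(relative_expression(cq3(0), "T", c("R1", "R2"), E2)$re, 1)
  expect_equal(relative_expression(cq3(3), "T", c("R1", "R2"),
                                   E2)$log2_re, 3)
  # references with C = 2 and C = 8: geometric mean 4; target C = 4
  cqm <- data.frame(
    gene = rep(c("T", "R1", "R2"), each = 4),
    condition = rep(rep(c("control", "treated"), each = 2), 3),
    sample = rep(1:2, 6),
    cq = c(25, 25, 23, 23,  25, 25, 24, 24,  25, 25, 22, 22))
  out <- relative_expression(cqm, "T", c("R1", "R2"), E2)
  expect_equal(unname(out$c_reference), c(2, 8))
  expect_equal(out$re, 1)
  expect_error(relative_expression(cq3(1)[cq3(1)$condition == "control", ],
                                   "T", c("R1", "R2"), E2), "missing")
  expect_error(relative_expression(cq3(1), "T", c("R1", "R2"),
                                   c(T = 0.9, R1 = 2, R2 = 2)), "1, 2.2")
})

test_that("with E = 2 the ratio reduces to 2^-ddCq on random inputs", {
  set.seed(33)
  for (i in 1:10) {
    cq <- data.frame(
      gene = rep(c("T", "R"), each = 6),
      condition = rep(rep(c("control", "treated"), each = 3), 2),
      sample = rep(1:3, 4),
      cq = rnorm(12, 26, 2))
    out <- relative_expression(cq, "T", "R", c(T = 2, R = 2))
    dcq_t <- mean(cq$cq[cq$gene == "T" & cq$condition == "treated"]) -
      mean(cq$cq[cq$gene == "T" & cq$condition == "control"])
    dcq_r <- mean(cq$cq[cq$gene == "R" & cq$condition == "treated"]) -
      mean(cq$cq[cq$gene == "R" & cq$condition == "control"])
    expect_equal(out$re, 2^-(dcq_t - dcq_r))
  }
})

test_that("the randomization test matches exhaustive enumeration", {
  cq <- data.frame(
    gene = rep(c("T", "R"), each = 6),
    condition = rep(rep(c("control", "treated"), each = 3), 2),
    sample = rep(1:3, 4),
    cq = c(25.1, 25.0, 24.9, 15.2, 15.0, 14.8, rep(25, 6)))
  ex <- randomization_test(cq, "T", "R", c(T = 2, R = 2),
                           exhaustive = TRUE)
  # 3v3 balanced reallocation: 20 label assignments, the observed one
  # and its complement are the only ones as extreme
  expect_identical(ex$n_perm, 19L)
  expect_equal(ex$p_value, 2 / 20)
  samp <- randomization_test(cq, "T", "R", c(T = 2, R = 2),
                             n_perm = 2000, seed = 5)
  expect_lt(abs(samp$p_value - ex$p_value), 0.05)
  # identical replicates: nothing is more extreme than 0
  cq0 <- cq; cq0$cq <- 25
  expect_equal(randomization_test(cq0, "T", "R", c(T = 2, R = 2),
                                  n_perm = 200, seed = 1)$p_value, 1)
})

test_that("the test is invariant to gene names and seed-stable", {
  set.seed(55)
  cq <- data.frame(
    gene = rep(c("T", "R1", "R2"), each = 8),
    condition = rep(rep(c("control", "treated"), each = 4), 3),
    sample = rep(1:4, 6),
    cq = rnorm(24, 25, 0.5))
  p1 <- randomization_test(cq, "T", c("R1", "R2"),
                           c(T = 1.9, R1 = 1.9, R2 = 1.9),
                           n_perm = 500, seed = 9)$p_value
  cq2 <- cq
  cq2$gene <- c(X = "T", Y = "R1", Z = "R2")[
    match(cq$gene, c("T", "R1", "R2"))]
  cq2$gene <- paste0("g_", cq2$gene)
  p2 <- randomization_test(cq2, "g_T", c("g_R1", "g_R2"),
                           c(g_T = 1.9, g_R1 = 1.9, g_R2 = 1.9),
                           n_perm = 500, seed = 9)$p_value
  expect_identical(p1, p2)
  expect_error(randomization_test(
    data.frame(gene = rep("T", 3),
               condition = c("control", "control", "treated"),
               sample = c(1, 2, 1), cq = c(25, 25, 24)),
    "T", character(0), c(T = 2)), "2 replicates")
})

test_that("physiology helpers compute their closed forms", {
  expect_equal(rwc(2.0, 2.5, 0.5), 75)
  expect_equal(rwc(2.5, 2.5, 0.5), 100)
  expect_error(rwc(2, 1, 1), "turgid")
  # catalase: analytic slope recovery and proportionality
  ab <- 1.2 - 0.03 * (0:12) * 10 / 60  # -0.03 absorbance per minute
  r1 <- catalase_rate(ab, 10, protein_mg = 0.5,
                      extinction_coefficient = 39.4, path_cm = 1,
                      volume_ml = 3.16)
  expect_equal(r1, 0.03 / 39.4 * 3.16 / 0.5, tolerance = 1e-9)
  r2 <- catalase_rate(ab, 10, protein_mg = 1,
                      extinction_coefficient = 39.4, path_cm = 1,
                      volume_ml = 3.16)
  expect_equal(r1, 2 * r2)
  expect_equal(catalase_rate(rep(1, 13), 10, 1, 39.4), 0)
  expect_error(catalase_rate(ab, 10, 0, 39.4), "protein")
})
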