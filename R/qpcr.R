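# Amplification-curve efficiency estimation (window-of-linearity),
# Cq determination, efficiency-corrected relative expression with a
# reference-gene geometric mean, the fixed-reallocation randomization
# test, and physiology helpers (relative water content, catalase rate).

#' Fit amplification efficiency from a fluorescence curve
#'
#' Baseline-corrects the curve (mean of `baseline_cycles` subtracted),
#' then scans all windows of `window_sizes` consecutive cycles lying in
#' the exponential phase: corrected fluorescence strictly positive,
#' above a noise floor (the larger of 10 standard deviations of the
#' corrected baseline cycles and 0.01 percent of the curve maximum;
#' points near the baseline carry a relative error from baseline
#' subtraction that biases the slope), and below 5 percent of the curve
#' maximum (the onset of plateau curvature). The window maximizing the
#' correlation r of log10(fluorescence) with cycle number is selected;
#' windows whose r lies within four times the best window's distance
#' from perfect correlation are treated as statistically equivalent,
#' and among those the longest, then highest-signal, then earliest
#' window wins — under noise this trades a negligible amount of r for a
#' markedly more stable slope. The per-cycle
#' amplification factor is `E = 10^slope`. The quantification cycle Cq
#' is where the window's regression line crosses the threshold, placed
#' by default at the geometric midpoint of the window's corrected
#' fluorescence. A fit is accepted when `1.8 <= E <= 2.0` and
#' `r >= 0.995`.
#'
#' @param fluorescence numeric vector of per-cycle fluorescence
#'   readings (cycles 1, 2, ...; at least 15).
#' @param baseline_cycles cycles averaged for the baseline (default
#'   1:8); `NULL` skips baseline correction.
#' @param window_sizes candidate window lengths in cycles (default
#'   4:6).
#' @param threshold fixed fluorescence threshold for Cq; `NULL` (the
#'   default) uses the selected window's geometric midpoint.
#' @param e_bounds acceptance bounds on E (default `c(1.8, 2.0)`).
#' @param min_r acceptance bound on the window correlation (default
#'   0.995).
#' @return A list of class `efficiency_fit`: `efficiency`, `slope`,
#'   `r`, `window` (first and last cycle), `cq`, `threshold`,
#'   `baseline`, `accepted`.
#' @export
fit_efficiency <- function(fluorescence, baseline_cycles = 1:8,
                           window_sizes = 4:6, threshold = NULL,
                           e_bounds = c(1.8, 2.0), min_r = 0.995) {
  f <- as.numeric(fluorescence)
  n <- length(f)
  if (n < 15) stop("need at least 15 cycles")
  if (any(!is.finite(f))) stop("non-finite fluorescence")
  baseline <- if (is.null(baseline_cycles)) 0 else
    mean(f[baseline_cycles])
  fc <- f - baseline
  noise_floor <- 0
  ceiling_level <- Inf
  if (!is.null(baseline_cycles)) {
    noise_floor <- max(10 * sd(fc[baseline_cycles]),
                       1e-4 * max(fc), 0)
    if (!is.finite(noise_floor)) noise_floor <- 0
    ceiling_level <- 0.05 * max(fc)
  }
  cand <- list()
  for (w in window_sizes) {
    for (s in seq_len(n - w + 1L)) {
      idx <- s:(s + w - 1L)
      y <- fc[idx]
      if (any(y <= 0) || any(y <= noise_floor) || max(y) > ceiling_level)
        next
      ly <- log10(y)
      r <- suppressWarnings(cor(idx, ly))
      if (!is.finite(r)) next
      cand[[length(cand) + 1L]] <- list(
        r = r, slope = cov(idx, ly) / var(idx), start = s, w = w,
        idx = idx, top = max(y))
    }
  }
  if (length(cand) == 0L)
    stop("no exponential phase: no window with positive corrected signal")
  rmax <- max(vapply(cand, `[[`, numeric(1), "r"))
  keep <- Filter(function(x) x$r >= 1 - (1 - rmax) * 4 - 1e-12, cand)
  ord <- order(-vapply(keep, `[[`, numeric(1), "w"),
               -vapply(keep, `[[`, numeric(1), "top"),
               vapply(keep, `[[`, numeric(1), "start"))
  best <- keep[[ord[1]]]
  idx <- best$idx
  ly <- log10(fc[idx])
  slope <- best$slope
  intercept <- mean(ly) - slope * mean(idx)
  efficiency <- 10^slope
  thr <- if (is.null(threshold))
    sqrt(fc[idx[1]] * fc[idx[length(idx)]]) else threshold
  cq <- (log10(thr) - intercept) / slope
  tol <- 1e-4  # float guard on the acceptance band
  structure(list(
    efficiency = efficiency, slope = slope, intercept = intercept,
    r = best$r, window = c(idx[1], idx[length(idx)]), cq = cq,
    threshold = thr, baseline = baseline,
    accepted = efficiency >= e_bounds[1] - tol &
      efficiency <= e_bounds[2] + tol & best$r >= min_r),
    class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf(
    "efficiency_fit: E = %.4f, r = %.5f, window %d-%d, Cq = %.3f (%s)\n",
    x$efficiency, x$r, x$window[1], x$window[2], x$cq,
    if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

check_cq_table <- function(cq, target, references) {
  needed <- c("gene", "condition", "cq")
  if (!all(needed %in% names(cq)))
    stop("cq table needs columns: ", paste(needed, collapse = ", "))
  genes <- c(target, references)
  for (g in genes) {
    for (cond in c("control", "treated")) {
      if (!any(cq$gene == g & cq$condition == cond))
        stop("missing ", cond, " replicates for gene ", g)
    }
  }
}

gene_concentration <- function(cq, gene, efficiency) {
  d <- mean(cq$cq[cq$gene == gene & cq$condition == "control"]) -
       mean(cq$cq[cq$gene == gene & cq$condition == "treated"])
  efficiency^d
}

#' Efficiency-corrected relative expression
#'
#' Computes, per gene, the expression concentration
#' `C = E^(mean Cq_control - mean Cq_treated)` and the relative
#' expression ratio `RE = C_target / geometric mean of C_reference`.
#' With `E = 2` for all genes this reduces to the classical
#' `2^-ddCq` formula.
#'
#' @param cq data frame with columns `gene`, `condition`
#'   (`control`/`treated`), `cq` (one row per replicate; a `sample`
#'   column, when present, identifies replicate pairing across genes).
#' @param target target gene name.
#' @param references character vector of reference gene names.
#' @param efficiency named numeric vector of per-gene amplification
#'   factors in `(1, 2.2]`, covering target and references.
#' @return A list of class `expression_result`: `target`, `c_target`,
#'   `c_reference` (named per reference), `re`, `log2_re`.
#' @export
relative_expression <- function(cq, target, references, efficiency) {
  check_cq_table(cq, target, references)
  genes <- c(target, references)
  miss <- setdiff(genes, names(efficiency))
  if (length(miss))
    stop("efficiency missing for gene(s): ", paste(miss, collapse = ", "))
  if (any(efficiency[genes] <= 1 | efficiency[genes] > 2.2))
    stop("efficiencies must lie in (1, 2.2]")
  c_target <- gene_concentration(cq, target, efficiency[[target]])
  c_ref <- vapply(references, function(g)
    gene_concentration(cq, g, efficiency[[g]]), numeric(1))
  re <- c_target / exp(mean(log(c_ref)))
  structure(list(target = target, c_target = c_target,
                 c_reference = c_ref, re = re, log2_re = log2(re)),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("expression_result: %s RE = %.4g (log2 = %.3f)",
              x$target, x$re, x$log2_re))
  if (!is.null(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Fixed-reallocation randomization test for relative expression
#'
#' Two-sided permutation test of the observed `log(RE)` against the
#' null built by reallocating control/treated labels among whole
#' replicate samples, jointly across all genes (labels are swapped for
#' a sample as a unit, so every gene's Cq for that sample moves with
#' it), keeping group sizes fixed. The p-value uses the add-one
#' estimator `(1 + #{|perm| >= |obs|}) / (1 + n_perm)`.
#'
#' @inheritParams relative_expression
#' @param n_perm number of random reallocations (default 2000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param exhaustive when `TRUE`, enumerate all balanced reallocations
#'   instead of sampling (feasible for small replicate counts); `n_perm`
#'   is then ignored.
#' @return An `expression_result` (as [relative_expression]) with
#'   additional fields `p_value`, `n_perm`, `observed_stat`.
#' @export
randomization_test <- function(cq, target, references, efficiency,
                               n_perm = 2000, seed = 1,
                               exhaustive = FALSE) {
  res <- relative_expression(cq, target, references, efficiency)
  genes <- c(target, references)
  if (!"sample" %in% names(cq))
    cq$sample <- stats::ave(seq_len(nrow(cq)),
                            cq$gene, cq$condition, FUN = seq_along)
  cq$sample_key <- paste(cq$condition, cq$sample, sep = ":")
  samples <- unique(cq$sample_key)
  cond <- vapply(samples, function(s)
    unique(cq$condition[cq$sample_key == s]), character(1))
  n_ctrl <- sum(cond == "control"); n_trt <- sum(cond == "treated")
  if (n_ctrl < 2 || n_trt < 2)
    stop("need at least 2 replicates per condition")
  # gene x sample Cq matrix (replicates must pair across genes)
  M <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  for (g in genes) {
    for (s in samples) {
      v <- cq$cq[cq$gene == g & cq$sample_key == s]
      if (length(v) != 1)
        stop("replicate structure must pair samples across genes")
      M[g, s] <- v
    }
  }
  logE <- log(efficiency[genes])
  stat_for <- function(ctrl_idx) {
    is_ctrl <- seq_along(samples) %in% ctrl_idx
    dcq <- rowMeans(M[, is_ctrl, drop = FALSE]) -
           rowMeans(M[, !is_ctrl, drop = FALSE])
    logC <- logE * dcq
    logC[[target]] - mean(logC[references])
  }
  obs <- stat_for(which(cond == "control"))
  if (exhaustive) {
    combos <- utils::combn(length(samples), n_ctrl)
    perm <- apply(combos, 2, stat_for)
    # drop the identity reallocation from the reference set
    ctrl_set <- sort(unname(which(cond == "control")))
    id_col <- which(vapply(seq_len(ncol(combos)), function(k)
      identical(sort(combos[, k]), ctrl_set), logical(1)))
    perm_stats <- if (length(id_col)) perm[-id_col] else perm
    p <- (1 + sum(abs(perm_stats) >= abs(obs) - 1e-12)) /
      (1 + length(perm_stats))
    n_used <- length(perm_stats)
  } else {
    set.seed(seed)
    perm_stats <- vapply(seq_len(n_perm), function(b)
      stat_for(sample(seq_along(samples), n_ctrl)), numeric(1))
    p <- (1 + sum(abs(perm_stats) >= abs(obs) - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  res$p_value <- p
  res$n_perm <- n_used
  res$observed_stat <- obs
  res
}

#' Relative water content
#'
#' `RWC (%) = (FW - DW) / (TW - DW) * 100` from fresh, turgid and dry
#' weights.
#'
#' @param fresh_weight,turgid_weight,dry_weight weights in the same
#'   unit; `turgid_weight > dry_weight`.
#' @return RWC in percent.
#' @export
rwc <- function(fresh_weight, turgid_weight, dry_weight) {
  if (any(turgid_weight <= dry_weight))
    stop("turgid weight must exceed dry weight")
  if (any(fresh_weight < dry_weight))
    stop("fresh weight below dry weight")
  (fresh_weight - dry_weight) / (turgid_weight - dry_weight) * 100
}

#' Catalase activity from an absorbance decay series
#'
#' Fits a least-squares slope to absorbance vs time (readings at fixed
#' intervals, e.g. every 10 s over 2 min) and converts it via
#' Beer-Lambert: `rate = |slope| / (extinction_coefficient * path_cm) *
#' volume_ml / protein_mg`, in umol min^-1 mg^-1 protein when the
#' extinction coefficient is in mM^-1 cm^-1.
#'
#' @param absorbance numeric vector of at least 3 readings.
#' @param interval_s seconds between readings (default 10).
#' @param protein_mg protein amount in the assay (mg), > 0.
#' @param extinction_coefficient substrate extinction coefficient in
#'   mM^-1 cm^-1 (no default; assay-specific).
#' @param path_cm optical path length (default 1).
#' @param volume_ml reaction volume in mL (default 1).
#' @return Activity in umol min^-1 mg^-1.
#' @export
catalase_rate <- function(absorbance, interval_s = 10, protein_mg,
                          extinction_coefficient, path_cm = 1,
                          volume_ml = 1) {
  if (length(absorbance) < 3) stop("need at least 3 time points")
  if (protein_mg <= 0) stop("protein_mg must be positive")
  if (extinction_coefficient <= 0)
    stop("extinction_coefficient must be positive")
  t_min <- (seq_along(absorbance) - 1) * interval_s / 60
  slope <- cov(t_min, absorbance) / var(t_min)  # dA per minute
  abs(slope) / (extinction_coefficient * path_cm) * volume_ml / protein_mg
}
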