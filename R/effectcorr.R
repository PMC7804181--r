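# Correlation of true SNP effects between two summary-statistic sets.
#
# Estimated effects are true effects plus estimation error, so the naive
# correlation of b-hats is attenuated and, with overlapping samples,
# contaminated by correlated errors. The moment estimator used here removes
# both: true-effect variances are var(b) minus the mean squared SE, the
# true-effect covariance subtracts a sample-overlap term estimated from the
# mean product of z-scores at null SNPs, and the standard error comes from a
# delete-one-SNP jackknife.

rb_moments <- function(b1, b2, se1, se2, r_p) {
  k <- length(b1)
  v1 <- var(b1) - mean(se1^2)
  v2 <- var(b2) - mean(se2^2)
  cv <- cov(b1, b2) - r_p * mean(se1 * se2)
  vp <- v1 * v2
  list(v1 = v1, v2 = v2, cov = cv,
       rb = if (vp > 0) cv / sqrt(vp) else NA_real_)
}

#' Estimate the correlation of true SNP effects between two scans
#'
#' @param set1,set2 `assoc_result` objects; alleles are harmonised to
#'   `set1`.
#' @param snps Optional SNP ids (or indices into the shared panel) defining
#'   the estimation set; defaults to all shared SNPs. In simulations the true
#'   causal set is the natural choice.
#' @param overlap If `TRUE`, the two scans come from overlapping samples and
#'   the error-covariance term is estimated from the mean product of z-scores
#'   at null SNPs (|z| below `null_z` in both scans) and removed.
#' @param null_z Null-SNP z threshold for the overlap term.
#' @return An `rb_estimate`: `rb` (clamped to `[-1, 1]`), `rb_raw`, `se`
#'   (jackknife), `n_snps`, `overlap_term`, `clamped`, and the moment
#'   diagnostics `v1`, `v2`, `cov`.
#' @export
estimate_rb <- function(set1, set2, snps = NULL, overlap = FALSE,
                        null_z = 2) {
  shared <- intersect(set1$snp, set2$snp)
  s1 <- set1[match(shared, set1$snp), , drop = FALSE]
  s2 <- harmonise_to(s1, set2)
  ok <- is.finite(s1$beta) & is.finite(s2$beta) &
    is.finite(s1$se) & is.finite(s2$se) & s1$se > 0 & s2$se > 0
  s1 <- s1[ok, ]; s2 <- s2[ok, ]
  r_p <- 0
  if (overlap) {
    z1 <- s1$beta / s1$se; z2 <- s2$beta / s2$se
    null_set <- abs(z1) < null_z & abs(z2) < null_z
    if (sum(null_set) >= 10) {
      r_p <- mean(z1[null_set] * z2[null_set])
    } else {
      warning("fewer than 10 null SNPs; overlap term set to 0")
    }
  }
  if (!is.null(snps)) {
    keep <- if (is.numeric(snps)) s1$snp %in% set1$snp[snps]
            else s1$snp %in% snps
    s1 <- s1[keep, ]; s2 <- s2[keep, ]
  }
  k <- nrow(s1)
  if (k < 3L) stop("need at least 3 shared SNPs", call. = FALSE)
  b1 <- s1$beta; b2 <- s2$beta; se1 <- s1$se; se2 <- s2$se
  mo <- rb_moments(b1, b2, se1, se2, r_p)
  if (mo$v1 <= 0 || mo$v2 <= 0) {
    cond <- structure(
      class = c("mlcbias_unstable_rb_error", "error", "condition"),
      list(message = sprintf(
        paste0("estimation-error variance exceeds effect-size variance ",
               "(var_true_1 = %.3g, var_true_2 = %.3g); the SNP-effect ",
               "correlation is not identified on this set"),
        mo$v1, mo$v2),
        call = sys.call(-1)))
    stop(cond)
  }
  jk <- vapply(seq_len(k), function(i) {
    rb_moments(b1[-i], b2[-i], se1[-i], se2[-i], r_p)$rb
  }, numeric(1))
  jk_ok <- is.finite(jk)
  if (!all(jk_ok))
    warning("some jackknife replicates unstable; SE uses finite replicates")
  kk <- sum(jk_ok)
  se <- sqrt((kk - 1) / kk * sum((jk[jk_ok] - mean(jk[jk_ok]))^2))
  structure(list(rb = max(-1, min(1, mo$rb)), rb_raw = mo$rb, se = se,
                 n_snps = k, overlap_term = r_p * mean(se1 * se2),
                 clamped = abs(mo$rb) > 1,
                 v1 = mo$v1, v2 = mo$v2, cov = mo$cov),
            class = "rb_estimate")
}

#' @export
print.rb_estimate <- function(x, ...) {
  cat(sprintf("<rb_estimate> rb = %.3f (se %.3f, jackknife over %d SNPs)%s\n",
              x$rb, x$se, x$n_snps,
              if (x$clamped) sprintf(" [raw %.3f clamped]", x$rb_raw) else ""))
  invisible(x)
}

# one simulated replicate: scans of reported behaviour and liability
scan_pair <- function(coh, corrected, rules, covariates = NULL) {
  if (is.null(covariates)) covariates <- default_covariates(coh)
  ys <- if (corrected) {
    ivw_meta(stratified_gwas(coh, rules, covariates = covariates))
  } else {
    scan_standardized(coh, rules, covariates)
  }
  ds <- run_gwas(coh$genotypes, coh$liability_d, covariates)
  list(y = ys, d = ds)
}

#' SNP-effect correlation across an ascertainment grid
#'
#' For each (q, c) on the grid and each replicate: simulate a cohort from
#' `cfg`, apply ascertainment, scan the reported behaviour (uncorrected
#' full-sample scan, or the stratified + IVW-meta corrected scan), scan
#' liability, and estimate the SNP-effect correlation on the union of the
#' true causal sets. Reports the mean and SEM per grid point.
#'
#' @param cfg A [scenario_config()].
#' @param q_grid,c_grid Ascertainment grids (defaults: the study grid).
#' @param reps Replicates per grid point.
#' @param corrected Use the two-group stratified correction for the
#'   behaviour scan.
#' @param rules QC rules for the corrected scan; stratification-only by
#'   default (no reason-based removal, so the demonstration rests on the
#'   partition itself).
#' @param overlap Passed to [estimate_rb()] (the two scans share a sample).
#' @param seed Root seed; defaults to `cfg$seed`.
#' @return A data.frame (`rb_grid`) with `q`, `c`, `mean_rb`, `sem_rb`,
#'   `reps_ok`; per-replicate values in attribute `draws`.
#' @export
rb_grid <- function(cfg, q_grid = c(0.10, 0.20, 0.30, 0.40),
                    c_grid = 1:5, reps = 20L, corrected = FALSE,
                    rules = qc_rules(drop_illness_reducers = FALSE),
                    overlap = FALSE, seed = cfg$seed) {
  grid <- expand.grid(q = q_grid, c = c_grid)
  draws <- matrix(NA_real_, nrow(grid), reps)
  for (r in seq_len(reps)) {
    cfg_r <- cfg
    cfg_r$seed <- derive_seed(seed, paste0("rep", r))
    base <- simulate_scenario(cfg_r)
    snps <- base$snp$id[union(base$causal_idx_y, base$causal_idx_d)]
    for (i in seq_len(nrow(grid))) {
      coh <- apply_ascertainment(base,
                                 ascertainment_config(grid$q[i], grid$c[i]))
      sc <- scan_pair(coh, corrected, rules)
      draws[i, r] <- tryCatch(
        estimate_rb(sc$y, sc$d, snps = snps, overlap = overlap)$rb_raw,
        mlcbias_unstable_rb_error = function(e) NA_real_)
    }
  }
  ok <- rowSums(is.finite(draws))
  out <- data.frame(grid,
                    mean_rb = rowMeans(draws, na.rm = TRUE),
                    sem_rb = apply(draws, 1, sd, na.rm = TRUE) / sqrt(ok),
                    reps_ok = ok)
  attr(out, "draws") <- draws
  attr(out, "corrected") <- corrected
  class(out) <- c("rb_grid", "data.frame")
  out
}
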