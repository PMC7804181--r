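# Correction for misreports and longitudinal changes (MLC).
#
# Step 1 removes suspected misreporters (phenoqc). Step 2 partitions the
# cohort by self-reported longitudinal-change group, standardises the
# phenotype within each group (and within sex), scans each group separately
# and recombines the per-group SNP effects by fixed-effect inverse-variance
# weighting. Because the ascertainment shift is (approximately) a
# group-constant offset, within-group standardisation absorbs it, and the
# meta-analysis restores full-sample precision.

default_covariates <- function(cohort) cbind(sex = cohort$sex, age = cohort$age)

scan_standardized <- function(cohort, rules, covariates, exact_t = FALSE,
                              phenotype = "reported_y") {
  std <- standardize_by_group(cohort[[phenotype]], cohort$sex, rules)
  run_gwas(cohort$genotypes, std$z, covariates, exact_t = exact_t)
}

#' Stratified association scans by longitudinal-change group
#'
#' Within each change group present in the cohort: illness/doctor reducers
#' are removed from the LESS stratum (when the rule is on), the phenotype is
#' standardised within group and sex (mean 0, variance 1, outlier screens per
#' `rules`), and a covariate-adjusted scan is run.
#'
#' @param cohort An `mlc_cohort`.
#' @param rules A [qc_rules()]; `min_group_n` sets the smallest allowed
#'   stratum.
#' @param covariates Covariate matrix aligned to the cohort; default sex and
#'   age.
#' @param phenotype Cohort field to scan (default `reported_y`).
#' @param exact_t Passed to [run_gwas()].
#' @return Named list of `assoc_result`, one per group present.
#' @export
stratified_gwas <- function(cohort, rules = qc_rules(),
                            covariates = default_covariates(cohort),
                            phenotype = "reported_y", exact_t = FALSE) {
  stopifnot(inherits(cohort, "mlc_cohort"))
  if (rules$drop_illness_reducers) {
    drop <- cohort$change_group == "LESS" &
      cohort$reason == "ILLNESS_OR_DOCTOR"
    if (any(drop)) {
      covariates <- covariates[!drop, , drop = FALSE]
      cohort <- subset_cohort(cohort, !drop)
    }
  }
  groups <- levels(droplevels(cohort$change_group))
  out <- list()
  for (gl in groups) {
    gi <- which(cohort$change_group == gl)
    if (length(gi) < rules$min_group_n)
      stop("stratum '", gl, "' has ", length(gi),
           " individuals (< min_group_n = ", rules$min_group_n, ")",
           call. = FALSE)
    sub <- subset_cohort(cohort, gi)
    out[[gl]] <- scan_standardized(sub, rules,
                                   covariates[gi, , drop = FALSE],
                                   exact_t = exact_t, phenotype = phenotype)
  }
  out
}

harmonise_to <- function(ref, x) {
  i <- match(ref$snp, x$snp)
  if (any(is.na(i)))
    stop("summary sets do not share all SNPs; cannot harmonise",
         call. = FALSE)
  x <- x[i, , drop = FALSE]
  same <- x$a1 == ref$a1 & x$a2 == ref$a2
  flip <- x$a1 == ref$a2 & x$a2 == ref$a1
  if (any(!same & !flip))
    stop("unresolvable allele mismatch at ",
         sum(!same & !flip), " SNP(s)", call. = FALSE)
  if (any(flip)) {
    x$beta[flip] <- -x$beta[flip]
    x$freq[flip] <- 1 - x$freq[flip]
    x$a1[flip] <- ref$a1[flip]
    x$a2[flip] <- ref$a2[flip]
  }
  x
}

#' Fixed-effect inverse-variance-weighted meta-analysis of scans
#'
#' Combines aligned per-group SNP effects with weights `1/se^2`:
#' `beta_meta = sum(w b) / sum(w)`, `se_meta = sum(w)^(-1/2)`. Alleles are
#' harmonised to the first set (flipping reverses the effect sign).
#' Cochran's Q is reported per SNP but never filters. SNPs flagged in some
#' groups (e.g. monomorphic there) are combined over the remaining groups.
#'
#' @param groups List of `assoc_result` over the same SNP panel.
#' @return A `meta_result` (also an `assoc_result`, so it can be clumped):
#'   per SNP `beta`, `se`, `p` (two-sided normal), `n` (total), `k` (groups
#'   used), `q_het` (Cochran's Q).
#' @export
ivw_meta <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  ref <- groups[[1]]
  groups <- c(list(ref), lapply(groups[-1], harmonise_to, ref = ref))
  m <- nrow(ref)
  B <- vapply(groups, `[[`, numeric(m), "beta")
  S <- vapply(groups, `[[`, numeric(m), "se")
  N <- vapply(groups, function(g) as.numeric(g$n), numeric(m))
  Fq <- vapply(groups, `[[`, numeric(m), "freq")
  if (is.null(dim(B))) {
    B <- matrix(B, m); S <- matrix(S, m); N <- matrix(N, m)
    Fq <- matrix(Fq, m)
  }
  W <- 1 / S^2
  use <- is.finite(B) & is.finite(W) & W > 0
  W[!use] <- 0
  sw <- rowSums(W)
  beta <- rowSums(W * ifelse(use, B, 0)) / sw
  se <- 1 / sqrt(sw)
  k <- rowSums(use)
  q_het <- rowSums(W * (ifelse(use, B, 0) - beta)^2)
  bad <- k == 0L
  beta[bad] <- NA_real_; se[bad] <- NA_real_; q_het[bad] <- NA_real_
  z <- beta / se
  out <- data.frame(snp = ref$snp, pos = ref$pos, a1 = ref$a1, a2 = ref$a2,
                    freq = rowSums(ifelse(use, N * Fq, 0)) /
                      pmax(rowSums(ifelse(use, N, 0)), 1),
                    beta = beta, se = se, p = 2 * pnorm(-abs(z)),
                    n = rowSums(N * (use * 1)),
                    k = k, q_het = q_het,
                    status = ifelse(bad, "monomorphic", "ok"),
                    stringsAsFactors = FALSE)
  class(out) <- c("meta_result", "assoc_result", "data.frame")
  out
}

#' Full two-step correction: QC, stratified scans, IVW meta, clumping
#'
#' @param cohort An `mlc_cohort` with `reported_y`, `change_group`, `reason`.
#' @param rules A [qc_rules()].
#' @param ccfg A [clump_config()] for the final locus list.
#' @param covariates Covariates aligned to the *input* cohort; subset along
#'   with it.
#' @param exact_t Passed to the scans.
#' @return A list of class `mlc_correct`: `meta` (`meta_result`), `report`
#'   (`filter_report` from step 1), `loci` (clumped leads), `groups`
#'   (per-group scans).
#' @export
mlc_correct <- function(cohort, rules = qc_rules(), ccfg = clump_config(),
                        covariates = default_covariates(cohort),
                        exact_t = FALSE) {
  qf <- qc_filter(cohort, rules)
  keep <- match(qf$cohort$id, cohort$id)
  sg <- stratified_gwas(qf$cohort, rules,
                        covariates = covariates[keep, , drop = FALSE],
                        exact_t = exact_t)
  meta <- ivw_meta(sg)
  loci <- clump(meta, qf$cohort$genotypes, ccfg)
  structure(list(meta = meta, report = qf$report, loci = loci, groups = sg),
            class = "mlc_correct")
}

#' @export
print.mlc_correct <- function(x, ...) {
  cat("<mlc_correct>", length(x$groups), "group(s) meta-analysed;",
      nrow(x$loci), "independent loci\n")
  print(x$report)
  invisible(x)
}

#' Excess-loss z statistic from summary inputs
#'
#' `z = (observed - expected_mean) / expected_sem`, two-sided normal p.
#' Pure arithmetic on a printed or computed down-sampling summary.
#'
#' @param observed Observed count.
#' @param expected_mean,expected_sem Down-sampling mean and standard error of
#'   that mean.
#' @return List with `z` and `p`.
#' @examples
#' excess_ztest(16, 10.03, 0.85)
#' @export
excess_ztest <- function(observed, expected_mean, expected_sem) {
  if (expected_sem <= 0) stop("expected_sem must be positive", call. = FALSE)
  z <- (observed - expected_mean) / expected_sem
  list(z = z, p = 2 * pnorm(-abs(z)))
}

match_loci <- function(pos_a, pos_b, window_bp) {
  if (!length(pos_a)) return(logical(0))
  if (!length(pos_b)) return(rep(FALSE, length(pos_a)))
  vapply(pos_a, function(p) any(abs(pos_b - p) <= window_bp), logical(1))
}

#' Down-sampling test for excess loss of significant loci
#'
#' Repeatedly removes `n_remove` individuals uniformly at random, rescans and
#' reclumps, and counts the loci of the full scan that are lost (no
#' down-sampled lead within `window_bp`) and the new loci gained. The
#' distribution of these counts is what a pure loss of sample size explains;
#' an observed count (e.g. loci lost to a correction procedure) is tested
#' against it.
#'
#' Two references are available. The default `z = (observed - mean) / sem`
#' treats the observed count as a fixed quantity and asks whether it equals
#' the down-sampling *expectation*. With `observed_is_draw = TRUE` the
#' observed count is treated as one more draw of the same process and is
#' tested against the predictive distribution (`sd * sqrt(1 + 1/reps)` scale,
#' t reference with `reps - 1` df) -- the calibrated choice when the
#' "observed" value is itself random.
#'
#' @param cohort An `mlc_cohort`.
#' @param n_remove Individuals removed per replicate (`< n`).
#' @param reps Number of down-sampling replicates (>= 2).
#' @param seed Integer seed (replicates use derived sub-seeds).
#' @param ccfg A [clump_config()].
#' @param rules A [qc_rules()] for within-sex standardisation of the scans.
#' @param covariates Covariates aligned to the cohort.
#' @param observed Optional observed lost-locus count to test.
#' @param observed_is_draw See Details.
#' @return An `excess_test` list: `observed`, `expected_mean`,
#'   `expected_sem`, `expected_sd`, `z`, `p`, `reps`, `lost`, `gained`,
#'   `n_full_loci`.
#' @export
downsample_excess <- function(cohort, n_remove, reps, seed = 1L,
                              ccfg = clump_config(), rules = qc_rules(),
                              covariates = default_covariates(cohort),
                              observed = NULL, observed_is_draw = FALSE) {
  stopifnot(inherits(cohort, "mlc_cohort"))
  if (reps < 2L) stop("reps must be >= 2", call. = FALSE)
  n <- cohort_size(cohort)
  if (n_remove >= n) stop("n_remove must be < n", call. = FALSE)
  scan_leads <- function(coh, cov) {
    a <- scan_standardized(coh, rules, cov)
    clump(a, coh$genotypes, ccfg)$pos
  }
  full <- scan_leads(cohort, covariates)
  lost <- gained <- integer(reps)
  for (r in seq_len(reps)) {
    keep <- with_seed(derive_seed(seed, paste0("downsample/", r)),
                      sort(sample.int(n, n - n_remove)))
    leads <- scan_leads(subset_cohort(cohort, keep),
                        covariates[keep, , drop = FALSE])
    lost[r] <- sum(!match_loci(full, leads, ccfg$window_bp))
    gained[r] <- sum(!match_loci(leads, full, ccfg$window_bp))
  }
  em <- mean(lost); esd <- sd(lost); esem <- esd / sqrt(reps)
  z <- p <- NA_real_
  if (!is.null(observed)) {
    if (observed_is_draw) {
      sc <- esd * sqrt(1 + 1 / reps)
      z <- (observed - em) / sc
      p <- 2 * pt(-abs(z), reps - 1L)
    } else {
      zt <- excess_ztest(observed, em, esem)
      z <- zt$z; p <- zt$p
    }
  }
  structure(list(observed = observed, expected_mean = em,
                 expected_sem = esem, expected_sd = esd, z = z, p = p,
                 reps = as.integer(reps), lost = lost, gained = gained,
                 n_full_loci = length(full)),
            class = "excess_test")
}

#' @export
print.excess_test <- function(x, ...) {
  cat(sprintf("<excess_test> %d reps | full-scan loci: %d\n",
              x$reps, x$n_full_loci))
  cat(sprintf("  lost: mean %.2f (sem %.2f) | gained: mean %.2f\n",
              x$expected_mean, x$expected_sem, mean(x$gained)))
  if (!is.null(x$observed))
    cat(sprintf("  observed %s -> z = %.2f, p = %.3g\n",
                format(x$observed), x$z, x$p))
  invisible(x)
}
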