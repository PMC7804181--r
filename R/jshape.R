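# Binned exposure-disease risk curves and polygenic-predictor curves.
#
# A J-shaped (interior-minimum) odds-ratio curve can be manufactured by
# reference-bin contamination: individuals who reduced the exposure because
# of disease sit disproportionately in the low/reference bins and carry
# excess risk, inflating the reference odds and depressing the relative odds
# of the neighbouring bins. Composition accounting per bin and a
# reference-bin exclusion rule make the mechanism visible.

#' Binned odds-ratio risk curve with reference-group composition
#'
#' Bins are left-open right-closed on the supplied edges; individuals
#' outside the edges are not analysed. Each bin's odds ratio comes from the
#' bin-vs-reference 2x2 table, `OR = (a d) / (b c)`, with a Woolf (log-OR
#' normal) 95% CI. Individuals whose group is listed in
#' `exclude_from_reference` are removed from the *reference side* of every
#' comparison only -- they still appear in their own bins -- which is how a
#' contaminated reference group is repaired without discarding data.
#'
#' @param exposure Numeric vector.
#' @param disease Binary vector (0/1).
#' @param groups Optional labels (e.g. change group) for composition
#'   accounting and reference exclusion.
#' @param bins Numeric bin edges (length >= 3).
#' @param reference Reference bin index (default 1, the lowest bin).
#' @param exclude_from_reference Character vector of group labels excluded
#'   from the reference side.
#' @return A `risk_curve` data.frame: per bin `bin`, `lo`, `hi`, `n`,
#'   `cases`, `or`, `ci_lo`, `ci_hi`, plus one `frac_<group>` composition
#'   column per group. Attributes: `reference`, `excluded_groups`,
#'   `reference_n`, `reference_cases`.
#' @examples
#' or_2x2(10, 90, 20, 80)   # the arithmetic behind each bin
#' @export
risk_curve <- function(exposure, disease, groups = NULL, bins,
                       reference = 1L, exclude_from_reference = NULL) {
  stopifnot(length(exposure) == length(disease),
            is.numeric(bins), length(bins) >= 3L)
  if (!is.null(groups)) stopifnot(length(groups) == length(exposure))
  bin <- cut(exposure, breaks = bins, right = TRUE, labels = FALSE)
  keep <- !is.na(bin) & !is.na(disease) & !is.na(exposure)
  bin <- bin[keep]; dis <- disease[keep]
  grp <- if (is.null(groups)) NULL else as.character(groups[keep])
  nb <- length(bins) - 1L
  if (reference < 1L || reference > nb)
    stop("reference bin out of range", call. = FALSE)
  ref_members <- bin == reference
  if (!is.null(exclude_from_reference) && !is.null(grp))
    ref_members <- ref_members & !(grp %in% exclude_from_reference)
  ref_cases <- sum(dis[ref_members] == 1)
  ref_ctrl <- sum(dis[ref_members] == 0)
  if (ref_cases == 0 || ref_ctrl == 0)
    stop("reference bin needs at least one case and one control ",
         "after exclusions", call. = FALSE)
  n <- tabulate(bin, nb)
  cases <- vapply(seq_len(nb), function(b) sum(dis[bin == b] == 1),
                  numeric(1))
  or <- ci_lo <- ci_hi <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    if (b == reference) { or[b] <- 1; next }
    a <- cases[b]; bb <- n[b] - cases[b]
    w <- or_2x2(a, bb, ref_cases, ref_ctrl)
    or[b] <- w$or; ci_lo[b] <- w$ci[1]; ci_hi[b] <- w$ci[2]
  }
  out <- data.frame(bin = seq_len(nb), lo = bins[-length(bins)],
                    hi = bins[-1], n = n, cases = cases,
                    or = or, ci_lo = ci_lo, ci_hi = ci_hi)
  if (!is.null(grp)) {
    for (gl in sort(unique(grp))) {
      out[[paste0("frac_", gl)]] <- vapply(seq_len(nb), function(b) {
        if (n[b] == 0) return(NA_real_)
        mean(grp[bin == b] == gl)
      }, numeric(1))
    }
  }
  attr(out, "reference") <- as.integer(reference)
  attr(out, "excluded_groups") <- exclude_from_reference
  attr(out, "reference_n") <- ref_cases + ref_ctrl
  attr(out, "reference_cases") <- ref_cases
  class(out) <- c("risk_curve", "data.frame")
  out
}

#' 2x2 odds ratio with Woolf confidence interval
#'
#' @param a,b Cases and controls in the index group.
#' @param c,d Cases and controls in the reference group.
#' @param conf Confidence level.
#' @return List with `or`, `ci`, `log_se`.
#' @export
or_2x2 <- function(a, b, c, d, conf = 0.95) {
  if (min(a, b, c, d) < 0) stop("cell counts must be >= 0", call. = FALSE)
  or <- (a * d) / (b * c)
  log_se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zq <- qnorm(1 - (1 - conf) / 2)
  list(or = or, ci = exp(log(or) + c(-1, 1) * zq * log_se), log_se = log_se)
}

#' Polygenic-score risk curve with an enforced train/evaluate split
#'
#' Trains an association scan of the exposure on a random half of the
#' cohort, clumps it to lead SNPs at `p_threshold`, scores the *other* half
#' (`score = sum of lead-SNP beta x allele count`), and draws the disease
#' risk curve across score quantile bins. The split is seeded and disjoint
#' by construction; supplying overlapping index sets is an error.
#'
#' @param cohort An `mlc_cohort`.
#' @param n_bins Number of score quantile bins.
#' @param train_frac Fraction of the cohort used for training.
#' @param seed Integer seed for the split.
#' @param ccfg A [clump_config()]; its `p_threshold` selects score SNPs.
#' @param phenotype Exposure field scanned in training (default
#'   `reported_y`).
#' @param train_idx,eval_idx Optional explicit disjoint index sets.
#' @param reference Reference bin for the odds ratios (default 1).
#' @return A `risk_curve` over score bins; the score and split are attached
#'   as attributes.
#' @export
pgs_curve <- function(cohort, n_bins = 5L, train_frac = 0.5, seed = 1L,
                      ccfg = clump_config(), phenotype = "reported_y",
                      train_idx = NULL, eval_idx = NULL, reference = 1L) {
  stopifnot(inherits(cohort, "mlc_cohort"))
  n <- cohort_size(cohort)
  if (is.null(train_idx)) {
    train_idx <- with_seed(derive_seed(seed, "pgs_split"),
                           sort(sample.int(n, round(train_frac * n))))
  }
  if (is.null(eval_idx)) eval_idx <- setdiff(seq_len(n), train_idx)
  if (length(intersect(train_idx, eval_idx)))
    stop("training and evaluation samples overlap", call. = FALSE)
  train <- subset_cohort(cohort, train_idx)
  scan <- run_gwas(train$genotypes, train[[phenotype]],
                   default_covariates(train))
  leads <- select_ivs(scan, train$genotypes, ccfg)
  ev <- subset_cohort(cohort, eval_idx)
  score <- as.numeric(ev$genotypes[, match(leads$snp, colnames(ev$genotypes)),
                                   drop = FALSE] %*% leads$beta)
  edges <- unique(quantile(score, probs = seq(0, 1, length.out = n_bins + 1)))
  edges[1] <- edges[1] - 1e-9
  rc <- risk_curve(score, ev$disease, groups = ev$change_group,
                   bins = edges, reference = reference)
  attr(rc, "score") <- score
  attr(rc, "train_idx") <- train_idx
  attr(rc, "eval_idx") <- eval_idx
  attr(rc, "n_score_snps") <- nrow(leads)
  rc
}

#' Quantile-binned means of an outcome against a predictor
#'
#' @param x Predictor.
#' @param y Outcome.
#' @param n_bins Number of quantile bins.
#' @return Data.frame with `bin`, `n`, `mean_x`, `mean_y`.
#' @export
binned_means <- function(x, y, n_bins = 10L) {
  edges <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  edges[1] <- edges[1] - 1e-9
  bin <- cut(x, breaks = edges, right = TRUE, labels = FALSE)
  data.frame(bin = seq_len(length(edges) - 1L),
             n = tabulate(bin, length(edges) - 1L),
             mean_x = vapply(seq_len(length(edges) - 1L),
                             function(b) mean(x[bin == b]), numeric(1)),
             mean_y = vapply(seq_len(length(edges) - 1L),
                             function(b) mean(y[bin == b]), numeric(1)))
}

#' Does a curve attain its minimum strictly in the interior?
#'
#' @param values Numeric vector (bin-level curve values).
#' @return `TRUE` when the minimum is neither the first nor the last entry.
#' @export
interior_minimum <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 3L) return(FALSE)
  wm <- which.min(v)
  wm > 1L && wm < length(v)
}
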