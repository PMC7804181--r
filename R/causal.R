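# Instrumental-variable causal-effect estimation from summary statistics.
#
# Instruments are clumped genome-wide-significant SNPs from the exposure
# scan. Per instrument the Wald ratio is b_outcome / b_exposure; the IVW
# estimate combines ratios with weights b_exp^2 / se_out^2 (a weighted
# regression of outcome effects on exposure effects through the origin);
# simple and weighted medians are robust alternatives with parametric
# bootstrap standard errors.

new_causal_estimate <- function(method, b, se, n_iv, removed = character(0)) {
  b <- unname(b); se <- unname(se)
  structure(list(method = method, b_xy = b, se = se,
                 ci95 = c(b - 1.96 * se, b + 1.96 * se),
                 n_iv = as.integer(n_iv), removed_outliers = removed),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("<causal_estimate> %s: b_xy = %.4f (se %.4f, 95%% CI %.4f to %.4f), %d IV(s)\n",
              x$method, x$b_xy, x$se, x$ci95[1], x$ci95[2], x$n_iv))
  if (length(x$removed_outliers))
    cat("  outliers removed:", paste(x$removed_outliers, collapse = ", "), "\n")
  invisible(x)
}

#' Select instruments by clumping an exposure scan
#'
#' Clumps at the configured thresholds (defaults: p < 5e-8, 1 Mb window,
#' r^2 < 0.01) and errors if nothing passes.
#'
#' @param exposure `assoc_result` for the exposure.
#' @param genotypes Allele-count matrix for the LD rule (`NULL` allowed).
#' @param cfg A [clump_config()].
#' @return Lead rows (the instrument set).
#' @export
select_ivs <- function(exposure, genotypes = NULL, cfg = clump_config()) {
  ivs <- clump(exposure, genotypes, cfg)
  if (!nrow(ivs)) {
    cond <- structure(
      class = c("mlcbias_no_instrument_error", "error", "condition"),
      list(message = sprintf(
        "no instrument passes p < %g after clumping", cfg$p_threshold),
        call = sys.call(-1)))
    stop(cond)
  }
  ivs
}

iv_frame <- function(ivs, exposure, outcome) {
  ids <- if (is.data.frame(ivs)) ivs$snp else as.character(ivs)
  ex <- exposure[match(ids, exposure$snp), , drop = FALSE]
  if (any(is.na(ex$beta)))
    stop("instrument(s) missing from the exposure scan", call. = FALSE)
  ou <- harmonise_to(ex, outcome)
  if (any(ex$beta == 0)) {
    cond <- structure(
      class = c("mlcbias_weak_instrument_error", "error", "condition"),
      list(message = "exposure effect exactly zero for an instrument",
           call = sys.call(-1)))
    stop(cond)
  }
  data.frame(snp = ids, b_exp = ex$beta, se_exp = ex$se,
             b_out = ou$beta, se_out = ou$se, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted (and single-IV Wald) causal estimate
#'
#' With one instrument this is exactly the Wald ratio with its delta-method
#' SE. With several, `b_xy = sum(w r) / sum(w)` with `r = b_out / b_exp` and
#' `w = b_exp^2 / se_out^2`, `se = sum(w)^(-1/2)` (fixed-effect). An
#' optional outlier screen (one pass) drops instruments whose ratio deviates
#' from the IVW estimate by more than `outlier_k` ratio-SEs, approximating
#' heterogeneity-outlier removal.
#'
#' @param ivs Instrument set (`select_ivs` output or SNP ids).
#' @param exposure,outcome `assoc_result` objects.
#' @param outlier_k `NULL` (no screen) or a positive multiplier (default 3
#'   when enabled).
#' @return A `causal_estimate` (method `"IVW"`, or `"WALD"` for one IV).
#' @export
ivw_estimate <- function(ivs, exposure, outcome, outlier_k = NULL) {
  d <- iv_frame(ivs, exposure, outcome)
  est <- function(d) {
    r <- d$b_out / d$b_exp
    w <- d$b_exp^2 / d$se_out^2
    b <- sum(w * r) / sum(w)
    list(b = b, se = 1 / sqrt(sum(w)), r = r)
  }
  e <- est(d)
  removed <- character(0)
  if (!is.null(outlier_k) && nrow(d) > 2L) {
    se_r <- d$se_out / abs(d$b_exp)
    out <- abs(e$r - e$b) > outlier_k * se_r
    if (any(out) && !all(out)) {
      removed <- d$snp[out]
      d <- d[!out, , drop = FALSE]
      e <- est(d)
    }
  }
  method <- if (nrow(d) == 1L) "WALD" else "IVW"
  new_causal_estimate(method, e$b, e$se, nrow(d), removed)
}

# interpolated weighted median of ratios (normalised cumulative weights)
weighted_median_value <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] < 0.5) return(r[length(r)])
  j <- which(cw >= 0.5)[1]
  r[j - 1] + (r[j] - r[j - 1]) * (0.5 - cw[j - 1]) / (cw[j] - cw[j - 1])
}

#' Simple- and weighted-median causal estimates
#'
#' The weighted median is the interpolated median of Wald ratios under
#' normalised inverse-variance weights (`b_exp^2 / se_out^2`); the simple
#' median uses equal weights. Standard errors come from a seeded parametric
#' bootstrap (effects resampled from their sampling distributions).
#'
#' @param ivs Instrument set (>= 3 instruments required).
#' @param exposure,outcome `assoc_result` objects.
#' @param boot Bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @return List with `simple` and `weighted`, each a `causal_estimate`.
#' @export
median_estimates <- function(ivs, exposure, outcome, boot = 1000L,
                             seed = 1L) {
  d <- iv_frame(ivs, exposure, outcome)
  if (nrow(d) < 3L) {
    cond <- structure(
      class = c("mlcbias_insufficient_instruments_error", "error",
                "condition"),
      list(message = "median estimators need at least 3 instruments",
           call = sys.call(-1)))
    stop(cond)
  }
  point <- function(be, bo) {
    r <- bo / be
    w <- be^2 / d$se_out^2
    c(simple = weighted_median_value(r, rep(1, length(r))),
      weighted = weighted_median_value(r, w))
  }
  pt0 <- point(d$b_exp, d$b_out)
  bs <- with_seed(seed, {
    k <- nrow(d)
    vapply(seq_len(boot), function(i) {
      point(rnorm(k, d$b_exp, d$se_exp), rnorm(k, d$b_out, d$se_out))
    }, numeric(2))
  })
  list(simple = new_causal_estimate("SIMPLE_MEDIAN", pt0["simple"],
                                    sd(bs["simple", ]), nrow(d)),
       weighted = new_causal_estimate("WEIGHTED_MEDIAN", pt0["weighted"],
                                      sd(bs["weighted", ]), nrow(d)))
}

#' Run a panel of MR estimators, optionally in the reverse direction
#'
#' Selects instruments from the exposure scan (unless given), runs the
#' requested estimators, and records the direction and clumping thresholds
#' in a manifest.
#'
#' @param exposure,outcome `assoc_result` objects.
#' @param genotypes For instrument clumping (`NULL` allowed).
#' @param ivs Optional pre-selected instruments.
#' @param cfg A [clump_config()].
#' @param methods Subset of `c("ivw", "simple_median", "weighted_median")`.
#' @param reverse Swap the roles of exposure and outcome.
#' @param outlier_k Passed to [ivw_estimate()].
#' @param boot,seed Bootstrap controls for the medians.
#' @return An `mr_result`: `estimates` (named list of `causal_estimate`),
#'   `ivs`, `manifest` (direction + clumping thresholds).
#' @export
mr_analysis <- function(exposure, outcome, genotypes = NULL, ivs = NULL,
                        cfg = clump_config(),
                        methods = c("ivw", "simple_median",
                                    "weighted_median"),
                        reverse = FALSE, outlier_k = NULL, boot = 1000L,
                        seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (reverse) { tmp <- exposure; exposure <- outcome; outcome <- tmp }
  if (is.null(ivs)) ivs <- select_ivs(exposure, genotypes, cfg)
  est <- list()
  if ("ivw" %in% methods)
    est$ivw <- ivw_estimate(ivs, exposure, outcome, outlier_k = outlier_k)
  if (any(c("simple_median", "weighted_median") %in% methods) &&
      nrow(iv_frame(ivs, exposure, outcome)) >= 3L) {
    med <- median_estimates(ivs, exposure, outcome, boot = boot, seed = seed)
    if ("simple_median" %in% methods) est$simple_median <- med$simple
    if ("weighted_median" %in% methods) est$weighted_median <- med$weighted
  }
  structure(list(estimates = est, ivs = ivs,
                 manifest = list(direction = if (reverse) "reverse" else
                                 "forward",
                                 p_threshold = cfg$p_threshold,
                                 window_bp = cfg$window_bp,
                                 r2_threshold = cfg$r2_threshold,
                                 n_iv = nrow(ivs), seed = seed)),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat("<mr_result>", x$manifest$direction, "direction,",
      x$manifest$n_iv, "instrument(s)\n")
  for (e in x$estimates) print(e)
  invisible(x)
}
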