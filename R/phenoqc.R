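# Phenotypic quality control for self-reported behavioural traits.
#
# Step 1 of the correction for misreports and longitudinal changes: remove
# never-users misclassified as current users, current users reporting exactly
# zero consumption, non-responders, and (within the reduced group) individuals
# who reduced the behaviour because of illness or doctor's advice. Every
# removal is accounted for in a ledger so published-style percentages can be
# recomputed from counts.

#' Quality-control rule set
#'
#' @param drop_never_drinkers Remove self-reported never-users (requires a
#'   `drinker_status` field; a no-op when absent).
#' @param drop_zero_consumption_current Remove current users whose reported
#'   consumption is exactly zero (suspected underreporting).
#' @param drop_nonresponse Remove individuals with a missing consumption
#'   report.
#' @param drop_illness_reducers Remove, from the LESS stratum only,
#'   individuals whose reason for reducing is illness or doctor's advice.
#' @param raw_outlier_sd Pre-adjustment screen: drop raw values outside
#'   mean +/- this many SDs within each group (default 7).
#' @param post_adjust_z Post-adjustment screen: exclude |z| above this value
#'   (default 5).
#' @param outlier_screen_stage Whether the +/-7 SD screen applies to the
#'   transformed consumption values (`"after"`, default) or the raw units
#'   (`"before"`); kept explicit because the choice is a convention.
#' @param min_group_n Minimum stratum size for group-wise operations.
#' @return A `qc_rules` list.
#' @export
qc_rules <- function(drop_never_drinkers = TRUE,
                     drop_zero_consumption_current = TRUE,
                     drop_nonresponse = TRUE,
                     drop_illness_reducers = TRUE,
                     raw_outlier_sd = 7,
                     post_adjust_z = 5,
                     outlier_screen_stage = c("after", "before"),
                     min_group_n = 50L) {
  if (raw_outlier_sd <= 0 || post_adjust_z <= 0)
    stop("outlier thresholds must be positive", call. = FALSE)
  structure(list(drop_never_drinkers = isTRUE(drop_never_drinkers),
                 drop_zero_consumption_current = isTRUE(drop_zero_consumption_current),
                 drop_nonresponse = isTRUE(drop_nonresponse),
                 drop_illness_reducers = isTRUE(drop_illness_reducers),
                 raw_outlier_sd = raw_outlier_sd,
                 post_adjust_z = post_adjust_z,
                 outlier_screen_stage = match.arg(outlier_screen_stage),
                 min_group_n = as.integer(min_group_n)),
            class = "qc_rules")
}

new_filter_report <- function(rules_applied, removed, n_input) {
  remaining <- n_input - cumsum(removed)
  out <- data.frame(rule = rules_applied,
                    n_removed = as.integer(removed),
                    n_remaining = as.integer(remaining),
                    stringsAsFactors = FALSE)
  attr(out, "n_input") <- as.integer(n_input)
  class(out) <- c("filter_report", "data.frame")
  out
}

#' @export
print.filter_report <- function(x, ...) {
  n0 <- attr(x, "n_input")
  cat("<filter_report> input n =", n0, "\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s removed %8d (%5.1f%%)  remaining %8d\n",
                x$rule[i], x$n_removed[i],
                round_half_up(100 * x$n_removed[i] / n0, 1),
                x$n_remaining[i]))
  }
  invisible(x)
}

#' Filter a cohort or phenotype table by the misreport QC rules
#'
#' Rules are applied in a fixed order -- never-users, zero-consumption
#' current users, non-responders, illness/doctor reducers (LESS stratum
#' only) -- and each removal is attributed to the first rule that matches, so
#' removals are disjoint by construction and the ledger is conservative:
#' input n equals retained plus the sum of removals.
#'
#' @param x An `mlc_cohort`, or a data.frame with columns `reported_y`,
#'   `change_group`, `reason` and optionally `drinker_status`.
#' @param rules A [qc_rules()].
#' @return A list with `cohort` (or `pheno`, same type as the input) and
#'   `report` (a `filter_report`).
#' @export
qc_filter <- function(x, rules = qc_rules()) {
  UseMethod("qc_filter")
}

qc_flags <- function(status, reported_y, change_group, reason, rules) {
  n <- length(reported_y)
  alive <- rep(TRUE, n)
  labels <- c("never_drinker", "zero_consumption", "nonresponse",
              "illness_reducer")
  removed <- integer(4)
  hit <- vector("list", 4)
  hit[[1]] <- if (rules$drop_never_drinkers && !is.null(status))
    !is.na(status) & status == "never" else rep(FALSE, n)
  hit[[2]] <- if (rules$drop_zero_consumption_current)
    !is.na(reported_y) & reported_y == 0 else rep(FALSE, n)
  hit[[3]] <- if (rules$drop_nonresponse) is.na(reported_y) else rep(FALSE, n)
  hit[[4]] <- if (rules$drop_illness_reducers)
    change_group == "LESS" & reason == "ILLNESS_OR_DOCTOR" else rep(FALSE, n)
  for (k in 1:4) {
    take <- alive & hit[[k]]
    removed[k] <- sum(take)
    alive <- alive & !take
  }
  list(alive = alive, labels = labels, removed = removed)
}

#' @export
qc_filter.mlc_cohort <- function(x, rules = qc_rules()) {
  f <- qc_flags(NULL, x$reported_y, x$change_group, x$reason, rules)
  list(cohort = subset_cohort(x, f$alive),
       report = new_filter_report(f$labels, f$removed, cohort_size(x)))
}

#' @export
qc_filter.data.frame <- function(x, rules = qc_rules()) {
  need <- c("reported_y", "change_group", "reason")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("phenotype table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  f <- qc_flags(x[["drinker_status"]], x$reported_y, x$change_group,
                x$reason, rules)
  list(pheno = x[f$alive, , drop = FALSE],
       report = new_filter_report(f$labels, f$removed, nrow(x)))
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percentage accounting for labelled group counts
#'
#' Percentages are `100 * count / denominator` reported at one decimal with
#' half-up rounding (the presentation convention for cohort accounting
#' tables). Complements (denominator minus count) can be added on request.
#'
#' @param counts Named numeric vector of group counts.
#' @param denominator Positive count; every count must be <= it.
#' @param complements Add `not_<label>` rows.
#' @return A data.frame with columns `label`, `count`, `pct`.
#' @examples
#' filter_accounting(c(zero_consumption = 9064), 424507)
#' @export
filter_accounting <- function(counts, denominator, complements = FALSE) {
  stopifnot(is.numeric(counts), length(counts) >= 0)
  if (denominator <= 0) stop("denominator must be > 0", call. = FALSE)
  if (any(counts > denominator))
    stop("count exceeds denominator", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  labs <- names(counts)
  if (is.null(labs)) labs <- paste0("group", seq_along(counts))
  out <- data.frame(label = labs, count = as.numeric(counts),
                    pct = round_half_up(100 * as.numeric(counts) / denominator, 1),
                    stringsAsFactors = FALSE)
  if (complements) {
    comp <- denominator - out$count
    out <- rbind(out, data.frame(label = paste0("not_", labs), count = comp,
                                 pct = round_half_up(100 * comp / denominator, 1)))
  }
  attr(out, "denominator") <- denominator
  out
}

#' Log2(x + 1) consumption transform
#'
#' Compresses the heavy right tail of consumption-type variables; zero maps
#' to zero and missing values propagate.
#'
#' @param values Non-negative numeric vector.
#' @return `log2(values + 1)`.
#' @export
transform_consumption <- function(values) {
  if (any(values < 0, na.rm = TRUE))
    stop("consumption values must be non-negative", call. = FALSE)
  log2(values + 1)
}

#' Group-wise standardisation with outlier screens
#'
#' Within each group: (1) drop raw values outside mean +/- `raw_outlier_sd`
#' SDs; (2) regress out the supplied covariates; (3) z-score the residuals;
#' (4) exclude |z| > `post_adjust_z`; (5) re-standardise the retained values
#' so every group has mean 0 and variance 1 exactly. This removes any mean or
#' variance difference between groups before they are analysed jointly.
#'
#' @param values Numeric vector (missing allowed; stays missing).
#' @param group Group labels (e.g. sex, or change-group x sex).
#' @param rules A [qc_rules()] supplying the two thresholds.
#' @param covariates Optional numeric matrix/data.frame of covariates to
#'   regress out within each group.
#' @return A list with `z` (standardised values, `NA` where excluded or
#'   missing) and `excluded` (character vector: `"raw_outlier"`,
#'   `"z_outlier"`, `"missing"` or `""`).
#' @export
standardize_by_group <- function(values, group, rules = qc_rules(),
                                 covariates = NULL) {
  stopifnot(length(values) == length(group))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(values))
  }
  z <- rep(NA_real_, length(values))
  excluded <- ifelse(is.na(values), "missing", "")
  for (gl in unique(group[!is.na(group)])) {
    gi <- which(!is.na(group) & group == gl & !is.na(values))
    if (length(gi) < 2L)
      stop("group '", gl, "' has fewer than 2 non-missing values",
           call. = FALSE)
    v <- values[gi]
    m0 <- mean(v); s0 <- sd(v)
    if (s0 == 0)
      stop("group '", gl, "' is constant; cannot standardise", call. = FALSE)
    raw_out <- abs(v - m0) > rules$raw_outlier_sd * s0
    excluded[gi[raw_out]] <- "raw_outlier"
    keep <- gi[!raw_out]
    v <- values[keep]
    if (!is.null(covariates)) {
      fit <- lm.fit(cbind(1, covariates[keep, , drop = FALSE]), v)
      v <- fit$residuals
    }
    s <- sd(v)
    if (s == 0)
      stop("group '", gl, "' is constant after adjustment", call. = FALSE)
    zz <- (v - mean(v)) / s
    z_out <- abs(zz) > rules$post_adjust_z
    excluded[keep[z_out]] <- "z_outlier"
    kept <- keep[!z_out]
    zz <- zz[!z_out]
    # re-standardise after exclusions so each group is exactly mean 0, var 1
    z[kept] <- (zz - mean(zz)) / sd(zz)
  }
  list(z = z, excluded = excluded)
}

#' Welch two-sample t test from summary statistics
#'
#' `t = (mean1 - mean2) / sqrt(se1^2 + se2^2)`. With per-group sample sizes
#' the Welch-Satterthwaite degrees of freedom are used; otherwise the normal
#' approximation (degrees of freedom effectively infinite at biobank scale).
#'
#' @param mean1,se1,mean2,se2 Group means and standard errors of the means.
#' @param n1,n2 Optional group sizes for the exact df.
#' @return A list with `t`, `p`, and `df` (`Inf` under the normal
#'   approximation).
#' @examples
#' welch_t(1.630, 0.007, 1.372, 0.002)
#' @export
welch_t <- function(mean1, se1, mean2, se2, n1 = NULL, n2 = NULL) {
  if (se1 <= 0 || se2 <= 0)
    stop("standard errors must be positive", call. = FALSE)
  t <- (mean1 - mean2) / sqrt(se1^2 + se2^2)
  if (!is.null(n1) && !is.null(n2)) {
    df <- (se1^2 + se2^2)^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
    p <- 2 * pt(-abs(t), df)
  } else {
    df <- Inf
    p <- 2 * pnorm(-abs(t))
  }
  list(t = t, p = p, df = df)
}

#' Write / read a cohort phenotype table
#'
#' Tab-separated with header; one row per individual with columns `id`,
#' `sex`, `age`, `true_y`, `reported_y`, `liability_d`, `disease`,
#' `change_group`, `reason`.
#'
#' @param cohort An `mlc_cohort`.
#' @param path File path.
#' @return `write_pheno_tsv` returns `path` invisibly; `read_pheno_tsv`
#'   returns a data.frame with factor columns restored.
#' @export
write_pheno_tsv <- function(cohort, path) {
  df <- data.frame(id = cohort$id, sex = cohort$sex, age = cohort$age,
                   true_y = cohort$true_y, reported_y = cohort$reported_y,
                   liability_d = cohort$liability_d, disease = cohort$disease,
                   change_group = as.character(cohort$change_group),
                   reason = as.character(cohort$reason))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$change_group <- factor(df$change_group,
                            levels = c("LESS", "SAME", "MORE"))
  df$reason <- factor(df$reason,
                      levels = c("ILLNESS_OR_DOCTOR", "HEALTH_PRECAUTION",
                                 "FINANCIAL", "OTHER", "NONE"))
  df
}
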