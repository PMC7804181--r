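test_that("qc_filter applies rules in order with a conservative ledger", {
  df <- data.frame(
    reported_y = c(5, 0, NA, 3, 0, 2, 4, NA, 1, 6),
    change_group = factor(c("SAME", "SAME", "LESS", "LESS", "SAME", "MORE",
                            "LESS", "LESS", "SAME", "SAME"),
                          levels = c("LESS", "SAME", "MORE")),
    reason = factor(c("NONE", "NONE", "ILLNESS_OR_DOCTOR", "ILLNESS_OR_DOCTOR",
                      "NONE", "NONE", "OTHER", "NONE", "NONE", "NONE"),
                    levels = c("ILLNESS_OR_DOCTOR", "HEALTH_PRECAUTION",
                               "FINANCIAL", "OTHER", "NONE")))
  out <- qc_filter(df, qc_rules())
  rep <- out$report
  # zero-consumption rows 2,5; nonresponse rows 3,8; illness reducer row 4
  expect_equal(rep$n_removed, c(0L, 2L, 2L, 1L))
  expect_equal(rep$n_remaining[4], 5L)
  expect_equal(nrow(out$pheno), 5L)
  # conservation: input n = retained + sum removed
  expect_equal(attr(rep, "n_input"),
               rep$n_remaining[nrow(rep)] + sum(rep$n_removed))
  # idempotence
  again <- qc_filter(out$pheno, qc_rules())
  expect_equal(sum(again$report$n_removed), 0L)
  expect_equal(again$pheno, out$pheno)

  off <- qc_rules(FALSE, FALSE, FALSE, FALSE)
  ident <- qc_filter(df, off)
  expect_equal(ident$pheno, df)
  expect_true(all(ident$report$n_removed == 0L))

  expect_error(qc_filter(df[, 1, drop = FALSE]), "required column")
})

test_that("qc_filter on a cohort subsets genotypes in step", {
  coh <- simulate_scenario(scenario_config("I", n = 200, m = 20,
                                           n_causal_y = 5, seed = 2))
  coh <- apply_ascertainment(coh, ascertainment_config(0.1, 2))
  coh <- apply_misreport(coh, misreport_config(nonresponse_frac = 0.1),
                         seed = 4)
  out <- qc_filter(coh, qc_rules())
  expect_equal(cohort_size(out$cohort), nrow(out$cohort$genotypes))
  expect_false(any(is.na(out$cohort$reported_y)))
  expect_false(any(out$cohort$reason == "ILLNESS_OR_DOCTOR"))
})

test_that("filter accounting reproduces published-style percentages", {
  acct <- filter_accounting(c(zero = 9064, nonresp = 66058, less = 191653),
                            424507)
  expect_equal(acct$pct, c(2.1, 15.6, 45.1))
  expect_equal(filter_accounting(c(x = 0), 424507)$pct, 0)
  expect_error(filter_accounting(c(x = 10), 5), "exceeds")
  expect_error(filter_accounting(c(x = 1), 0), "denominator")
  comp <- filter_accounting(c(x = 100), 400, complements = TRUE)
  expect_equal(comp$count[2], 300)
  expect_equal(comp$pct[2], 75)
})

test_that("consumption transform is log2(x + 1) with domain checks", {
  expect_equal(transform_consumption(0), 0)
  expect_equal(transform_consumption(1), 1)
  # oracle: direct arithmetic on the mean weekly consumption worked example
  expect_equal(transform_consumption(10.67), log(11.67) / log(2),
               tolerance = 1e-12)
  expect_equal(transform_consumption(10.67), 3.5446, tolerance = 1e-4)
  expect_true(is.na(transform_consumption(c(1, NA))[2]))
  expect_error(transform_consumption(-0.5), "non-negative")
})

test_that("group-wise standardisation: exact moments, screens, errors", {
  v <- c(-1, 0, 1)
  out <- standardize_by_group(v, rep("a", 3))
  expect_equal(out$z, v)

  set.seed(1)
  vals <- c(rnorm(300, 5, 2), rnorm(300, -3, 0.5))
  grp <- rep(c("m", "f"), each = 300)
  std <- standardize_by_group(vals, grp)
  for (g in c("m", "f")) {
    expect_equal(mean(std$z[grp == g]), 0, tolerance = 1e-10)
    expect_equal(var(std$z[grp == g]), 1, tolerance = 1e-10)
  }

  # a value at mean + 8 SD is screened out before z-scoring
  vals2 <- c(rnorm(500), NA)
  vals2[1] <- mean(vals2[-1], na.rm = TRUE) + 8 * sd(vals2[-1], na.rm = TRUE)
  std2 <- standardize_by_group(vals2, rep("a", 501))
  expect_identical(std2$excluded[1], "raw_outlier")
  expect_true(is.na(std2$z[1]))
  expect_identical(std2$excluded[501], "missing")

  expect_error(standardize_by_group(c(1, 1, 1), rep("a", 3)), "constant")
  expect_error(standardize_by_group(c(1, NA), c("a", "a")), "fewer than 2")

  # covariate adjustment removes a linear age effect
  age <- runif(400, 40, 70)
  v3 <- 0.1 * age + rnorm(400)
  std3 <- standardize_by_group(v3, rep("a", 400), covariates = cbind(age))
  expect_lt(abs(cor(std3$z, age)), 0.02)
})

test_that("welch_t matches the textbook test and the summary worked example", {
  eq <- welch_t(1, 0.5, 1, 0.7)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  set.seed(42)
  x <- rnorm(50, 1, 2); y <- rnorm(50, 0, 1)
  ref <- t.test(x, y)
  got <- welch_t(mean(x), sd(x) / sqrt(50), mean(y), sd(y) / sqrt(50),
                 n1 = 50, n2 = 50)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  # disease-burden contrast between non-responders and responders
  tab <- welch_t(1.630, 0.007, 1.372, 0.002)
  expect_equal(tab$t, 35.4, tolerance = 0.1)
  expect_error(welch_t(1, 0, 2, 1), "positive")
})

test_that("phenotype table round-trips through TSV", {
  coh <- simulate_scenario(scenario_config("I", n = 30, m = 5,
                                           n_causal_y = 2, seed = 6))
  coh <- apply_misreport(coh, misreport_config(nonresponse_frac = 0.2),
                         seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pheno_tsv(coh, path)
  back <- read_pheno_tsv(path)
  expect_equal(back$reported_y, coh$reported_y, tolerance = 1e-12)
  expect_identical(back$change_group, coh$change_group)
  expect_identical(levels(back$reason), levels(coh$reason))
})
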