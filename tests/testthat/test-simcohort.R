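test_that("genotype simulation: empty cases, determinism, binomial sampling", {
  g0 <- simulate_genotypes(5, 0, c(0.1, 0.5), seed = 1)
  expect_equal(dim(g0), c(5L, 0L))

  g1 <- simulate_genotypes(50, 20, c(0.1, 0.5), seed = 9)
  g2 <- simulate_genotypes(50, 20, c(0.1, 0.5), seed = 9)
  expect_identical(g1, g2)
  expect_true(all(g1 %in% 0:2))
  expect_identical(attr(g1, "position"),
                   (0:19) * 100000L + 1L)

  # fixed maf = 0.5: sample allele frequency concentrates as binomial predicts
  n <- 10000
  g <- simulate_genotypes(n, 200, c(0.5, 0.5), seed = 3)
  freq <- colMeans(g) / 2
  tol <- 4 * sqrt(0.25 / (2 * n))
  expect_gte(mean(abs(freq - 0.5) <= tol), 0.99)

  expect_error(simulate_genotypes(10, 5, c(0, 0.6)), "maf_range")
})

test_that("block-LD generator induces within-block correlation only", {
  g <- simulate_genotypes(3000, 20, c(0.2, 0.5), seed = 5,
                          ld = list(block_size = 10, rho = 0.9))
  r_within <- cor(g[, 1], g[, 2])
  r_across <- cor(g[, 10], g[, 11])   # last of block 1, first of block 2
  expect_gt(r_within^2, 0.3)
  expect_lt(r_across^2, 0.05)
})

test_that("scenario configs validate their invariants", {
  expect_error(scenario_config("I", n = 100, m = 50, n_causal_y = 60),
               "causal sets exceed")
  expect_error(scenario_config("I", h2_y = 1.2), "h2_y")
  expect_error(scenario_config("I", prevalence = 0), "prevalence")
  expect_error(ascertainment_config(q = 1), "q must be")
  expect_error(ascertainment_config(q = 0.1, c = -1), "c must be")
  expect_error(misreport_config(underreport_frac = 1.3), "fractions")
})

test_that("scenario structure: variances, prevalence, independence, causality", {
  slopes <- covs <- vy <- vd <- prev <- numeric(20)
  for (r in 1:20) {
    c1 <- simulate_scenario(scenario_config("I", n = 1500, m = 60,
                                            n_causal_y = 30, seed = 100 + r))
    c2 <- simulate_scenario(scenario_config("II", n = 1500, m = 60,
                                            n_causal_y = 30, b_yd = 0.3,
                                            seed = 200 + r))
    slopes[r] <- coef(lm(c1$liability_d ~ c1$true_y))[2]
    covs[r] <- cov(c2$true_y, c2$liability_d)
    vy[r] <- var(c1$true_y); vd[r] <- var(c1$liability_d)
    prev[r] <- mean(c1$disease)
  }
  sem <- function(x) sd(x) / sqrt(length(x))
  # scenario I: D independent of Y
  expect_lt(abs(mean(slopes)), 3 * sem(slopes))
  # scenario II: cov(Y, D) = b_yd
  expect_lt(abs(mean(covs) - 0.3), 3 * sem(covs))
  # unit variances and configured prevalence
  expect_lt(abs(mean(vy) - 1), 3 * sem(vy))
  expect_lt(abs(mean(vd) - 1), 3 * sem(vd))
  expect_lt(abs(mean(prev) - 0.15), 0.01)
})

test_that("h2 = 0 gives a null scan with uniform p-values", {
  coh <- simulate_scenario(scenario_config("I", n = 5000, m = 500,
                                           h2_y = 0, seed = 77))
  expect_true(all(coh$true_beta_y == 0))
  a <- run_gwas(coh$genotypes, coh$true_y)
  expect_gt(stats::ks.test(a$p, "punif")$p.value, 0.01)
})

test_that("same config twice reproduces the cohort bit for bit", {
  cfg <- scenario_config("IV", n = 300, m = 80, n_causal_y = 20,
                         n_causal_d = 20, seed = 13)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a[names(a) != "config"], b[names(b) != "config"])
})

test_that("ascertainment shifts exactly ceil(q n) top-liability individuals", {
  coh <- simulate_scenario(scenario_config("II", n = 1000, m = 50,
                                           n_causal_y = 20, seed = 21))
  same <- apply_ascertainment(coh, ascertainment_config(0, 0))
  expect_identical(same$reported_y, coh$reported_y)
  expect_identical(same$change_group, coh$change_group)

  asc <- apply_ascertainment(coh, ascertainment_config(0.10, 2))
  less <- which(asc$change_group == "LESS")
  expect_length(less, 100L)
  expect_identical(sort(asc$ascertained), less)
  # shifted by exactly 2 SDs of the true behaviour
  expect_equal(asc$reported_y[less],
               coh$true_y[less] - 2 * sd(coh$true_y))
  # they are the top-liability individuals
  expect_gte(min(asc$liability_d[less]),
             sort(coh$liability_d, decreasing = TRUE)[101])
  # everyone else untouched (conservation)
  rest <- setdiff(seq_len(1000), less)
  expect_identical(asc$reported_y[rest], coh$reported_y[rest])
  expect_identical(asc$reason[less], factor(rep("ILLNESS_OR_DOCTOR", 100),
                                            levels = levels(asc$reason)))
  # mean shift arithmetic: -q c SD up to ceiling rounding
  expect_equal(mean(asc$reported_y) - mean(coh$true_y),
               -100 / 1000 * 2 * sd(coh$true_y))
})

test_that("misreporting: identity, calibrated rates, liability dependence", {
  coh <- simulate_scenario(scenario_config("I", n = 4000, m = 40,
                                           n_causal_y = 20, seed = 31))
  ident <- apply_misreport(coh, misreport_config())
  expect_identical(ident$reported_y, coh$reported_y)

  # dependence-free non-response hits its marginal rate (binomial 99% CI)
  mis <- apply_misreport(coh, misreport_config(nonresponse_frac = 0.156),
                         seed = 5)
  rate <- mean(is.na(mis$reported_y))
  ci <- qnorm(0.995) * sqrt(0.156 * (1 - 0.156) / 4000)
  expect_lt(abs(rate - 0.156), ci)

  # liability-dependent underreporting selects sicker individuals
  diffs <- vapply(1:20, function(r) {
    coh_r <- simulate_scenario(scenario_config("I", n = 2000, m = 40,
                                               n_causal_y = 20,
                                               seed = 400 + r))
    m <- apply_misreport(coh_r, misreport_config(underreport_frac = 0.021,
                                                 underreport_dep = 1),
                         seed = r)
    mean(m$liability_d[m$underreported]) - mean(m$liability_d)
  }, numeric(1))
  expect_gt(mean(diffs) / (sd(diffs) / sqrt(20)), 2)
})

test_that("J-curve worlds: degenerate linear curve is monotone, true J is inherited", {
  lin <- simulate_jshape_world(6000, curve = function(x) 0.5 * x, seed = 8)
  bm <- binned_means(lin$gx, lin$y, 8)
  expect_true(all(diff(bm$mean_y) > 0))

  expect_error(simulate_jshape_world(100, curve = list(x0 = 1, k_left = -1,
                                                       k_right = 1)),
               "interior minimum")

  hits <- vapply(1:20, function(r) {
    w <- simulate_jshape_world(6000, seed = 500 + r)
    c(interior_minimum(binned_means(w$x, w$y, 8)$mean_y),
      interior_minimum(binned_means(w$gx, w$y, 8)$mean_y))
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
})

test_that("cohort round-trips through the plain-text directory format", {
  coh <- simulate_scenario(scenario_config("IV", n = 40, m = 15,
                                           n_causal_y = 5, n_causal_d = 5,
                                           seed = 3))
  coh <- apply_ascertainment(coh, ascertainment_config(0.2, 1))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(as.vector(back$genotypes), as.vector(coh$genotypes))
  expect_equal(attr(back$genotypes, "maf"), attr(coh$genotypes, "maf"),
               tolerance = 1e-9)
  expect_equal(back$true_y, coh$true_y, tolerance = 1e-12)
  expect_identical(back$change_group, coh$change_group)
  expect_identical(back$causal_idx_y, coh$causal_idx_y)
  expect_equal(back$true_beta_y, coh$true_beta_y, tolerance = 1e-12)
})
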