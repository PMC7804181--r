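test_that("Wald ratio and IVW closed forms", {
  ex <- make_assoc(beta = 0.5, se = 0.05)
  ou <- make_assoc(beta = 0.15, se = 0.04)
  est <- ivw_estimate("snp1", ex, ou)
  expect_identical(est$method, "WALD")
  expect_equal(est$b_xy, 0.3)
  expect_equal(est$se, 0.04 / 0.5)
  expect_equal(est$ci95, est$b_xy + c(-1.96, 1.96) * est$se)

  # several identical instruments: same estimate, smaller SE
  ex3 <- make_assoc(beta = rep(0.5, 3), se = rep(0.05, 3))
  ou3 <- make_assoc(beta = rep(0.15, 3), se = rep(0.04, 3))
  est3 <- ivw_estimate(ex3$snp, ex3, ou3)
  expect_identical(est3$method, "IVW")
  expect_equal(est3$b_xy, 0.3)
  expect_equal(est3$se, est$se / sqrt(3), tolerance = 1e-12)

  exz <- make_assoc(beta = c(0.5, 0), se = c(0.05, 0.05))
  expect_error(ivw_estimate(exz$snp, exz, ou3[1:2, ]),
               class = "mlcbias_weak_instrument_error")
})

test_that("median estimators: closed cases and the cumulative-weight oracle", {
  ex <- make_assoc(beta = rep(1, 3), se = rep(0.01, 3))
  ou <- make_assoc(beta = c(0.1, 0.3, 0.5), se = rep(0.05, 3))
  med <- median_estimates(ex$snp, ex, ou, boot = 50, seed = 2)
  expect_equal(med$simple$b_xy, 0.3)

  same <- make_assoc(beta = rep(0.42, 4), se = rep(0.03, 4))
  exs <- make_assoc(beta = rep(1, 4), se = rep(0.01, 4))
  both <- median_estimates(exs$snp, exs, same, boot = 50, seed = 2)
  expect_equal(both$simple$b_xy, 0.42)
  expect_equal(both$weighted$b_xy, 0.42)

  expect_error(median_estimates(ex$snp[1:2], ex[1:2, ], ou[1:2, ]),
               class = "mlcbias_insufficient_instruments_error")

  # 20 random fixtures against the independent interpolation oracle
  set.seed(14)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    be <- rnorm(k, 1, 0.3); bo <- rnorm(k, 0.3, 0.4)
    seo <- runif(k, 0.02, 0.3)
    exf <- make_assoc(beta = be, se = rep(0.01, k))
    ouf <- make_assoc(beta = bo, se = seo)
    got <- median_estimates(exf$snp, exf, ouf, boot = 2, seed = 1)
    r <- bo / be; w <- be^2 / seo^2
    expect_equal(got$weighted$b_xy, weighted_median_oracle(r, w),
                 tolerance = 1e-12)
    expect_equal(got$simple$b_xy, weighted_median_oracle(r, rep(1, k)),
                 tolerance = 1e-12)
  }
})

test_that("instrument selection: defaults echoed, no-instrument error, causal-only IVs", {
  null_scan <- make_assoc(beta = rep(0.01, 5), se = rep(0.05, 5))
  expect_error(select_ivs(null_scan),
               class = "mlcbias_no_instrument_error")

  coh <- simulate_scenario(scenario_config("II", n = 20000, m = 300,
                                           n_causal_y = 30, h2_y = 0.4,
                                           b_yd = 0.3, seed = 31))
  scan <- run_gwas(coh$genotypes, coh$true_y)
  mr <- mr_analysis(scan, run_gwas(coh$genotypes, coh$liability_d),
                    genotypes = coh$genotypes, boot = 50, seed = 3)
  expect_equal(mr$manifest$p_threshold, 5e-8)
  expect_equal(mr$manifest$window_bp, 1e6)
  expect_equal(mr$manifest$r2_threshold, 0.01)
  expect_identical(mr$manifest$direction, "forward")
  # in linkage equilibrium every selected instrument is a true causal SNP
  expect_true(all(mr$ivs$snp %in% coh$snp$id[coh$causal_idx_y]))
})

test_that("IVW recovers the causal effect and scales correctly", {
  hits <- 0
  ests <- numeric(10)
  for (r in 1:10) {
    coh <- simulate_scenario(scenario_config("II", n = 8000, m = 300,
                                             n_causal_y = 50, h2_y = 0.4,
                                             b_yd = 0.3, seed = 900 + r))
    ys <- run_gwas(coh$genotypes, coh$true_y)
    ds <- run_gwas(coh$genotypes, coh$liability_d)
    ivs <- select_ivs(ys, coh$genotypes,
                      clump_config(p_threshold = 5e-8, window_bp = 200000))
    est <- ivw_estimate(ivs, ys, ds)
    ests[r] <- est$b_xy
    if (est$ci95[1] <= 0.3 && 0.3 <= est$ci95[2]) hits <- hits + 1
    if (r == 1) {
      # rescaling the exposure scan rescales the estimate inversely
      ys2 <- ys; ys2$beta <- 2 * ys$beta; ys2$se <- 2 * ys$se
      est2 <- ivw_estimate(ivs, ys2, ds)
      expect_equal(est2$b_xy, est$b_xy / 2, tolerance = 1e-10)
    }
  }
  expect_gte(hits, 8)
  expect_lt(abs(mean(ests) - 0.3), 0.05)
})

test_that("reverse direction and the outlier screen are plumbed through", {
  ex <- make_assoc(beta = rep(0.5, 4), se = rep(0.02, 4))
  ou <- make_assoc(beta = c(0.15, 0.16, 0.14, 0.35), se = rep(0.02, 4))
  scr <- ivw_estimate(ex$snp, ex, ou, outlier_k = 3)
  expect_identical(scr$removed_outliers, "snp4")
  no_scr <- ivw_estimate(ex$snp, ex, ou)
  expect_gt(no_scr$b_xy, scr$b_xy)

  rev <- mr_analysis(ou, ex, ivs = ex$snp, methods = "ivw", reverse = TRUE)
  fwd <- mr_analysis(ex, ou, ivs = ex$snp, methods = "ivw")
  expect_identical(rev$manifest$direction, "reverse")
  expect_equal(rev$estimates$ivw$b_xy, fwd$estimates$ivw$b_xy)
})

test_that("null world: both directions compatible with zero", {
  cfg <- null_world_config(n = 8000, m = 300, seed = 77)
  cfg$n_causal_y <- 40L; cfg$n_causal_d <- 40L; cfg$h2_y <- 0.4
  cfg$h2_d <- 0.4
  coh <- simulate_scenario(cfg)
  ys <- run_gwas(coh$genotypes, coh$true_y)
  ds <- run_gwas(coh$genotypes, coh$liability_d)
  ccfg <- clump_config(window_bp = 200000)
  f <- ivw_estimate(select_ivs(ys, coh$genotypes, ccfg), ys, ds)
  b <- ivw_estimate(select_ivs(ds, coh$genotypes, ccfg), ds, ys)
  expect_lt(abs(f$b_xy), 2 * f$se)
  expect_lt(abs(b$b_xy), 2 * b$se)
})
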