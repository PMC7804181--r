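# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# mid-sized scenario-II cohort with clear signals
fixture_cohort2 <- function() cached("cohort2", {
  simulate_scenario(scenario_config("II", n = 4000, m = 300,
                                    n_causal_y = 60, h2_y = 0.4,
                                    b_yd = 0.3, seed = 42))
})

# two-trait null: independent genetic architectures, no causal link
null_world_config <- function(n = 10000L, m = 1000L, seed = 1L)
  scenario_config("IV", n = n, m = m, n_causal_y = 100L, n_causal_d = 100L,
                  h2_y = 0.3, h2_d = 0.3, b_yd = 0, seed = seed)

strat_rules <- function() qc_rules(drop_illness_reducers = FALSE)

# the uncorrected full-sample scan: sex-standardised phenotype, sex + age
# adjustment (same treatment the stratified arm gives each group)
scan_standardized_pub <- function(coh, phenotype = "reported_y") {
  run_gwas(coh$genotypes,
           standardize_by_group(coh[[phenotype]], coh$sex, strat_rules())$z,
           cbind(coh$sex, coh$age))
}

# per-SNP OLS through the full normal equations -- the independent oracle
# for the scan
lm_scan_oracle <- function(g, y, covar = NULL) {
  m <- ncol(g)
  out <- data.frame(beta = numeric(m), se = numeric(m), p = numeric(m))
  for (j in seq_len(m)) {
    X <- if (is.null(covar)) cbind(1, g[, j]) else cbind(1, g[, j], covar)
    fit <- lm(y ~ X - 1)
    sm <- summary(fit)$coefficients
    out$beta[j] <- sm[2, 1]
    out$se[j] <- sm[2, 2]
    out$p[j] <- 2 * pnorm(-abs(sm[2, 1] / sm[2, 2]))
  }
  out
}

# interpolated weighted median through approx() -- independent of the
# package's cumulative-weight loop
weighted_median_oracle <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] < 0.5) return(r[length(r)])
  stats::approx(cw, r, xout = 0.5, ties = "ordered")$y
}

# assoc_result constructed directly from vectors (for estimator tests)
make_assoc <- function(beta, se, snp = paste0("snp", seq_along(beta)),
                       pos = (seq_along(beta) - 1L) * 100000L + 1L,
                       freq = rep(0.3, length(beta)),
                       n = 1000L) {
  out <- data.frame(snp = snp, pos = pos, a1 = "A", a2 = "G", freq = freq,
                    beta = beta, se = se,
                    p = 2 * pnorm(-abs(beta / se)), n = n, status = "ok",
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}
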