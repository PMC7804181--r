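# Synthetic cohorts with disease ascertainment of a behavioural trait.
#
# The generative model: a behavioural trait Y is polygenic (n_causal_y SNPs,
# heritability h2_y, var(Y) = 1); disease liability D is a unit-variance
# Gaussian that may receive a causal contribution b_yd * Y and/or its own
# polygenic component (n_causal_d SNPs, h2_d); disease status is D exceeding
# the (1 - prevalence) quantile. Disease ascertainment then rewrites the
# *reported* behaviour: the top q fraction of liability subtract c standard
# deviations of Y and are labelled as having reduced the behaviour (LESS).
# Misreporting (zero reports, non-response) is layered on top with a
# liability-dependent logistic mechanism.

#' Scenario configuration for cohort simulation
#'
#' Four scenarios describe how the behavioural trait Y and disease liability D
#' are genetically related:
#' \describe{
#'   \item{I}{D independent of Y; `n_causal_y` SNPs affect Y only.}
#'   \item{II}{Y causally affects D (`b_yd` per SD of Y on the liability
#'     scale); SNPs affect Y, and D only through Y.}
#'   \item{III}{Y and D independent; `n_causal_d` SNPs affect D only.}
#'   \item{IV}{Y causally affects D, and a disjoint set of `n_causal_d` SNPs
#'     affects D directly.}
#' }
#' Setting `b_yd = 0` in scenario IV gives a two-trait null with independent
#' genetic architectures (true SNP-effect correlation zero) in which both
#' traits carry genetic variance.
#'
#' @param scenario One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param n Number of individuals.
#' @param m Number of SNPs.
#' @param n_causal_y,n_causal_d Causal-set sizes (default 100 each;
#'   `n_causal_d` only used in scenarios III/IV).
#' @param h2_y Heritability of Y in `[0, 1]`.
#' @param h2_d Variance of D explained by its direct SNPs (scenarios III/IV).
#' @param b_yd Causal effect of Y on D, liability SDs per SD of Y
#'   (scenarios II/IV).
#' @param prevalence Disease prevalence in `(0, 1)`.
#' @param maf_range Minor-allele-frequency interval within `(0, 0.5]`.
#' @param ld Optional LD spec `list(block_size =, rho =)` passed to
#'   [simulate_genotypes()].
#' @param seed Integer root seed; all stages derive sub-seeds from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("I", "II", "III", "IV"),
                            n = 10000L, m = 1000L,
                            n_causal_y = 100L, n_causal_d = 100L,
                            h2_y = 0.3, h2_d = 0.3, b_yd = 0.3,
                            prevalence = 0.15,
                            maf_range = c(0.01, 0.5),
                            ld = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  n <- as.integer(n); m <- as.integer(m)
  stopifnot(n >= 0, m >= 0)
  if (h2_y < 0 || h2_y > 1) stop("h2_y must be in [0, 1]", call. = FALSE)
  if (h2_d < 0 || h2_d > 1) stop("h2_d must be in [0, 1]", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)", call. = FALSE)
  check_maf_range(maf_range)
  uses_y <- scenario %in% c("I", "II", "IV")
  uses_d <- scenario %in% c("III", "IV")
  need <- (if (uses_y) n_causal_y else 0L) + (if (uses_d) n_causal_d else 0L)
  if (need > m)
    stop("causal sets exceed the number of SNPs (", need, " > ", m, ")",
         call. = FALSE)
  structure(list(scenario = scenario, n = n, m = m,
                 n_causal_y = as.integer(n_causal_y),
                 n_causal_d = as.integer(n_causal_d),
                 h2_y = h2_y, h2_d = h2_d, b_yd = b_yd,
                 prevalence = prevalence, maf_range = maf_range,
                 ld = ld, seed = as.integer(seed)),
            class = "scenario_config")
}

check_maf_range <- function(maf_range) {
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be an interval within (0, 0.5]", call. = FALSE)
  invisible(maf_range)
}

#' Ascertainment configuration
#'
#' @param q Top fraction of the liability distribution that is ascertained,
#'   in `[0, 1)`. The study grid is `{0.10, 0.20, 0.30, 0.40}`.
#' @param c Downward shift of the reported behaviour, in SDs of the true
#'   behaviour (`c >= 0`). The study grid is `{1, 2, 3, 4, 5}`.
#' @param illness_frac Fraction of ascertained individuals whose recorded
#'   reason is illness or doctor's advice (the rest get `OTHER`). Default 1.
#' @return An `ascertainment_config` list.
#' @export
ascertainment_config <- function(q, c = 0, illness_frac = 1.0) {
  stopifnot(is.numeric(q), length(q) == 1L, is.numeric(c), length(c) == 1L)
  if (q < 0 || q >= 1) stop("q must be in [0, 1)", call. = FALSE)
  if (c < 0) stop("c must be >= 0", call. = FALSE)
  if (illness_frac < 0 || illness_frac > 1)
    stop("illness_frac must be in [0, 1]", call. = FALSE)
  structure(list(q = q, c = c, illness_frac = illness_frac),
            class = "ascertainment_config")
}

#' Misreport configuration
#'
#' Underreporting (a zero consumption report) and non-response (a missing
#' report) are Bernoulli per individual with logistic dependence on disease
#' liability; the intercept is calibrated so the marginal rate matches the
#' requested fraction.
#'
#' @param underreport_frac,nonresponse_frac Marginal rates in `[0, 1]`.
#' @param underreport_dep,nonresponse_dep Log-odds change per SD of liability.
#' @return A `misreport_config` list.
#' @export
misreport_config <- function(underreport_frac = 0, underreport_dep = 0,
                             nonresponse_frac = 0, nonresponse_dep = 0) {
  for (f in c(underreport_frac, nonresponse_frac))
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]", call. = FALSE)
  structure(list(underreport_frac = underreport_frac,
                 underreport_dep = underreport_dep,
                 nonresponse_frac = nonresponse_frac,
                 nonresponse_dep = nonresponse_dep),
            class = "misreport_config")
}

#' Simulate SNP genotypes
#'
#' Allele counts are binomial(2, maf) per SNP under Hardy-Weinberg
#' equilibrium, built from two independent haplotypes. MAFs are uniform on
#' `maf_range`. By default SNPs are in linkage equilibrium; an optional
#' block-AR(1) generator induces LD: within blocks of `block_size` SNPs each
#' haplotype's latent Gaussian follows an AR(1) with parameter `rho` (blocks
#' are independent), giving positively correlated allele counts for nearby
#' SNPs. Base-pair positions are assigned at 100 kb spacing (1-based) on a
#' single synthetic chromosome.
#'
#' @param n Individuals (rows).
#' @param m SNPs (columns).
#' @param maf_range MAF interval within `(0, 0.5]`; a single value fixes all
#'   MAFs.
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @param ld `NULL` (linkage equilibrium) or `list(block_size =, rho =)`.
#' @return An `n x m` integer-valued matrix with values 0/1/2, column names
#'   `snp1..snpm`, and attributes `position` (bp) and `maf` (simulated MAF).
#' @examples
#' g <- simulate_genotypes(100, 5, c(0.1, 0.5), seed = 7)
#' table(g[, 1])
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.01, 0.5), seed = 1L,
                               ld = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  stopifnot(n >= 0, m >= 0)
  if (length(maf_range) == 1L) maf_range <- rep(maf_range, 2L)
  check_maf_range(maf_range)
  if (!is.null(ld)) {
    stopifnot(is.list(ld), !is.null(ld$block_size), !is.null(ld$rho))
    if (abs(ld$rho) >= 1) stop("ld$rho must be in (-1, 1)", call. = FALSE)
  }
  out <- with_seed(seed, {
    maf <- runif(m, maf_range[1], maf_range[2])
    if (m == 0L || n == 0L) {
      g <- matrix(integer(0), n, m)
    } else if (is.null(ld)) {
      u1 <- matrix(runif(n * m), n, m)
      u2 <- matrix(runif(n * m), n, m)
      g <- (u1 < rep(maf, each = n)) + (u2 < rep(maf, each = n))
    } else {
      # Gaussian-copula haplotypes: correlated latents, HWE marginals
      thr <- rep(qnorm(maf), each = n)
      g <- (ld_latent(n, m, ld) < thr) + (ld_latent(n, m, ld) < thr)
    }
    storage.mode(g) <- "integer"
    list(g = g, maf = maf)
  })
  g <- out$g
  colnames(g) <- if (m > 0L) paste0("snp", seq_len(m)) else character(0)
  attr(g, "position") <- if (m > 0L) (seq_len(m) - 1L) * 100000L + 1L else integer(0)
  attr(g, "maf") <- out$maf
  g
}

# latent AR(1) Gaussians, restarted at block boundaries
ld_latent <- function(n, m, ld) {
  z <- matrix(rnorm(n * m), n, m)
  rho <- ld$rho
  bs <- as.integer(ld$block_size)
  if (bs < 1L) stop("ld$block_size must be >= 1", call. = FALSE)
  sc <- sqrt(1 - rho^2)
  for (j in seq_len(m)[-1]) {
    if ((j - 1L) %% bs != 0L) z[, j] <- rho * z[, j - 1L] + sc * z[, j]
  }
  z
}

#' Simulate a cohort under one scenario
#'
#' Builds genotypes, the behavioural trait Y (unit variance, genetic variance
#' `h2_y`), disease liability D (unit variance), binary disease status via the
#' liability-threshold model at the configured prevalence, and demographic
#' covariates (sex, age; no phenotypic effect, available for adjustment
#' plumbing). `reported_y` starts equal to `true_y` and `change_group` at
#' `SAME`; [apply_ascertainment()] and [apply_misreport()] then perturb the
#' reports.
#'
#' `true_beta_y` and `true_gamma_d` hold per-SNP true effects on Y and on D
#' (for D: direct effects plus `b_yd` times the effect on Y), so the true
#' SNP-effect correlation between the traits is known exactly.
#'
#' @param cfg A [scenario_config()].
#' @return An `mlc_cohort` list; see Details.
#' @export
simulate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$n; m <- cfg$m
  g <- simulate_genotypes(n, m, cfg$maf_range,
                          seed = derive_seed(cfg$seed, "genotypes"),
                          ld = cfg$ld)
  uses_y <- cfg$scenario %in% c("I", "II", "IV")
  uses_d <- cfg$scenario %in% c("III", "IV")
  uses_byd <- cfg$scenario %in% c("II", "IV")

  eff <- with_seed(derive_seed(cfg$seed, "effects"), {
    idx_all <- sample.int(m, (if (uses_y) cfg$n_causal_y else 0L) +
                               (if (uses_d) cfg$n_causal_d else 0L))
    k_y <- if (uses_y) cfg$n_causal_y else 0L
    list(idx_y = sort(idx_all[seq_len(k_y)]),
         idx_d = sort(idx_all[seq_len(length(idx_all) - k_y) + k_y]),
         raw_y = rnorm(k_y),
         raw_d = rnorm(length(idx_all) - k_y))
  })

  beta_y <- numeric(m)
  genet_y <- numeric(n)
  if (uses_y && cfg$h2_y > 0 && length(eff$idx_y)) {
    gy <- as.numeric(g[, eff$idx_y, drop = FALSE] %*% eff$raw_y)
    s <- sqrt(cfg$h2_y) / sd(gy)
    beta_y[eff$idx_y] <- eff$raw_y * s
    genet_y <- (gy - mean(gy)) * s
  }
  true_y <- genet_y +
    with_seed(derive_seed(cfg$seed, "env_y"),
              rnorm(n, 0, sqrt(max(0, 1 - cfg$h2_y))))

  gamma_direct <- numeric(m)
  genet_d <- numeric(n)
  if (uses_d && cfg$h2_d > 0 && length(eff$idx_d)) {
    gd <- as.numeric(g[, eff$idx_d, drop = FALSE] %*% eff$raw_d)
    s <- sqrt(cfg$h2_d) / sd(gd)
    gamma_direct[eff$idx_d] <- eff$raw_d * s
    genet_d <- (gd - mean(gd)) * s
  }
  b <- if (uses_byd) cfg$b_yd else 0
  res_var <- 1 - b^2 - (if (uses_d) cfg$h2_d else 0)
  if (res_var < 0)
    stop("liability residual variance negative: reduce b_yd or h2_d",
         call. = FALSE)
  liability <- b * true_y + genet_d +
    with_seed(derive_seed(cfg$seed, "env_d"), rnorm(n, 0, sqrt(res_var)))

  thr <- quantile(liability, 1 - cfg$prevalence, names = FALSE)
  disease <- as.integer(liability > thr)

  demog <- with_seed(derive_seed(cfg$seed, "demog"),
                     list(sex = rbinom(n, 1L, 0.5),
                          age = runif(n, 40, 70)))

  cohort <- list(
    genotypes = g,
    snp = data.frame(id = colnames(g),
                     position = attr(g, "position"),
                     maf = attr(g, "maf")),
    id = seq_len(n),
    sex = demog$sex,
    age = demog$age,
    true_y = true_y,
    reported_y = true_y,
    liability_d = liability,
    disease = disease,
    change_group = factor(rep("SAME", n),
                          levels = c("LESS", "SAME", "MORE")),
    reason = factor(rep("NONE", n),
                    levels = c("ILLNESS_OR_DOCTOR", "HEALTH_PRECAUTION",
                               "FINANCIAL", "OTHER", "NONE")),
    underreported = logical(n),
    nonresponse = logical(n),
    causal_idx_y = eff$idx_y,
    causal_idx_d = eff$idx_d,
    true_beta_y = beta_y,
    true_gamma_d = gamma_direct + b * beta_y,
    config = cfg
  )
  class(cohort) <- "mlc_cohort"
  cohort
}

#' @export
print.mlc_cohort <- function(x, ...) {
  cat("<mlc_cohort> scenario", x$config$scenario,
      "| n =", length(x$id), "| m =", ncol(x$genotypes), "\n")
  cat("  cases:", sum(x$disease), sprintf("(%.1f%%)", 100 * mean(x$disease)),
      "| LESS:", sum(x$change_group == "LESS"),
      "| missing reports:", sum(is.na(x$reported_y)), "\n")
  invisible(x)
}

#' Number of individuals in a cohort
#' @param cohort An `mlc_cohort`.
#' @return Integer count.
#' @export
cohort_size <- function(cohort) length(cohort$id)

#' Subset a cohort by individuals
#'
#' Keeps all per-SNP information and subsets every per-individual field,
#' including genotype rows.
#'
#' @param cohort An `mlc_cohort`.
#' @param keep Integer or logical index of individuals to keep.
#' @return The subset `mlc_cohort`.
#' @export
subset_cohort <- function(cohort, keep) {
  stopifnot(inherits(cohort, "mlc_cohort"))
  per_ind <- c("id", "sex", "age", "true_y", "reported_y", "liability_d",
               "disease", "change_group", "reason", "underreported",
               "nonresponse")
  cohort$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  for (f in per_ind) cohort[[f]] <- cohort[[f]][keep]
  cohort
}

#' Apply disease ascertainment to reported behaviour
#'
#' Exactly `ceiling(q * n)` individuals with the highest liability (ties
#' broken by individual index) have their reported behaviour reduced by
#' `c` SDs of the true behaviour and are labelled `change_group = LESS`; a
#' fraction `illness_frac` of them (the highest-liability ones) record
#' illness or doctor's advice as the reason, the rest `OTHER`. Everyone else
#' is untouched.
#'
#' @param cohort An `mlc_cohort` with `reported_y` present.
#' @param acfg An [ascertainment_config()].
#' @return The modified cohort; the ascertained index set is stored in
#'   `cohort$ascertained`.
#' @export
apply_ascertainment <- function(cohort, acfg) {
  stopifnot(inherits(cohort, "mlc_cohort"),
            inherits(acfg, "ascertainment_config"))
  n <- cohort_size(cohort)
  n_asc <- as.integer(ceiling(acfg$q * n))
  cohort$ascertainment <- acfg
  if (n_asc == 0L) {
    cohort$ascertained <- integer(0)
    return(cohort)
  }
  ord <- order(-cohort$liability_d, seq_len(n))
  idx <- ord[seq_len(n_asc)]
  shift <- acfg$c * sd(cohort$true_y)
  cohort$reported_y[idx] <- cohort$true_y[idx] - shift
  cohort$change_group[idx] <- "LESS"
  n_ill <- as.integer(ceiling(acfg$illness_frac * n_asc))
  if (n_ill > 0L) cohort$reason[idx[seq_len(n_ill)]] <- "ILLNESS_OR_DOCTOR"
  if (n_ill < n_asc) cohort$reason[idx[(n_ill + 1L):n_asc]] <- "OTHER"
  cohort$ascertained <- idx
  cohort
}

# intercept such that mean(plogis(a + dep * x)) == target
calibrate_logistic <- function(target, dep, x) {
  if (target == 0) return(-Inf)
  if (target == 1) return(Inf)
  f <- function(a) mean(plogis(a + dep * x)) - target
  out <- tryCatch(uniroot(f, c(-50, 50), tol = 1e-10),
                  error = function(e) NULL)
  if (is.null(out))
    stop("cannot calibrate marginal misreport rate ", target,
         " with dependence ", dep, call. = FALSE)
  out$root
}

#' Apply misreporting mechanisms to reported behaviour
#'
#' Each individual underreports (reported value set to 0) with probability
#' `plogis(a + underreport_dep * D)` where the intercept `a` is calibrated so
#' the marginal rate equals `underreport_frac`; non-response (reported value
#' set to missing) works the same way and is applied after underreporting.
#'
#' @param cohort An `mlc_cohort`.
#' @param mcfg A [misreport_config()].
#' @param seed Optional seed; defaults to a sub-seed of the cohort's root.
#' @return The modified cohort with logical fields `underreported` and
#'   `nonresponse` updated.
#' @export
apply_misreport <- function(cohort, mcfg, seed = NULL) {
  stopifnot(inherits(cohort, "mlc_cohort"), inherits(mcfg, "misreport_config"))
  if (is.null(seed)) seed <- derive_seed(cohort$config$seed, "misreport")
  n <- cohort_size(cohort)
  d <- cohort$liability_d
  with_seed(seed, {
    if (mcfg$underreport_frac > 0) {
      a <- calibrate_logistic(mcfg$underreport_frac, mcfg$underreport_dep, d)
      hit <- runif(n) < plogis(a + mcfg$underreport_dep * d)
      cohort$reported_y[hit] <- 0
      cohort$underreported <- cohort$underreported | hit
    }
    if (mcfg$nonresponse_frac > 0) {
      a <- calibrate_logistic(mcfg$nonresponse_frac, mcfg$nonresponse_dep, d)
      hit <- runif(n) < plogis(a + mcfg$nonresponse_dep * d)
      cohort$reported_y[hit] <- NA_real_
      cohort$nonresponse <- cohort$nonresponse | hit
    }
  })
  cohort$misreport <- mcfg
  cohort
}

#' Evaluate a piecewise-quadratic exposure-outcome curve
#'
#' `curve` is either a function of x or a list `list(x0 =, k_left =,
#' k_right =)` describing `k_left * (x - x0)^2` left of the minimum and
#' `k_right * (x - x0)^2` right of it (unique interior minimum at `x0`).
#'
#' @param curve Curve spec.
#' @param x Numeric vector.
#' @return Numeric vector of curve values.
#' @export
eval_curve <- function(curve, x) {
  if (is.function(curve)) return(curve(x))
  stopifnot(is.list(curve), all(c("x0", "k_left", "k_right") %in% names(curve)))
  if (curve$k_left <= 0 || curve$k_right <= 0)
    stop("piecewise-quadratic curve must have a unique interior minimum ",
         "(k_left > 0 and k_right > 0)", call. = FALSE)
  ifelse(x < curve$x0,
         curve$k_left * (x - curve$x0)^2,
         curve$k_right * (x - curve$x0)^2)
}

#' Simulate a world with a known exposure-outcome dose-response curve
#'
#' The exposure X is polygenic with heritability `h2`; the outcome is
#' `curve(X)` plus Gaussian noise. Used to check that a J-shaped (interior
#' minimum) true relationship is inherited by the genetic predictor of the
#' exposure: binning the outcome on the genetic component of X reproduces the
#' interior minimum, since E\[outcome | genetic score\] traces the curve
#' evaluated at the score plus a constant.
#'
#' @param n Individuals.
#' @param curve Curve spec for [eval_curve()]; must have a unique interior
#'   minimum (checked for the list form).
#' @param seed Integer seed.
#' @param h2 Heritability of the exposure.
#' @param m Number of SNPs behind the exposure.
#' @param noise_sd SD of outcome noise.
#' @return A data.frame with columns `x` (exposure), `gx` (genetic component
#'   of the exposure) and `y` (outcome); genotypes in attribute `genotypes`.
#' @export
simulate_jshape_world <- function(n, curve = list(x0 = 0.5, k_left = 1,
                                                  k_right = 0.6),
                                  seed = 1L, h2 = 0.5, m = 200L,
                                  noise_sd = 0.5) {
  cfg <- scenario_config("I", n = n, m = m, n_causal_y = min(100L, m),
                         h2_y = h2, seed = seed,
                         maf_range = c(0.05, 0.5))
  coh <- simulate_scenario(cfg)
  gx <- as.numeric(coh$genotypes %*% coh$true_beta_y)
  gx <- gx - mean(gx)
  y0 <- eval_curve(curve, coh$true_y)
  y <- y0 + with_seed(derive_seed(seed, "jshape_noise"),
                      rnorm(n, 0, noise_sd))
  out <- data.frame(x = coh$true_y, gx = gx, y = y)
  attr(out, "genotypes") <- coh$genotypes
  attr(out, "curve") <- curve
  out
}
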