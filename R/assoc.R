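# Per-SNP association scans and greedy clumping.
#
# Each SNP is tested by ordinary least squares of the phenotype on its allele
# count plus covariates and an intercept. With unrelated individuals this is
# the appropriate desk-scale model; the scan is computed for all SNPs at once
# through the Frisch-Waugh-Lovell decomposition (project phenotype and
# genotypes off the covariate space, then simple regression per SNP), which
# reproduces the full normal-equations fit exactly.

#' Per-SNP least-squares association scan
#'
#' @param genotypes `n x m` allele-count matrix (attributes `position` and
#'   column names are carried into the result when present).
#' @param phenotype Numeric vector of length `n`; rows with missing phenotype
#'   (or any missing covariate) are dropped for the whole scan.
#' @param covariates Optional `n x k` numeric matrix/data.frame, fitted
#'   alongside each SNP. Must not be rank deficient after adding the
#'   intercept.
#' @param exact_t Use the exact t reference instead of the large-sample
#'   normal approximation for p-values.
#' @return An `assoc_result` data.frame with one row per SNP: `snp`, `pos`,
#'   `a1`, `a2` (synthetic effect/other allele labels), `freq` (frequency of
#'   the counted allele), `beta`, `se`, `p`, `n`, `status` (`"ok"` or
#'   `"monomorphic"`; monomorphic SNPs are flagged, not estimated).
#' @examples
#' g <- simulate_genotypes(200, 10, c(0.2, 0.5), seed = 3)
#' y <- rnorm(200) + 0.5 * g[, 1]
#' head(run_gwas(g, y))
#' @export
run_gwas <- function(genotypes, phenotype, covariates = NULL,
                     exact_t = FALSE) {
  g <- as.matrix(genotypes)
  n0 <- nrow(g); m <- ncol(g)
  stopifnot(length(phenotype) == n0)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n0)
  }
  keep <- !is.na(phenotype)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  if (!any(keep)) stop("no usable rows: phenotype all missing", call. = FALSE)
  y <- phenotype[keep]
  if (sd(y) == 0) stop("phenotype is constant", call. = FALSE)
  g <- g[keep, , drop = FALSE]
  n <- length(y)
  C <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(1, covariates[keep, , drop = FALSE])
  qrC <- qr(C)
  if (qrC$rank < ncol(C))
    stop("covariate design is rank deficient", call. = FALSE)
  Q <- qr.Q(qrC)
  yr <- y - Q %*% crossprod(Q, y)
  gty <- as.numeric(crossprod(g, yr))
  QtG <- crossprod(Q, g)
  gss <- colSums(g^2) - colSums(QtG^2)   # residual SS of each SNP
  df <- n - ncol(C) - 1L
  mono <- gss <= n * 1e-12
  beta <- se <- p <- rep(NA_real_, m)
  ok <- !mono
  beta[ok] <- gty[ok] / gss[ok]
  rss <- sum(yr^2) - beta[ok]^2 * gss[ok]
  se[ok] <- sqrt(pmax(rss, 0) / df / gss[ok])
  z <- beta[ok] / se[ok]
  p[ok] <- if (exact_t) 2 * pt(-abs(z), df) else 2 * pnorm(-abs(z))
  pos <- attr(genotypes, "position")
  if (is.null(pos)) pos <- (seq_len(m) - 1L) * 100000L + 1L
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  out <- data.frame(snp = ids, pos = as.integer(pos),
                    a1 = "A", a2 = "G",
                    freq = colMeans(g) / 2,
                    beta = beta, se = se, p = p, n = n,
                    status = ifelse(mono, "monomorphic", "ok"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Write / read summary statistics in COJO .ma format
#'
#' Tab-separated with the canonical column order `SNP A1 A2 freq b se p N`.
#' Positions are not part of the format; `read_ma` restores them from an
#' optional `pos` argument or leaves them `NA`.
#'
#' @param assoc An `assoc_result`.
#' @param path File path.
#' @param pos Optional integer positions for `read_ma`.
#' @return `write_ma` returns `path` invisibly; `read_ma` an `assoc_result`.
#' @export
write_ma <- function(assoc, path) {
  df <- data.frame(SNP = assoc$snp, A1 = assoc$a1, A2 = assoc$a2,
                   freq = assoc$freq, b = assoc$beta, se = assoc$se,
                   p = assoc$p, N = assoc$n)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ma
#' @export
read_ma <- function(path, pos = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
  if (!all(need %in% names(df)))
    stop("not a .ma file: need columns ", paste(need, collapse = " "),
         call. = FALSE)
  out <- data.frame(snp = df$SNP, pos = if (is.null(pos)) NA_integer_ else
                    as.integer(pos),
                    a1 = df$A1, a2 = df$A2, freq = df$freq,
                    beta = df$b, se = df$se, p = df$p, n = df$N,
                    status = "ok", stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Clumping configuration
#'
#' Defaults follow standard instrument-selection practice: 1 Mb window,
#' p < 5e-8, LD r^2 < 0.01.
#'
#' @param window_bp Distance window in bp.
#' @param p_threshold Significance threshold in `(0, 1)`.
#' @param r2_threshold Squared-correlation threshold.
#' @return A `clump_config` list.
#' @export
clump_config <- function(window_bp = 1000000L, p_threshold = 5e-8,
                         r2_threshold = 0.01) {
  if (window_bp <= 0 || r2_threshold <= 0)
    stop("window_bp and r2_threshold must be positive", call. = FALSE)
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must be in (0, 1)", call. = FALSE)
  structure(list(window_bp = as.numeric(window_bp),
                 p_threshold = p_threshold,
                 r2_threshold = r2_threshold),
            class = "clump_config")
}

#' Greedy clumping of an association scan into independent loci
#'
#' Repeatedly takes the lowest-p SNP passing `p_threshold` as a lead (ties
#' broken by position, then id) and removes every remaining candidate within
#' `window_bp` of it or with sample `r^2 >=` `r2_threshold` against it. The
#' surviving leads therefore form an antichain: no two violate either rule.
#'
#' @param assoc An `assoc_result` (or IVW meta result) with `pos` available.
#' @param genotypes Allele-count matrix for the r^2 rule, columns matching
#'   `assoc$snp`; `NULL` for distance-only clumping.
#' @param cfg A [clump_config()].
#' @return The lead rows of `assoc` (possibly zero rows) with a `locus`
#'   index column prepended.
#' @export
clump <- function(assoc, genotypes = NULL, cfg = clump_config()) {
  stopifnot(inherits(cfg, "clump_config"))
  cand <- which(!is.na(assoc$p) & assoc$p <= cfg$p_threshold)
  empty <- assoc[integer(0), , drop = FALSE]
  if (!length(cand)) {
    out <- cbind(locus = integer(0), empty)
    class(out) <- class(assoc)
    return(out)
  }
  if (any(is.na(assoc$pos[cand])))
    stop("positions required for clumping", call. = FALSE)
  ord <- cand[order(assoc$p[cand], assoc$pos[cand], assoc$snp[cand])]
  if (!is.null(genotypes)) {
    gi <- match(assoc$snp, colnames(genotypes))
    if (any(is.na(gi[cand])))
      stop("genotypes missing for some candidate SNPs", call. = FALSE)
  }
  leads <- integer(0)
  alive <- rep(TRUE, length(ord))
  while (any(alive)) {
    i <- ord[which(alive)[1]]
    leads <- c(leads, i)
    rest_pos <- which(alive)
    rest <- ord[rest_pos]
    kill <- abs(assoc$pos[rest] - assoc$pos[i]) <= cfg$window_bp
    if (!is.null(genotypes) && any(!kill)) {
      chk <- rest[!kill]
      r <- suppressWarnings(
        cor(genotypes[, gi[i]], genotypes[, gi[chk], drop = FALSE],
            use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      r2[is.na(r2)] <- 0
      kill[!kill] <- r2 >= cfg$r2_threshold
    }
    alive[rest_pos[kill]] <- FALSE
  }
  out <- cbind(locus = seq_along(leads), assoc[leads, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- class(assoc)
  out
}
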