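# Plain-text cohort persistence: phenotype TSV, SNP table TSV, genotype
# matrix as whitespace-separated allele counts (one row per individual,
# header row of SNP ids), and the scenario configuration as JSON.

#' Write / read a full cohort directory
#'
#' Writes `pheno.tsv`, `snps.tsv`, `genotypes.txt` and `config.json` under
#' `dir`. The genotype file is a whitespace-separated 0/1/2 matrix with a
#' header row of SNP ids -- deliberately a plain-text format so cohorts are
#' inspectable and diffable.
#'
#' @param cohort An `mlc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` an
#'   `mlc_cohort` (true effect vectors and causal sets restored from
#'   `snps.tsv`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mlc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pheno_tsv(cohort, file.path(dir, "pheno.tsv"))
  snp <- cohort$snp
  snp$true_beta_y <- cohort$true_beta_y
  snp$true_gamma_d <- cohort$true_gamma_d
  snp$causal_y <- seq_len(nrow(snp)) %in% cohort$causal_idx_y
  snp$causal_d <- seq_len(nrow(snp)) %in% cohort$causal_idx_d
  write.table(snp, file.path(dir, "snps.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- cohort$genotypes
  con <- file(file.path(dir, "genotypes.txt"), "w")
  writeLines(paste(colnames(g), collapse = " "), con)
  write.table(g, con, col.names = FALSE, row.names = FALSE, quote = FALSE)
  close(con)
  cfg <- cohort$config
  jsonlite::write_json(unclass_deep(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pheno <- read_pheno_tsv(file.path(dir, "pheno.tsv"))
  snp <- read.delim(file.path(dir, "snps.tsv"), stringsAsFactors = FALSE)
  g <- as.matrix(read.table(file.path(dir, "genotypes.txt"), header = TRUE,
                            check.names = FALSE))
  storage.mode(g) <- "integer"
  attr(g, "position") <- snp$position
  attr(g, "maf") <- snp$maf
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- scenario_config(cfgl$scenario, n = cfgl$n, m = cfgl$m,
                         n_causal_y = cfgl$n_causal_y,
                         n_causal_d = cfgl$n_causal_d,
                         h2_y = cfgl$h2_y, h2_d = cfgl$h2_d,
                         b_yd = cfgl$b_yd, prevalence = cfgl$prevalence,
                         maf_range = cfgl$maf_range,
                         ld = cfgl$ld, seed = cfgl$seed)
  cohort <- list(
    genotypes = g,
    snp = snp[, c("id", "position", "maf")],
    id = pheno$id, sex = pheno$sex, age = pheno$age,
    true_y = pheno$true_y, reported_y = pheno$reported_y,
    liability_d = pheno$liability_d, disease = pheno$disease,
    change_group = pheno$change_group, reason = pheno$reason,
    underreported = !is.na(pheno$reported_y) & pheno$reported_y == 0 &
      pheno$true_y != 0,
    nonresponse = is.na(pheno$reported_y),
    causal_idx_y = which(snp$causal_y),
    causal_idx_d = which(snp$causal_d),
    true_beta_y = snp$true_beta_y,
    true_gamma_d = snp$true_gamma_d,
    config = cfg)
  class(cohort) <- "mlc_cohort"
  cohort
}
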