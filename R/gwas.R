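# Per-SNP linear association baseline: vectorized closed-form simple OLS of
# the adjusted phenotype on each dosage column, with a two-sided t-test.

#' Per-SNP linear regression scan
#'
#' For each SNP fits y ~ intercept + g by ordinary least squares and reports
#' the slope, the two-sided p-value of the slope t-test, and the importance
#' score -log10(p). p-values are computed on the log scale, so importance does
#' not overflow for extreme associations. Monomorphic SNPs get slope NA,
#' p = 1, importance 0, and are flagged.
#'
#' @param G A `genotype_matrix` or plain dosage matrix (samples x SNPs).
#' @param y Adjusted phenotype vector (no further covariates are used).
#' @return `data.frame` with columns `snp_id`, `beta`, `p`, `neglog10p`,
#'   `monomorphic`.
#' @export
gwas_scan <- function(G, y) {
  X <- if (inherits(G, "genotype_matrix")) G$dosages else G
  n <- nrow(X)
  if (length(y) != n) ab_config_error("phenotype length mismatch")
  if (n < 3) ab_config_error("need at least 3 samples for the t-test")
  yc <- y - mean(y)
  gbar <- colMeans(X)
  sxx <- colSums(X^2) - n * gbar^2
  sxy <- as.numeric(crossprod(X, yc))
  syy <- sum(yc^2)
  mono <- sxx <= 0
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  rss <- pmax(syy - ifelse(mono, 0, beta^2 * sxx), 0)
  se <- sqrt(rss / (n - 2) / ifelse(mono, 1, sxx))
  tstat <- ifelse(mono, 0, ifelse(se == 0, Inf, beta / se))
  logp <- log(2) + stats::pt(-abs(tstat), df = n - 2, log.p = TRUE)
  neglog10p <- ifelse(mono, 0, -logp / log(10))
  # exact fits (se == 0) would give infinite importance; cap beyond any
  # attainable finite score so ranking stays well defined
  neglog10p <- pmin(neglog10p, 350)
  ids <- colnames(X) %||% sprintf("SNP_%06d", seq_len(ncol(X)))
  data.frame(
    snp_id = ids, beta = beta,
    p = ifelse(mono, 1, exp(logp)),
    neglog10p = neglog10p,
    monomorphic = mono,
    row.names = NULL
  )
}

#' Write a GWAS result table as TSV
#'
#' Column naming follows the association-tool convention
#' (ID, BETA, P, NEG_LOG10_P).
#'
#' @param res Result of [gwas_scan()].
#' @param path Output file path.
#' @export
write_gwas_tsv <- function(res, path) {
  out <- data.frame(ID = res$snp_id, BETA = res$beta, P = res$p,
                    NEG_LOG10_P = res$neglog10p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
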