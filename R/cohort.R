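# Synthetic cohort generation: genotypes under HWE, age/sex covariates, a
# polygenic phenotype with nuisance effects, covariate adjustment, and
# sex-stratified data splits.

#' Generate a base genotype matrix under Hardy-Weinberg equilibrium
#'
#' SNPs are independent and biallelic; each SNP draws a minor-allele frequency
#' p uniformly from `maf_range` and genotypes are sampled i.i.d. with HWE class
#' probabilities ((1-p)^2, 2p(1-p), p^2), i.e. dosage ~ Binomial(2, p). There
#' is no linkage disequilibrium: the simulator targets the same independence
#' assumptions as the spike-in machinery.
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_snps Number of SNPs (>= 1).
#' @param maf_range Length-2 interval inside (0, 0.5] for the per-SNP MAF.
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @return An object of class `genotype_matrix`: list with integer matrix
#'   `dosages` (n_samples x n_snps, entries 0/1/2), `snp_ids`, `maf`,
#'   `sample_ids`.
#' @export
generate_base_genotypes <- function(n_samples, n_snps,
                                    maf_range = c(0.05, 0.5), seed = 1L) {
  if (n_samples < 2 || n_snps < 1) {
    ab_config_error("need n_samples >= 2 and n_snps >= 1")
  }
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    ab_config_error("maf_range must be an interval inside (0, 0.5]")
  }
  with_seed(seed, {
    p <- stats::runif(n_snps, maf_range[1], maf_range[2])
    dos <- matrix(
      stats::rbinom(n_samples * n_snps, 2L, rep(p, each = n_samples)),
      nrow = n_samples, ncol = n_snps
    )
    storage.mode(dos) <- "integer"
    snp_ids <- sprintf("SNP_%06d", seq_len(n_snps))
    sample_ids <- sprintf("S%06d", seq_len(n_samples))
    dimnames(dos) <- list(sample_ids, snp_ids)
    structure(
      list(dosages = dos, snp_ids = snp_ids, maf = p, sample_ids = sample_ids),
      class = "genotype_matrix"
    )
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs, MAF in [%.3f, %.3f]\n",
              nrow(x$dosages), ncol(x$dosages), min(x$maf), max(x$maf)))
  invisible(x)
}

#' Generate an age/sex covariate table
#'
#' Ages are uniform over `age_range` (default 40-69 years, the recruitment
#' window typical of adult biobank cohorts); sex is Bernoulli(`sex_prob`)
#' coded 0 = female, 1 = male.
#'
#' @param n_samples Number of samples.
#' @param age_range Length-2 numeric range of ages in years.
#' @param sex_prob Probability of sex code 1.
#' @param seed Integer seed.
#' @return `data.frame` with columns `sample_id`, `age`, `sex`.
#' @export
generate_covariates <- function(n_samples, age_range = c(40, 69),
                                sex_prob = 0.5, seed = 1L) {
  with_seed(seed, {
    age <- stats::runif(n_samples, age_range[1], age_range[2])
    sex <- stats::rbinom(n_samples, 1L, sex_prob)
    if (n_samples >= 2 && length(unique(sex)) == 1L) {
      # both sexes must be present for stratification; flip one sample
      sex[1] <- 1L - sex[1]
    }
    data.frame(
      sample_id = sprintf("S%06d", seq_len(n_samples)),
      age = age, sex = as.integer(sex)
    )
  })
}

#' Generate a raw polygenic phenotype with nuisance effects
#'
#' The phenotype is an additive polygenic signal plus Gaussian noise plus
#' age/sex nuisance terms:
#' raw = genetic + e + age_effect * age + sex_effect * sex,
#' where genetic is a weighted sum of `n_background` randomly chosen SNP
#' dosages (Gaussian weights), rescaled so that the genetic component explains
#' exactly fraction `h2` of the variance of (genetic + e) in this cohort.
#'
#' @param G A `genotype_matrix`.
#' @param cov Covariate table from [generate_covariates()].
#' @param n_background Number of causal background SNPs (<= n_snps).
#' @param h2 Heritability of the covariate-free component, in [0, 1).
#' @param age_effect,sex_effect Nuisance effect sizes (phenotype units per
#'   year / per sex code).
#' @param seed Integer seed.
#' @return Object of class `phenotype`: list with `raw`, `adjusted` (NULL
#'   until [adjust_phenotype()]), `causal_idx`, `h2`.
#' @export
generate_phenotype <- function(G, cov, n_background = 200, h2 = 0.5,
                               age_effect = -0.01, sex_effect = 1.3,
                               seed = 1L) {
  if (h2 < 0 || h2 >= 1) ab_config_error("h2 must be in [0, 1)")
  m <- ncol(G$dosages)
  if (n_background > m) ab_config_error("n_background exceeds n_snps")
  n <- nrow(G$dosages)
  with_seed(seed, {
    noise <- stats::rnorm(n)
    if (h2 > 0 && n_background > 0) {
      causal_idx <- sort(sample.int(m, n_background))
      w <- stats::rnorm(n_background)
      gen <- as.numeric(G$dosages[, causal_idx, drop = FALSE] %*% w)
      gen <- gen - mean(gen)
      sdg <- stats::sd(gen)
      if (sdg == 0) ab_generation_error("degenerate genetic component")
      gen <- gen * sqrt(h2) / sdg
      noise <- noise * sqrt(1 - h2)
    } else {
      causal_idx <- integer(0)
      gen <- numeric(n)
    }
    raw <- gen + noise + age_effect * cov$age + sex_effect * cov$sex
    structure(
      list(raw = raw, adjusted = NULL, causal_idx = causal_idx, h2 = h2,
           genetic = gen, noise = noise),
      class = "phenotype"
    )
  })
}

#' Adjust a phenotype for age and sex and z-score it
#'
#' Fits raw ~ intercept + age + sex by OLS on the samples in `fit_mask`
#' (normally the training split), applies the fitted coefficients to all
#' samples, and z-scores the residuals using the fit-mask mean and standard
#' deviation. Fitting on the training split only avoids leaking validation or
#' test information into the labels.
#'
#' @param pheno A `phenotype` object (uses `$raw`).
#' @param cov Covariate table aligned with the phenotype.
#' @param fit_mask Logical or integer index of samples used for fitting;
#'   defaults to all samples.
#' @return The `phenotype` with `$adjusted` filled in; attributes
#'   `coef`, `center`, `scale` record the fitted transformation.
#' @export
adjust_phenotype <- function(pheno, cov, fit_mask = NULL) {
  raw <- pheno$raw
  n <- length(raw)
  if (is.null(fit_mask)) fit_mask <- seq_len(n)
  if (is.logical(fit_mask)) fit_mask <- which(fit_mask)
  if (length(fit_mask) == 0) ab_config_error("fit_mask is empty")
  X <- cbind(1, cov$age, cov$sex)
  if (any(!is.finite(X))) ab_config_error("covariates must be finite")
  Xf <- X[fit_mask, , drop = FALSE]
  qrf <- qr(Xf)
  if (qrf$rank < ncol(Xf)) {
    ab_stop("degenerate covariate design (constant age and single sex)",
            "ab_singular_fit_error")
  }
  beta <- qr.coef(qrf, raw[fit_mask])
  resid <- raw - as.numeric(X %*% beta)
  ctr <- mean(resid[fit_mask])
  scl <- stats::sd(resid[fit_mask])
  # residual variance at numerical-noise level means the covariates explain
  # the phenotype exactly: z-scoring would amplify rounding error
  if (scl < sqrt(.Machine$double.eps) * max(stats::sd(raw[fit_mask]), 1)) {
    ab_stop("residuals have (numerically) zero variance on fit_mask",
            "ab_singular_fit_error")
  }
  pheno$adjusted <- (resid - ctr) / scl
  attr(pheno, "coef") <- beta
  attr(pheno, "center") <- ctr
  attr(pheno, "scale") <- scl
  pheno
}

#' Sex-stratified train/validation/test split
#'
#' Within each sex, samples are randomly permuted and allocated to splits by
#' largest-remainder rounding of the target fractions, so sex proportions in
#' every split match the cohort to within one sample per stratum.
#'
#' @param cov Covariate table (uses `$sex`).
#' @param fractions Named or positional numeric triple (train, validation,
#'   test); must sum to 1.
#' @param seed Integer seed.
#' @return Character vector of split labels (`"train"`, `"validation"`,
#'   `"test"`), one per sample, with attribute `fractions`.
#' @export
stratified_split <- function(cov, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions < 0)) {
    ab_config_error("fractions must be three non-negative values summing to 1")
  }
  labels <- c("train", "validation", "test")
  out <- character(nrow(cov))
  with_seed(seed, {
    for (s in unique(cov$sex)) {
      idx <- which(cov$sex == s)
      idx <- idx[sample.int(length(idx))]
      ns <- length(idx)
      exact <- fractions * ns
      base <- floor(exact)
      rem <- exact - base
      short <- ns - sum(base)
      if (short > 0) {
        top_up <- order(rem, decreasing = TRUE)[seq_len(short)]
        base[top_up] <- base[top_up] + 1
      }
      assign_lab <- rep(labels, times = base)
      out[idx] <- assign_lab
    }
  })
  attr(out, "fractions") <- fractions
  out
}
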