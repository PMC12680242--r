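test_that("generated genotypes live in {0,1,2} and respect HWE", {
  # degenerate MAF interval, tiny cohort: domain membership
  G <- generate_base_genotypes(4, 1, maf_range = c(0.5, 0.5), seed = 3)
  expect_true(all(G$dosages %in% 0:2))

  # HWE class frequencies within 4 SE of ((1-p)^2, 2p(1-p), p^2)
  n <- 50000
  for (p in c(0.05, 0.2, 0.45)) {
    G <- generate_base_genotypes(n, 3, maf_range = c(p, p), seed = 7)
    probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    for (j in 1:3) {
      counts <- tabulate(G$dosages[, j] + 1L, 3L)
      se <- sqrt(probs * (1 - probs) / n)
      expect_true(all(abs(counts / n - probs) < 4 * se),
                  label = sprintf("HWE at p=%.2f", p))
    }
  }
})

test_that("mean dosage matches 2p within binomial sampling error", {
  n <- 200000; p <- 0.1
  G <- generate_base_genotypes(n, 1, maf_range = c(p, p), seed = 11)
  se <- sqrt(2 * p * (1 - p) / n)
  expect_lt(abs(mean(G$dosages) - 2 * p), 3 * se)
})

test_that("genotype generation is deterministic and validates maf_range", {
  a <- generate_base_genotypes(100, 20, seed = 5)
  b <- generate_base_genotypes(100, 20, seed = 5)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$maf, b$maf)
  expect_error(generate_base_genotypes(10, 2, maf_range = c(0, 0.6)),
               class = "ab_config_error")
  expect_error(generate_base_genotypes(1, 2), class = "ab_config_error")
})

test_that("phenotype generator respects h2", {
  G <- generate_base_genotypes(2000, 50, seed = 21)
  cov <- generate_covariates(2000, seed = 22)

  # null heritability: independent of every causal candidate
  ph0 <- generate_phenotype(G, cov, n_background = 20, h2 = 0, seed = 23)
  rs <- abs(apply(G$dosages[, 1:20], 2, safe_cor, b = ph0$raw))
  expect_true(all(rs < 4 / sqrt(2000) + 0.02))
  expect_identical(ph0$genetic, numeric(2000))

  # variance decomposition on the simulated components at larger n
  G2 <- generate_base_genotypes(50000, 60, seed = 24)
  cov2 <- generate_covariates(50000, seed = 25)
  ph <- generate_phenotype(G2, cov2, n_background = 40, h2 = 0.5, seed = 26)
  frac <- var(ph$genetic) / (var(ph$genetic) + var(ph$noise))
  expect_lt(abs(frac - 0.5), 0.05)

  expect_error(generate_phenotype(G, cov, h2 = 1), class = "ab_config_error")
  expect_error(generate_phenotype(G, cov, n_background = 100),
               class = "ab_config_error")
})

test_that("phenotype adjustment is an OLS residual z-score", {
  cc <- tiny_cohort(n = 2000, m = 30, seed = 31)
  fit <- cc$split == "train"
  y <- cc$pheno$adjusted
  # mean 0, variance 1 on the fitting cohort
  expect_lt(abs(mean(y[fit])), 1e-8)
  expect_lt(abs(var(y[fit]) - 1), 1e-6)

  # raw exactly orthogonal to the design: adjustment is just centering/scaling
  cov <- generate_covariates(500, seed = 32)
  raw <- with_seed(33, rnorm(500))
  raw <- unname(resid(lm(raw ~ cov$age + cov$sex)))
  ph <- structure(list(raw = raw), class = "phenotype")
  adj <- adjust_phenotype(ph, cov)
  expect_equal(cor(adj$adjusted, scale(raw)[, 1]), 1, tolerance = 1e-6)

  # (near-)perfect fit: residual vector vanishes before scaling
  ph2 <- structure(list(raw = 3 * cov$age + 1e-6 * with_seed(34, rnorm(500))),
                   class = "phenotype")
  adj2 <- adjust_phenotype(ph2, cov)
  expect_lt(attr(adj2, "scale"), 1e-5)

  # exactly-zero residual variance is a degenerate fit
  ph3 <- structure(list(raw = 3 * cov$age), class = "phenotype")
  expect_error(adjust_phenotype(ph3, cov), class = "ab_singular_fit_error")

  # degenerate design: constant age, single sex
  cov_bad <- data.frame(sample_id = sprintf("S%d", 1:50),
                        age = rep(50, 50), sex = rep(1L, 50))
  ph4 <- structure(list(raw = rnorm(50)), class = "phenotype")
  expect_error(adjust_phenotype(ph4, cov_bad),
               class = "ab_singular_fit_error")
})

test_that("adjusted phenotype is orthogonal to covariates at scale", {
  n <- 50000
  G <- generate_base_genotypes(n, 10, seed = 41)
  cov <- generate_covariates(n, seed = 42)
  ph <- generate_phenotype(G, cov, n_background = 10, h2 = 0.3,
                           age_effect = -0.02, sex_effect = 1.3, seed = 43)
  adj <- adjust_phenotype(ph, cov)
  expect_lt(abs(cor(adj$adjusted, cov$age)), 0.01)
  expect_lt(abs(cor(adj$adjusted, cov$sex)), 0.01)
})

test_that("adjustment is idempotent", {
  cc <- tiny_cohort(n = 800, m = 20, seed = 51)
  again <- structure(list(raw = cc$pheno$adjusted), class = "phenotype")
  fit <- cc$split == "train"
  re <- adjust_phenotype(again, cc$cov, fit_mask = fit)
  expect_lt(max(abs(re$adjusted - cc$pheno$adjusted)), 1e-6)
})

test_that("stratified split conserves samples and sex proportions", {
  cov <- generate_covariates(1000, seed = 61)
  sp <- stratified_split(cov, seed = 62)
  expect_setequal(unique(sp), c("train", "validation", "test"))
  expect_equal(length(sp), 1000)
  expect_equal(sum(table(sp)), 1000)
  # sex proportions within 1 percentage point of the cohort's in each split
  overall <- mean(cov$sex)
  for (s in unique(sp)) {
    expect_lt(abs(mean(cov$sex[sp == s]) - overall), 0.01 + 1e-9)
  }
  # per-sex train counts: 80% of each stratum up to rounding
  for (sx in 0:1) {
    n_sx <- sum(cov$sex == sx)
    expect_lte(abs(sum(sp == "train" & cov$sex == sx) - 0.8 * n_sx), 1)
  }

  # conservation property across random fractions and seeds
  with_seed(63, {
    for (rep in 1:5) {
      f <- as.numeric(rmultinom(1, 20, c(1, 1, 1))) / 20
      sp2 <- stratified_split(cov, fractions = f, seed = rep)
      expect_equal(length(sp2), nrow(cov))
      expect_equal(unname(sum(table(sp2))), nrow(cov))
    }
  })

  # degenerate fractions
  sp3 <- stratified_split(cov, fractions = c(1, 0, 0), seed = 64)
  expect_true(all(sp3 == "train"))
  expect_error(stratified_split(cov, fractions = c(0.5, 0.2, 0.2)),
               class = "ab_config_error")

  # different seeds: different assignment, same marginal counts
  a <- stratified_split(cov, seed = 65)
  b <- stratified_split(cov, seed = 66)
  expect_false(identical(a, b))
  expect_equal(as.vector(table(a)), as.vector(table(b)))
})
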