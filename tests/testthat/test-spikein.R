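test_that("latent sampler hits its target correlation", {
  n <- 240000
  y <- std_pheno(n, seed = 1)

  # rho = 0: independence up to sampling noise
  z0 <- sample_latent(y, 0, seed = 2)
  expect_lt(abs(cor(z0, y)), 3 / sqrt(n))

  # boundary rejected
  expect_error(sample_latent(y, 1, seed = 2), class = "ab_domain_error")
  expect_error(sample_latent(y, -1.2, seed = 2), class = "ab_domain_error")

  # realized correlation within Fisher-z sampling error of the target
  z <- sample_latent(y, 0.05, seed = 3)
  expect_lt(abs(cor(z, y) - 0.05), 3 / sqrt(n))
})

test_that("HWE discretization yields exact class counts from ranks", {
  with_seed(11, {
    z <- rnorm(10000)
    g <- discretize_hwe(z, 0.1)
    expect_equal(tabulate(g + 1L, 3L), c(8100, 1800, 100))

    # symmetric HWE at p = 0.5
    g5 <- discretize_hwe(z, 0.5)
    expect_equal(tabulate(g5 + 1L, 3L), c(2500, 5000, 2500))

    # counts depend only on ranks
    gs <- discretize_hwe(sample(z), 0.1)
    expect_equal(tabulate(gs + 1L, 3L), tabulate(g + 1L, 3L))
  })
  expect_error(discretize_hwe(rep(1, 100), 0.1), class = "ab_degenerate_error")
  expect_error(discretize_hwe(rnorm(100), 0.6), class = "ab_config_error")
})

test_that("additive spike-ins have monotone, sign-consistent class means", {
  n <- 60000
  y <- std_pheno(n, seed = 21)

  r <- gen_additive(y, 0.07, 0.2, seed = 22)
  d <- r$diagnostics
  expect_gt(d$realized_r, 0)
  expect_true(d$m0 < d$m1 && d$m1 < d$m2)
  # latent correlation recovers the target within 3 SE; hard-call r attenuates
  expect_lt(abs(d$latent_r - 0.07), 3 / sqrt(n))
  expect_lt(d$realized_r, d$latent_r)

  # negative sign flips the pattern
  rn <- gen_additive(y, -0.07, 0.2, seed = 23)
  expect_true(rn$diagnostics$m0 > rn$diagnostics$m2)
  expect_lt(rn$diagnostics$realized_r, 0)

  # null effect: class means equal within noise
  r0 <- gen_additive(y, 0, 0.2, seed = 24)
  d0 <- r0$diagnostics
  expect_lt(abs(d0$m2 - d0$m0), 5 * sqrt(1 / d0$n0 + 1 / d0$n2))
})

test_that("dominant spike-ins satisfy the carrier constraint and pattern", {
  n <- 100000
  y <- std_pheno(n, seed = 31)

  # carrier-fraction arithmetic: p(2-p)
  r <- gen_dominant(y, 0.05, 0.06, seed = 32)
  expect_equal(r$diagnostics$carrier_fraction, 0.06 * (2 - 0.06),
               tolerance = 1e-3)
  expect_true(r$diagnostics$carrier_fraction >= 0.10 &&
                r$diagnostics$carrier_fraction <= 0.14)

  # infeasible MAF rejected up front
  expect_error(gen_dominant(y, 0.05, 0.2, seed = 33),
               class = "ab_config_error")

  # strong effect: m1 ~ m2 > m0, strictly flatter within carriers
  rs <- gen_dominant(y, 0.25, 0.06, seed = 34)
  d <- rs$diagnostics
  expect_true(d$m1 > d$m0 && d$m2 > d$m0)
  expect_lt(abs(d$m1 - d$m2), abs(d$m1 - d$m0))

  # null effect: all three class means equal within noise
  r0 <- gen_dominant(y, 0, 0.06, seed = 35)
  d0 <- r0$diagnostics
  expect_lt(abs(d0$m1 - d0$m0), 5 * sqrt(1 / d0$n0 + 1 / d0$n1))
})

test_that("recessive spike-ins enforce the hom-alt floor and pattern", {
  n <- 100000
  y <- std_pheno(n, seed = 41)

  # boundary MAF accepted (expected count exactly 1200 per 240k)
  r <- gen_recessive(y, 0.05, sqrt(1200 / 240000), seed = 42)
  expect_s3_class(data.frame(r$diagnostics), "data.frame")

  # below the floor: rejected with the feasibility message
  expect_error(gen_recessive(y, 0.05, 0.05, seed = 43),
               class = "ab_config_error")

  # strong effect: m0 ~ m1 < m2
  rs <- gen_recessive(y, 0.25, 0.15, seed = 44)
  d <- rs$diagnostics
  expect_true(d$m2 > d$m0 && d$m2 > d$m1)
  expect_lt(abs(d$m0 - d$m1), abs(d$m2 - d$m1))

  # null effect
  r0 <- gen_recessive(y, 0, 0.15, seed = 45)
  d0 <- r0$diagnostics
  expect_lt(abs(d0$m2 - d0$m1), 5 * sqrt(1 / d0$n1 + 1 / d0$n2))
})

test_that("epistatic pairs couple the interaction, not the marginals", {
  n <- 60000
  y <- std_pheno(n, seed = 51)

  p <- gen_epistatic_pair(y, 0.05, 0.10, 0.15, seed = 52)
  d <- p$diagnostics
  # line search reached the target within tolerance
  expect_lt(abs(d$r_H - 0.05), 0.005 + 1e-9)
  # marginals below the scale-aware cap
  cap <- max(0.01, 4 / sqrt(n))
  expect_lt(max(abs(d$r_marginal_A), abs(d$r_marginal_B)), cap)
  # genotype columns are valid HWE variants
  expect_equal(tabulate(p$gA + 1L, 3L), hwe_counts(n, 0.10))
  expect_equal(tabulate(p$gB + 1L, 3L), hwe_counts(n, 0.15))

  # near-zero target: alpha stays near zero and H is uncorrelated
  p0 <- gen_epistatic_pair(y, 0.001, 0.10, 0.15, seed = 53, tol = 0.005)
  expect_lt(abs(p0$diagnostics$r_H), 0.01)

  # negative target supported
  pn <- gen_epistatic_pair(y, -0.05, 0.10, 0.15, seed = 54)
  expect_lt(pn$diagnostics$r_H, -0.04)
})

test_that("build_spikein_set assembles the requested architecture mix", {
  n <- 20000
  y <- std_pheno(n, seed = 61)
  counts <- c(additive = 6, dominant = 6, recessive = 6, epistatic = 6)
  ss <- build_spikein_set(y, counts = counts, rho_range = c(0.1, 0.3),
                          epi_rho_range = c(0.05, 0.15), seed = 62)
  expect_equal(ncol(ss$dosages), 24)
  expect_equal(unname(table(ss$type)[c("additive", "dominant", "recessive",
                                       "epistatic")]),
               c(6L, 6L, 6L, 6L), ignore_attr = TRUE)
  expect_equal(length(unique(ss$diagnostics$pair_id[ss$type == "epistatic"])), 3)

  # every column satisfies HWE class counts exactly (quantile construction)
  for (j in seq_len(ncol(ss$dosages))) {
    pj <- ss$diagnostics$maf[j]
    expect_equal(tabulate(ss$dosages[, j] + 1L, 3L), hwe_counts(n, pj))
  }
  # targets inside the configured magnitude ranges
  epi <- ss$type == "epistatic"
  expect_true(all(abs(ss$diagnostics$target_rho[!epi]) >= 0.1 &
                    abs(ss$diagnostics$target_rho[!epi]) <= 0.3))
  expect_true(all(abs(ss$diagnostics$target_rho[epi]) >= 0.05 &
                    abs(ss$diagnostics$target_rho[epi]) <= 0.15))
  # dominant carrier fractions inside the constraint window
  dom <- ss$diagnostics$type == "dominant"
  expect_true(all(ss$diagnostics$carrier_fraction[dom] >= 0.10 &
                    ss$diagnostics$carrier_fraction[dom] <= 0.14))
  # recessive MAFs at or above the scaled feasibility floor
  rec <- ss$diagnostics$type == "recessive"
  expect_true(all(ss$diagnostics$maf[rec] >= sqrt(1200 / 240000) - 1e-12))

  # determinism: identical seed, identical set
  ss2 <- build_spikein_set(y, counts = counts, rho_range = c(0.1, 0.3),
                           epi_rho_range = c(0.05, 0.15), seed = 62)
  expect_identical(ss$dosages, ss2$dosages)
  expect_identical(ss$diagnostics, ss2$diagnostics)

  # single-type request
  s1 <- build_spikein_set(y, counts = c(additive = 1, dominant = 0,
                                        recessive = 0, epistatic = 0),
                          rho_range = c(0.1, 0.3), seed = 63)
  expect_equal(ncol(s1$dosages), 1)
  expect_equal(s1$type, "additive")

  # odd epistatic count rejected
  expect_error(
    build_spikein_set(y, counts = c(additive = 0, dominant = 0,
                                    recessive = 0, epistatic = 3), seed = 64),
    class = "ab_config_error"
  )
})
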