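# Spike-in SNP simulation: phenotype-correlated synthetic variants with
# additive, dominant, recessive, and epistatic architectures, generated under
# exact Hardy-Weinberg class counts via rank thresholding of a latent Gaussian.

#' Sample a phenotype-correlated latent Gaussian
#'
#' Constructs z = rho * y + sqrt(1 - rho^2) * e with e i.i.d. standard normal,
#' so that the population correlation of z with the standardized phenotype y
#' equals rho exactly.
#'
#' @param y Standardized phenotype vector (mean ~ 0, variance ~ 1).
#' @param rho Target correlation, |rho| < 1.
#' @param seed Optional integer seed; if NULL the ambient RNG stream is used.
#' @return Numeric vector z of the same length as `y`.
#' @export
sample_latent <- function(y, rho, seed = NULL) {
  if (abs(rho) >= 1) ab_stop("|rho| must be < 1", "ab_domain_error")
  draw <- function() rho * y + sqrt(1 - rho^2) * stats::rnorm(length(y))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Integer HWE class counts (g = 0, 1, 2) for n samples at MAF p.
hwe_counts <- function(n, p) {
  c0 <- round(n * (1 - p)^2)
  c2 <- round(n * p^2)
  c1 <- n - c0 - c2
  if (c1 < 0) { # pathological rounding at tiny n
    c1 <- 0L
    c0 <- n - c2
  }
  c(c0, c1, c2)
}

#' Discretize a latent variable into HWE hard-call genotypes
#'
#' Ranks of z are thresholded so that the lowest (1-p)^2 fraction becomes
#' g = 0, the highest p^2 fraction becomes g = 2, and the remainder g = 1.
#' Class counts therefore match Hardy-Weinberg expectations exactly up to
#' integer rounding, and depend only on the ranks of z.
#'
#' @param z Latent numeric vector (must not be constant).
#' @param p Minor-allele frequency in (0, 0.5].
#' @return Integer genotype vector with entries in 0/1/2.
#' @export
discretize_hwe <- function(z, p) {
  if (p <= 0 || p > 0.5) ab_config_error("MAF p must be in (0, 0.5]")
  if (max(z) == min(z)) ab_stop("constant latent vector", "ab_degenerate_error")
  n <- length(z)
  cnt <- hwe_counts(n, p)
  r <- rank(z, ties.method = "first")
  g <- integer(n)
  g[r > cnt[1]] <- 1L
  g[r > n - cnt[3]] <- 2L
  g
}

# Per-genotype-class phenotype means and counts.
class_means <- function(g, y) {
  m <- rep(NA_real_, 3)
  nn <- integer(3)
  for (k in 0:2) {
    idx <- g == k
    nn[k + 1] <- sum(idx)
    if (nn[k + 1] > 0) m[k + 1] <- mean(y[idx])
  }
  list(m = m, n = nn)
}

# Standard error guard: a mean-difference check is only enforceable when the
# class counts make it detectable; tolerance scales as 5 standard errors.
se_sum <- function(counts) sqrt(sum(1 / pmax(counts, 1)))

spike_column <- function(g, y, type, rho, p, extra = list()) {
  cm <- class_means(g, y)
  c(list(
    type = type, target_rho = rho, maf = p,
    realized_r = safe_cor(g, y),
    m0 = cm$m[1], m1 = cm$m[2], m2 = cm$m[3],
    n0 = cm$n[1], n1 = cm$n[2], n2 = cm$n[3],
    carrier_fraction = (cm$n[2] + cm$n[3]) / length(g)
  ), extra)
}

#' Generate an additive spike-in SNP
#'
#' The latent z = rho*y + sqrt(1-rho^2)*e is HWE-discretized; the genotype
#' inherits an approximately linear genotype-phenotype relationship. A
#' diagnostic keep-rule requires the heterozygote mean to sit near the
#' midpoint of the homozygote means (within max(half the homozygote span,
#' 5 SE)) and the homozygote ordering to match the sign of rho whenever the
#' effect is statistically detectable; failing draws are retried with fresh
#' seeds up to `max_retries`.
#'
#' @param y Standardized phenotype vector.
#' @param rho Signed target latent correlation.
#' @param p MAF in (0, 0.5].
#' @param seed Integer seed.
#' @param max_retries Regeneration attempts before failing.
#' @return List with integer vector `g` and list `diagnostics`.
#' @export
gen_additive <- function(y, rho, p, seed = 1L, max_retries = 5L) {
  last <- NULL
  for (attempt in seq_len(max_retries)) {
    z <- sample_latent(y, rho, derive_seed(seed, attempt))
    g <- discretize_hwe(z, p)
    d <- spike_column(g, y, "additive", rho, p,
                      extra = list(latent_r = safe_cor(z, y)))
    span <- d$m2 - d$m0
    mid_dev <- abs(d$m1 - (d$m0 + d$m2) / 2)
    se_mid <- sqrt(1 / max(d$n1, 1) + 0.25 / max(d$n0, 1) + 0.25 / max(d$n2, 1))
    detectable <- abs(span) >= 4 * se_sum(c(d$n0, d$n2))
    ok_sign <- !detectable || rho == 0 || sign(span) == sign(rho)
    ok_mid <- mid_dev < max(0.5 * abs(span), 5 * se_mid)
    last <- list(g = g, diagnostics = d)
    if (ok_sign && ok_mid) return(last)
  }
  ab_generation_error("additive spike-in failed linearity check after retries",
                      data = last$diagnostics)
}

#' Generate a dominant spike-in SNP
#'
#' Carrier status (g > 0) is assigned by thresholding a y-correlated latent at
#' the HWE carrier-count quantile; carriers are then split into g = 1 versus
#' g = 2 at the conditional HWE ratio 2(1-p):p *independently of y*, which
#' enforces equal heterozygote and homozygote-alternate phenotype means in
#' expectation (the dominant pattern m1 = m2 != m0).
#'
#' @inheritParams gen_additive
#' @param carrier_range Feasible carrier-fraction interval; p(2-p) must fall
#'   inside it or a spec error is raised.
#' @export
gen_dominant <- function(y, rho, p, seed = 1L, carrier_range = c(0.10, 0.14),
                         max_retries = 5L) {
  cf <- p * (2 - p)
  if (cf < carrier_range[1] || cf > carrier_range[2]) {
    ab_config_error(sprintf(
      "dominant MAF %.4f gives carrier fraction %.4f outside [%.2f, %.2f]",
      p, cf, carrier_range[1], carrier_range[2]))
  }
  n <- length(y)
  cnt <- hwe_counts(n, p)
  last <- NULL
  for (attempt in seq_len(max_retries)) {
    s <- derive_seed(seed, attempt)
    g <- with_seed(s, {
      z <- sample_latent(y, rho)
      carriers <- rank(z, ties.method = "first") > cnt[1]
      gg <- as.integer(carriers)
      hom <- sample(which(carriers), cnt[3])
      gg[hom] <- 2L
      gg
    })
    d <- spike_column(g, y, "dominant", rho, p)
    mc <- mean(y[g > 0])
    eff <- mc - d$m0
    se12 <- se_sum(c(d$n1, d$n2))
    detectable <- abs(eff) >= 4 * se_sum(c(d$n0, d$n1 + d$n2))
    ok_sign <- !detectable || rho == 0 || sign(eff) == sign(rho)
    ok_flat <- abs(d$m1 - d$m2) < max(abs(d$m1 - d$m0), 5 * se12)
    last <- list(g = g, diagnostics = d)
    if (ok_sign && ok_flat) return(last)
  }
  ab_generation_error("dominant spike-in failed pattern check after retries",
                      data = last$diagnostics)
}

#' Generate a recessive spike-in SNP
#'
#' Homozygous-alternate status (g = 2) is assigned by thresholding a
#' y-correlated latent at the p^2 quantile; the remaining samples are split
#' into g = 0 versus g = 1 at the conditional HWE ratio (1-p):2p independently
#' of y, enforcing m0 = m1 != m2 in expectation. The expected
#' homozygous-alternate count n*p^2 must reach `min_homalt` scaled by
#' n/`ref_n` (equivalently p >= sqrt(min_homalt/ref_n)), or a spec error
#' listing the feasible MAF floor is raised.
#'
#' @inheritParams gen_additive
#' @param min_homalt Minimum expected homozygous-alternate count at the
#'   reference cohort size.
#' @param ref_n Reference cohort size at which `min_homalt` applies verbatim.
#' @export
gen_recessive <- function(y, rho, p, seed = 1L, min_homalt = 1200,
                          ref_n = 240000, max_retries = 5L) {
  p_floor <- sqrt(min_homalt / ref_n)
  if (p < p_floor) {
    ab_config_error(sprintf(
      "recessive MAF %.4f infeasible: expected hom-alt count %.0f per %d samples < %d (MAF floor %.4f)",
      p, length(y) * p^2 * ref_n / length(y), ref_n, min_homalt, p_floor))
  }
  n <- length(y)
  cnt <- hwe_counts(n, p)
  last <- NULL
  for (attempt in seq_len(max_retries)) {
    s <- derive_seed(seed, attempt)
    g <- with_seed(s, {
      z <- sample_latent(y, rho)
      gg <- integer(n)
      homalt <- rank(z, ties.method = "first") > n - cnt[3]
      gg[homalt] <- 2L
      het <- sample(which(!homalt), cnt[2])
      gg[het] <- 1L
      gg
    })
    d <- spike_column(g, y, "recessive", rho, p)
    eff <- d$m2 - mean(y[g < 2])
    se01 <- se_sum(c(d$n0, d$n1))
    detectable <- abs(eff) >= 4 * se_sum(c(d$n0 + d$n1, d$n2))
    ok_sign <- !detectable || rho == 0 || sign(eff) == sign(rho)
    ok_flat <- abs(d$m0 - d$m1) < max(abs(d$m2 - d$m1), 5 * se01)
    last <- list(g = g, diagnostics = d)
    if (ok_sign && ok_flat) return(last)
  }
  ab_generation_error("recessive spike-in failed pattern check after retries",
                      data = last$diagnostics)
}

#' Generate an epistatic spike-in pair
#'
#' The first SNP gA is a null HWE variant. The second SNP's latent is an
#' alpha-blend of a term coupled to the product of the centered, standardized
#' gA and the phenotype: zB = alpha * cA * y + sqrt(1 - alpha^2) * e with
#' cA = (gA - 2 pA)/sd(gA). Centering gA (rather than taking its sign) keeps
#' the marginal correlation of gB with y at zero in expectation while making
#' the interaction correlation corr(H, y), H = (gA - 2pA)(gB - 2pB), increase
#' monotonically in alpha — which is what permits the bisection line search
#' over alpha in [0, `alpha_max`]. After the search, both marginal
#' correlations are checked against `marginal_cap`; the pair is regenerated
#' with a fresh seed on failure.
#'
#' @inheritParams gen_additive
#' @param rho_epi Signed target correlation of the interaction term with y.
#' @param pA,pB MAFs of the two SNPs.
#' @param alpha_max Upper bound of the dependency parameter (default 0.95).
#' @param tol Line-search tolerance on |corr(H, y) - rho_epi| (default 0.005).
#' @param max_iter Maximum bisection iterations (default 40).
#' @param marginal_cap Cap on |corr(g, y)| for each marginal; default
#'   max(0.01, 4/sqrt(n)) so the verbatim 0.01 cap applies at biobank scale
#'   while desk-scale runs use a sampling-noise-aware cap.
#' @return List with integer vectors `gA`, `gB` and list `diagnostics`
#'   (realized alpha, corr(H, y), both marginals).
#' @export
gen_epistatic_pair <- function(y, rho_epi, pA, pB, seed = 1L,
                               alpha_max = 0.95, tol = 0.005, max_iter = 40L,
                               marginal_cap = NULL, max_retries = 5L) {
  n <- length(y)
  if (is.null(marginal_cap)) marginal_cap <- max(0.01, 4 / sqrt(n))
  target <- abs(rho_epi)
  sgn <- if (rho_epi < 0) -1 else 1
  best <- NULL
  for (attempt in seq_len(max_retries)) {
    res <- with_seed(derive_seed(seed, attempt), {
      gA <- discretize_hwe(stats::rnorm(n), pA)
      cA <- (gA - 2 * pA) / stats::sd(gA)
      e <- stats::rnorm(n)
      coupled <- sgn * cA * y
      hcorr <- function(alpha) {
        zB <- alpha * coupled + sqrt(max(0, 1 - alpha^2)) * e
        gB <- discretize_hwe(zB, pB)
        H <- (gA - 2 * pA) * (gB - 2 * pB)
        list(gB = gB, r = safe_cor(H, y) * sgn) # r on the |target| scale
      }
      lo <- 0; hi <- alpha_max
      at_hi <- hcorr(hi)
      if (at_hi$r < target - tol) {
        return(list(ok = FALSE, best_r = sgn * at_hi$r, gA = gA,
                    gB = at_hi$gB, alpha = hi))
      }
      cur <- hcorr(lo)
      alpha <- lo
      for (it in seq_len(max_iter)) {
        if (abs(cur$r - target) <= tol) break
        mid <- (lo + hi) / 2
        cand <- hcorr(mid)
        if (cand$r < target) lo <- mid else hi <- mid
        cur <- cand
        alpha <- mid
      }
      list(ok = abs(cur$r - target) <= tol, gA = gA, gB = cur$gB,
           alpha = alpha, best_r = sgn * cur$r)
    })
    if (!res$ok) {
      best <- res
      next
    }
    rA <- safe_cor(res$gA, y)
    rB <- safe_cor(res$gB, y)
    if (max(abs(rA), abs(rB)) < marginal_cap) {
      return(list(
        gA = res$gA, gB = res$gB,
        diagnostics = list(
          type = "epistatic", target_rho = rho_epi, pA = pA, pB = pB,
          alpha = res$alpha, r_H = res$best_r,
          r_marginal_A = rA, r_marginal_B = rB
        )
      ))
    }
    best <- res
  }
  ab_generation_error(sprintf(
    "epistatic pair failed after %d attempts (best corr(H, y) = %.4f, target %.4f)",
    max_retries, best$best_r, rho_epi),
    data = best[c("alpha", "best_r")])
}

#' Build a full spike-in set
#'
#' Draws per-SNP specifications (correlation magnitudes uniform in `rho_range`
#' with random signs; MAFs uniform in effect-type-specific feasible
#' sub-ranges) and generates all spike-in columns against the standardized
#' phenotype `y`. Defaults mirror the benchmark's stated world: 100 SNPs per
#' effect type (epistatic as 50 pairs), |rho| in [0.018, 0.070], MAF in
#' [0.05, 0.20], dominant carrier fraction in [0.10, 0.14], and expected
#' recessive homozygous-alternate counts of at least 1200 per 240,000 samples.
#'
#' @param y Standardized phenotype vector.
#' @param counts Named integer vector of SNP counts per effect type
#'   (`additive`, `dominant`, `recessive`, `epistatic`); the epistatic count
#'   must be even (pairs).
#' @param rho_range Magnitude range for target correlations.
#' @param epi_rho_range Magnitude range for epistatic interaction targets;
#'   defaults to `rho_range`.
#' @param maf_range MAF sampling range.
#' @param carrier_range Dominant carrier-fraction constraint.
#' @param min_homalt,ref_n Recessive feasibility rule, see [gen_recessive()].
#' @param marginal_cap Epistatic marginal cap, see [gen_epistatic_pair()].
#' @param seed Integer seed; the set is byte-identical across reruns.
#' @return Object of class `spikein_set`: integer matrix `dosages`
#'   (n x total), `diagnostics` data.frame (one row per SNP), `type` vector,
#'   and the generating configuration.
#' @export
build_spikein_set <- function(y,
                              counts = c(additive = 100, dominant = 100,
                                         recessive = 100, epistatic = 100),
                              rho_range = c(0.018, 0.070),
                              epi_rho_range = NULL,
                              maf_range = c(0.05, 0.20),
                              carrier_range = c(0.10, 0.14),
                              min_homalt = 1200, ref_n = 240000,
                              marginal_cap = NULL, seed = 1L) {
  counts <- counts[c("additive", "dominant", "recessive", "epistatic")]
  counts[is.na(counts)] <- 0
  names(counts) <- c("additive", "dominant", "recessive", "epistatic")
  if (counts["epistatic"] %% 2 != 0) {
    ab_config_error("epistatic count must be even (generated in pairs)")
  }
  epi_rho_range <- epi_rho_range %||% rho_range
  n <- length(y)

  # Carrier-fraction feasibility pins dominant MAFs to a narrow band; when the
  # requested maf_range does not intersect it, the carrier constraint (the hard
  # one) wins and dominant MAFs are drawn from the feasible band directly.
  feas <- c(1 - sqrt(1 - carrier_range[1]), 1 - sqrt(1 - carrier_range[2]))
  dom_range <- c(max(maf_range[1], feas[1]), min(maf_range[2], feas[2]))
  if (dom_range[1] > dom_range[2]) dom_range <- feas
  rec_range <- c(max(maf_range[1], sqrt(min_homalt / ref_n)), maf_range[2])
  if (rec_range[1] > rec_range[2] && counts["recessive"] > 0) {
    ab_config_error("no feasible recessive MAF range for the hom-alt constraint")
  }

  total <- sum(counts)
  specs <- with_seed(derive_seed(seed, 0), {
    runi <- function(k, rng) stats::runif(k, rng[1], rng[2])
    sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
    list(
      add_rho = runi(counts[1], rho_range) * sgn(counts[1]),
      add_p   = runi(counts[1], maf_range),
      dom_rho = runi(counts[2], rho_range) * sgn(counts[2]),
      dom_p   = runi(counts[2], dom_range),
      rec_rho = runi(counts[3], rho_range) * sgn(counts[3]),
      rec_p   = runi(counts[3], rec_range),
      epi_rho = runi(counts[4] / 2, epi_rho_range) * sgn(counts[4] / 2),
      epi_pA  = runi(counts[4] / 2, maf_range),
      epi_pB  = runi(counts[4] / 2, maf_range)
    )
  })

  dos <- matrix(0L, nrow = n, ncol = total)
  diag_rows <- vector("list", total)
  ids <- character(total)
  types <- character(total)
  col <- 0L
  add_col <- function(g, id, type, drow) {
    col <<- col + 1L
    dos[, col] <<- g
    ids[col] <<- id
    types[col] <<- type
    diag_rows[[col]] <<- drow
  }
  as_row <- function(d, id, pair_id = NA_character_) {
    data.frame(
      snp_id = id, type = d$type, target_rho = d$target_rho,
      maf = d$maf %||% NA_real_, realized_r = d$realized_r %||% NA_real_,
      latent_r = d$latent_r %||% NA_real_,
      m0 = d$m0 %||% NA_real_, m1 = d$m1 %||% NA_real_, m2 = d$m2 %||% NA_real_,
      carrier_fraction = d$carrier_fraction %||% NA_real_,
      alpha = d$alpha %||% NA_real_, r_H = d$r_H %||% NA_real_,
      pair_id = pair_id, stringsAsFactors = FALSE
    )
  }

  for (i in seq_len(counts[1])) {
    r <- gen_additive(y, specs$add_rho[i], specs$add_p[i],
                      seed = derive_seed(seed, 1000 + i))
    add_col(r$g, sprintf("SPIKE_ADD_%03d", i), "additive",
            as_row(r$diagnostics, sprintf("SPIKE_ADD_%03d", i)))
  }
  for (i in seq_len(counts[2])) {
    r <- gen_dominant(y, specs$dom_rho[i], specs$dom_p[i],
                      seed = derive_seed(seed, 2000 + i),
                      carrier_range = carrier_range)
    add_col(r$g, sprintf("SPIKE_DOM_%03d", i), "dominant",
            as_row(r$diagnostics, sprintf("SPIKE_DOM_%03d", i)))
  }
  for (i in seq_len(counts[3])) {
    r <- gen_recessive(y, specs$rec_rho[i], specs$rec_p[i],
                       seed = derive_seed(seed, 3000 + i),
                       min_homalt = min_homalt, ref_n = ref_n)
    add_col(r$g, sprintf("SPIKE_REC_%03d", i), "recessive",
            as_row(r$diagnostics, sprintf("SPIKE_REC_%03d", i)))
  }
  for (i in seq_len(counts[4] / 2)) {
    r <- gen_epistatic_pair(y, specs$epi_rho[i], specs$epi_pA[i],
                            specs$epi_pB[i],
                            seed = derive_seed(seed, 4000 + i),
                            marginal_cap = marginal_cap)
    pid <- sprintf("PAIR_%03d", i)
    dA <- r$diagnostics; dB <- r$diagnostics
    dA$maf <- r$diagnostics$pA; dA$realized_r <- r$diagnostics$r_marginal_A
    dB$maf <- r$diagnostics$pB; dB$realized_r <- r$diagnostics$r_marginal_B
    add_col(r$gA, sprintf("SPIKE_EPI_%03dA", i), "epistatic",
            as_row(dA, sprintf("SPIKE_EPI_%03dA", i), pid))
    add_col(r$gB, sprintf("SPIKE_EPI_%03dB", i), "epistatic",
            as_row(dB, sprintf("SPIKE_EPI_%03dB", i), pid))
  }

  colnames(dos) <- ids
  structure(
    list(
      dosages = dos,
      diagnostics = do.call(rbind, diag_rows),
      type = types,
      counts = counts, rho_range = rho_range, epi_rho_range = epi_rho_range,
      maf_range = maf_range, seed = seed
    ),
    class = "spikein_set"
  )
}

#' @export
print.spikein_set <- function(x, ...) {
  cat(sprintf("<spikein_set> %d spike-in SNPs (%s) over %d samples\n",
              ncol(x$dosages),
              paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
              nrow(x$dosages)))
  invisible(x)
}

#' @export
as.data.frame.spikein_set <- function(x, ...) x$diagnostics
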