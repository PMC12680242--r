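# Benchmark metrics: top-K selection, recall by effect type, micro-averaged
# recall, decoy precision, ensemble consistency (RSD/MAD), the half-life
# stability transform, and the composite score.

#' Select the top-K features by importance
#'
#' K = floor(q * number of features). Ties are broken by descending score
#' then ascending feature index (stable), so K membership is deterministic.
#'
#' @param S Importance vector.
#' @param q Quantile in (0, 1].
#' @return List with `K`, `q`, and integer vector `members`.
#' @export
topk_select <- function(S, q) {
  if (q <= 0 || q > 1) ab_config_error("q must be in (0, 1]")
  K <- floor(q * length(S))
  ord <- order(-S, seq_along(S))
  list(K = K, q = q, members = ord[seq_len(K)])
}

#' Attribution recall per effect type
#'
#' For each effect type, the fraction of its spike-in features found inside
#' the top-K of the combined ranking.
#'
#' @param sel Result of [topk_select()] over the combined feature ranking.
#' @param spike_idx Named list mapping effect type to the feature indices of
#'   its spike-ins.
#' @return Named numeric vector of recalls (NA for empty effect classes).
#' @export
recall_by_effect <- function(sel, spike_idx) {
  vapply(spike_idx, function(idx) {
    if (length(idx) == 0) return(NA_real_)
    mean(idx %in% sel$members)
  }, numeric(1))
}

#' Micro-averaged recall
#'
#' Total spike-ins recovered across effect types divided by the total number
#' of spike-ins: sum(recall_t * n_t) / sum(n_t).
#'
#' @param recalls Named per-effect recall vector.
#' @param sizes Per-effect class sizes (same order/names).
#' @return Scalar micro-average.
#' @export
micro_recall <- function(recalls, sizes) {
  keep <- !is.na(recalls)
  sum(recalls[keep] * sizes[keep]) / sum(sizes[keep])
}

#' Attribution precision at top K
#'
#' Over the combined real+decoy ranking: 1 - (#decoys in top K) / (#real in
#' top K). Undefined (NA with a warning) when no real feature is in the top K.
#'
#' @param sel Result of [topk_select()] over the expanded feature ranking.
#' @param labels Character vector `"real"`/`"decoy"` per feature.
#' @return Scalar precision (<= 1; negative when decoys dominate).
#' @export
precision_at_k <- function(sel, labels) {
  lab <- labels[sel$members]
  n_real <- sum(lab == "real")
  n_decoy <- sum(lab == "decoy")
  if (n_real == 0) {
    warning("no real features in top K; precision undefined")
    return(NA_real_)
  }
  1 - n_decoy / n_real
}

#' Normal-consistency MAD scaling constant
#'
#' 1 / qnorm(0.75) = 1.4826...: the factor making the median absolute
#' deviation comparable to a standard deviation under normality.
#'
#' @return Scalar constant.
#' @export
mad_scale_constant <- function() 1 / stats::qnorm(0.75)

#' Ensemble attribution consistency
#'
#' Per-SNP relative standard deviation RSD_j = sigma_j / mu_j of importance
#' scores across M independently trained models (sample standard deviation),
#' summarized by the median RSD and the scaled MAD
#' (1.4826 * median |RSD_j - median RSD|). SNPs with mu_j = 0 are excluded
#' from the summaries and counted.
#'
#' @param scores M x n_snps matrix (one row per ensemble member) or list of
#'   importance vectors.
#' @return List with `rsd` (per-SNP, NA where excluded), `median_rsd`,
#'   `mad_scaled`, `n_excluded`.
#' @export
ensemble_consistency <- function(scores) {
  if (is.list(scores)) scores <- do.call(rbind, scores)
  if (nrow(scores) < 2) ab_config_error("consistency requires M >= 2 members")
  mu <- colMeans(scores)
  sigma <- apply(scores, 2, stats::sd)
  rsd <- ifelse(mu == 0, NA_real_, sigma / mu)
  ok <- !is.na(rsd)
  med <- stats::median(rsd[ok])
  list(
    rsd = rsd,
    median_rsd = med,
    mad_scaled = mad_scale_constant() * stats::median(abs(rsd[ok] - med)),
    n_excluded = sum(!ok)
  )
}

#' Half-life stability transform
#'
#' S = 2^(-x / tau): maps a lower-is-better variability score x (median RSD)
#' to a stability score in (0, 1], halving with every increment of the
#' half-life constant tau.
#'
#' @param x Variability score (median RSD).
#' @param tau Half-life constant (> 0); by convention the median of the
#'   median-RSDs across all benchmarked method variants.
#' @return Stability in (0, 1] (1 at x = 0, 0.5 at x = tau).
#' @export
half_life_transform <- function(x, tau) {
  if (any(tau <= 0)) ab_config_error("tau must be positive")
  2^(-x / tau)
}

#' Composite interpretability score
#'
#' Geometric mean of top-1% micro recall, top-1% precision, and half-life
#' transformed consistency.
#'
#' @param recall,precision,stability Components in [0, 1].
#' @return Scalar composite score.
#' @export
composite_score <- function(recall, precision, stability) {
  comp <- c(recall, precision, stability)
  if (any(is.na(comp))) return(NA_real_)
  if (any(comp < 0)) ab_config_error("composite components must be >= 0")
  if (any(comp == 0)) return(0)
  exp(mean(log(comp)))
}
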