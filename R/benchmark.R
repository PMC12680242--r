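# End-to-end benchmark orchestration: configuration profiles, the three
# benchmark drivers (recall, precision, consistency), and the composite
# report. Every random draw descends from the master seed through
# derive_seed(), so a report is a pure function of its configuration.

#' Benchmark run configuration
#'
#' Two named profiles materialize the full parameter set:
#' * `"paper"` — the biobank-scale recipe (hidden 1000/200/50, dropout 0.5,
#'   lr 1e-6, 100 epochs, M = 10, 100 spike-ins per effect with |rho| in
#'   [0.018, 0.070] and MAF in [0.05, 0.20]). Not runnable on a desktop; kept
#'   as the reference stated world.
#' * `"desk"` — a reduced profile for laptop-scale runs and CI (n = 2000,
#'   1000 base SNPs, 10 spike-ins per effect, hidden 64/32/16, dropout 0.2,
#'   lr 1e-3, 30 epochs, M = 5). Spike-in correlations are inflated to
#'   [0.35, 0.55] (epistatic targets [0.10, 0.20]) and spike MAFs floored at
#'   0.10 so that ground-truth variants are unambiguously learnable from
#'   n = 2000; all spike-in feasibility constraints scale with cohort size.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param seed Master seed for the whole run.
#' @param ... Named overrides of any configuration field.
#' @return Object of class `bench_config`.
#' @export
bench_config <- function(profile = c("desk", "paper"), seed = 1L, ...) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile, seed = as.integer(seed),
    fractions = c(0.8, 0.1, 0.1),
    base_maf_range = c(0.05, 0.5),
    n_background = 200, h2 = 0.5, age_effect = -0.01, sex_effect = 1.3,
    carrier_range = c(0.10, 0.14), min_homalt = 1200, ref_n = 240000,
    chunk_size = 10000L,
    weight_decay = 1e-3, l2_factor = 1e-3, batch_size = 128L,
    methods = c("saliency", "gradient_shap", "deeplift",
                "integrated_gradients"),
    smoothing = c(FALSE, TRUE),
    attr_params = list(),
    thresholds = c(0.01, 0.02, 0.03, 0.05, 0.10, 0.20)
  )
  prof <- if (profile == "desk") {
    list(n_samples = 2000L, n_snps = 1000L,
         spike_counts = c(additive = 10, dominant = 10,
                          recessive = 10, epistatic = 10),
         rho_range = c(0.35, 0.55), epi_rho_range = c(0.10, 0.20),
         spike_maf_range = c(0.10, 0.20),
         hidden = c(64L, 32L, 16L), dropout = 0.2,
         lr = 1e-3, epochs = 30L, ensemble_m = 5L)
  } else {
    list(n_samples = 240000L, n_snps = 553000L,
         spike_counts = c(additive = 100, dominant = 100,
                          recessive = 100, epistatic = 100),
         rho_range = c(0.018, 0.070), epi_rho_range = NULL,
         spike_maf_range = c(0.05, 0.20),
         hidden = c(1000L, 200L, 50L), dropout = 0.5,
         lr = 1e-6, epochs = 100L, ensemble_m = 10L)
  }
  cfg <- utils::modifyList(c(base, prof), list(...))
  bad <- cfg$thresholds[cfg$thresholds <= 0 | cfg$thresholds > 1]
  if (length(bad) || is.unsorted(cfg$thresholds)) {
    ab_config_error("thresholds must be ascending values in (0, 1]")
  }
  structure(cfg, class = "bench_config")
}

# Build the shared synthetic cohort for a run: genotypes, covariates,
# adjusted phenotype (fit on the training split), split labels, spike-ins.
build_cohort <- function(cfg) {
  sd0 <- cfg$seed
  G <- generate_base_genotypes(cfg$n_samples, cfg$n_snps,
                               maf_range = cfg$base_maf_range,
                               seed = derive_seed(sd0, 1))
  cov <- generate_covariates(cfg$n_samples, seed = derive_seed(sd0, 2))
  pheno <- generate_phenotype(G, cov, n_background = cfg$n_background,
                              h2 = cfg$h2, age_effect = cfg$age_effect,
                              sex_effect = cfg$sex_effect,
                              seed = derive_seed(sd0, 3))
  split <- stratified_split(cov, cfg$fractions, seed = derive_seed(sd0, 4))
  pheno <- adjust_phenotype(pheno, cov, fit_mask = split == "train")
  spikes <- build_spikein_set(
    pheno$adjusted, counts = cfg$spike_counts,
    rho_range = cfg$rho_range, epi_rho_range = cfg$epi_rho_range,
    maf_range = cfg$spike_maf_range, carrier_range = cfg$carrier_range,
    min_homalt = cfg$min_homalt, ref_n = cfg$ref_n,
    seed = derive_seed(sd0, 5)
  )
  list(G = G, cov = cov, pheno = pheno, y = pheno$adjusted,
       split = split, spikes = spikes)
}

bench_spec_cfg <- function(cfg, input_dim, shuffle_seed) {
  list(
    spec = network_spec(input_dim, hidden = cfg$hidden,
                        dropout = cfg$dropout),
    train = train_config(lr = cfg$lr, weight_decay = cfg$weight_decay,
                         l2_factor = cfg$l2_factor,
                         batch_size = cfg$batch_size, epochs = cfg$epochs,
                         shuffle_seed = shuffle_seed)
  )
}

variant_key <- function(method, smoothed) {
  paste0(method, if (smoothed) ".smoothed" else ".raw")
}

log_stage <- function(stage, t0, extra = "") {
  message(sprintf("[attribench] %-22s %6.1fs %s", stage,
                  as.numeric(Sys.time() - t0, units = "secs"), extra))
}

#' Run the attribution recall benchmark
#'
#' Builds the cohort and spike-ins, trains one network on base + spike-in
#' features, attributes the held-out test split with every configured method
#' variant, and computes per-effect recall at each threshold. A per-SNP
#' linear-regression scan of the training split over the same features
#' provides the linear baseline row.
#'
#' @param cfg A [bench_config()].
#' @param data Optional prebuilt cohort (internal reuse by [run_all()]).
#' @return List with `recall` (long-format data.frame), `importances`
#'   (variant -> importance vector), `val_r`, `spike_idx`.
#' @export
run_recall_benchmark <- function(cfg, data = NULL) {
  t0 <- Sys.time()
  if (is.null(data)) data <- build_cohort(cfg)
  X <- cbind(data$G$dosages, data$spikes$dosages)
  storage.mode(X) <- "double"
  y <- data$y
  tr <- data$split == "train"; va <- data$split == "validation"
  te <- data$split == "test"
  nets <- bench_spec_cfg(cfg, ncol(X), derive_seed(cfg$seed, 6))
  model <- train_model(X[tr, , drop = FALSE], y[tr],
                       X[va, , drop = FALSE], y[va],
                       nets$spec, nets$train)
  log_stage("recall: train", t0, sprintf("val_r=%.3f", model$best_val_r))
  baseline <- mode_baseline(X[tr, , drop = FALSE])
  train_sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  attrs <- attribute_model(model, X[te, , drop = FALSE], baseline, train_sd,
                           methods = cfg$methods, smoothing = cfg$smoothing,
                           seed = derive_seed(cfg$seed, 10),
                           params = cfg$attr_params)
  importances <- lapply(attrs, aggregate_attributions)
  gwas <- gwas_scan(X[tr, , drop = FALSE], y[tr])
  importances[["gwas.raw"]] <- stats::setNames(gwas$neglog10p, gwas$snp_id)
  log_stage("recall: attribution", t0)

  m_base <- ncol(data$G$dosages)
  types <- data$spikes$type
  spike_idx <- split(m_base + seq_along(types), types)
  spike_idx <- spike_idx[intersect(c("additive", "dominant", "recessive",
                                     "epistatic"), names(spike_idx))]
  sizes <- vapply(spike_idx, length, integer(1))
  rows <- list()
  for (key in names(importances)) {
    S <- importances[[key]]
    meth <- sub("\\.(raw|smoothed)$", "", key)
    sm <- grepl("\\.smoothed$", key)
    for (q in cfg$thresholds) {
      sel <- topk_select(S, q)
      rec <- recall_by_effect(sel, spike_idx)
      rows[[length(rows) + 1]] <- data.frame(
        algorithm = meth, smoothing = sm, threshold = q, K = sel$K,
        t(rec), micro = micro_recall(rec, sizes),
        stringsAsFactors = FALSE
      )
    }
  }
  log_stage("recall: metrics", t0)
  list(recall = do.call(rbind, rows), importances = importances,
       val_r = model$best_val_r, spike_idx = spike_idx, sizes = sizes)
}

#' Run the attribution precision benchmark
#'
#' Expands each split's feature matrix with permutation decoys (doubling the
#' feature count), trains the doubled-input network, attributes the expanded
#' test split, and computes decoy precision at each threshold.
#'
#' @inheritParams run_recall_benchmark
#' @return List with `precision` (long-format data.frame), `val_r`.
#' @export
run_precision_benchmark <- function(cfg, data = NULL) {
  t0 <- Sys.time()
  if (is.null(data)) data <- build_cohort(cfg)
  Xr <- cbind(data$G$dosages, data$spikes$dosages)
  storage.mode(Xr) <- "double"
  y <- data$y
  dcfg <- decoy_config(decoy_seed = derive_seed(cfg$seed, 7),
                       chunk_size = cfg$chunk_size)
  parts <- list()
  for (s in c("train", "validation", "test")) {
    idx <- data$split == s
    parts[[s]] <- expand_features(Xr[idx, , drop = FALSE], dcfg, s)
  }
  labels <- parts$train$labels
  nets <- bench_spec_cfg(cfg, ncol(parts$train$features),
                         derive_seed(cfg$seed, 8))
  model <- train_model(parts$train$features, y[data$split == "train"],
                       parts$validation$features,
                       y[data$split == "validation"],
                       nets$spec, nets$train)
  log_stage("precision: train", t0, sprintf("val_r=%.3f", model$best_val_r))
  baseline <- mode_baseline(parts$train$features)
  train_sd <- apply(parts$train$features, 2, stats::sd)
  attrs <- attribute_model(model, parts$test$features, baseline, train_sd,
                           methods = cfg$methods, smoothing = cfg$smoothing,
                           seed = derive_seed(cfg$seed, 10),
                           params = cfg$attr_params)
  log_stage("precision: attribution", t0)
  rows <- list()
  for (key in names(attrs)) {
    S <- aggregate_attributions(attrs[[key]])
    meth <- sub("\\.(raw|smoothed)$", "", key)
    sm <- grepl("\\.smoothed$", key)
    for (q in cfg$thresholds) {
      sel <- topk_select(S, q)
      rows[[length(rows) + 1]] <- data.frame(
        algorithm = meth, smoothing = sm, threshold = q, K = sel$K,
        precision = precision_at_k(sel, labels), stringsAsFactors = FALSE
      )
    }
  }
  list(precision = do.call(rbind, rows), val_r = model$best_val_r)
}

#' Run the ensemble consistency benchmark
#'
#' Trains an ensemble of M models on the real (base) features only, attributes
#' the test split with each member, and summarizes per-SNP attribution RSDs
#' per method variant.
#'
#' @inheritParams run_recall_benchmark
#' @return List with `consistency` (data.frame: median RSD, scaled MAD,
#'   excluded count per variant), `val_r` (vector over members).
#' @export
run_consistency_benchmark <- function(cfg, data = NULL) {
  t0 <- Sys.time()
  if (is.null(data)) data <- build_cohort(cfg)
  X <- data$G$dosages
  storage.mode(X) <- "double"
  y <- data$y
  tr <- data$split == "train"; va <- data$split == "validation"
  te <- data$split == "test"
  nets <- bench_spec_cfg(cfg, ncol(X), derive_seed(cfg$seed, 9))
  models <- train_ensemble(X[tr, , drop = FALSE], y[tr],
                           X[va, , drop = FALSE], y[va],
                           nets$spec, nets$train,
                           n_members = cfg$ensemble_m)
  log_stage("consistency: ensemble", t0,
            sprintf("val_r=%s",
                    paste(sprintf("%.2f", vapply(models, `[[`, 0, "best_val_r")),
                          collapse = ",")))
  baseline <- mode_baseline(X[tr, , drop = FALSE])
  train_sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  member_scores <- lapply(models, function(mod) {
    attrs <- attribute_model(mod, X[te, , drop = FALSE], baseline, train_sd,
                             methods = cfg$methods, smoothing = cfg$smoothing,
                             seed = derive_seed(cfg$seed, 10),
                             params = cfg$attr_params)
    lapply(attrs, aggregate_attributions)
  })
  log_stage("consistency: attribution", t0)
  keys <- names(member_scores[[1]])
  rows <- lapply(keys, function(key) {
    mat <- do.call(rbind, lapply(member_scores, `[[`, key))
    st <- ensemble_consistency(mat)
    data.frame(
      algorithm = sub("\\.(raw|smoothed)$", "", key),
      smoothing = grepl("\\.smoothed$", key),
      median_rsd = st$median_rsd, mad_scaled = st$mad_scaled,
      n_excluded = st$n_excluded, stringsAsFactors = FALSE
    )
  })
  list(consistency = do.call(rbind, rows),
       val_r = vapply(models, `[[`, 0, "best_val_r"))
}

#' Run the full benchmark and assemble the composite report
#'
#' Executes the recall, precision, and consistency benchmarks on a shared
#' synthetic cohort (three separate trained models/ensembles), computes the
#' half-life constant tau as the median of the method-variant median RSDs,
#' and combines top-1% micro recall, top-1% precision, and transformed
#' consistency into the composite table.
#'
#' @param cfg A [bench_config()].
#' @return Object of class `benchmark_report` with elements `recall`,
#'   `precision`, `consistency`, `composite`, `tau`, `manifest`.
#' @export
run_all <- function(cfg) {
  t0 <- Sys.time()
  data <- build_cohort(cfg)
  log_stage("cohort", t0)
  rec <- run_recall_benchmark(cfg, data)
  prec <- run_precision_benchmark(cfg, data)
  cons <- run_consistency_benchmark(cfg, data)
  tau <- stats::median(cons$consistency$median_rsd)
  q1 <- min(cfg$thresholds)
  comp <- lapply(seq_len(nrow(cons$consistency)), function(i) {
    alg <- cons$consistency$algorithm[i]
    sm <- cons$consistency$smoothing[i]
    r <- rec$recall[rec$recall$algorithm == alg &
                      rec$recall$smoothing == sm &
                      rec$recall$threshold == q1, ]
    p <- prec$precision[prec$precision$algorithm == alg &
                          prec$precision$smoothing == sm &
                          prec$precision$threshold == q1, ]
    stab <- half_life_transform(cons$consistency$median_rsd[i], tau)
    # a failed cell (e.g. negative decoy precision at a loose threshold) is
    # flagged as NA rather than aborting the report
    comp_val <- tryCatch(composite_score(r$micro, p$precision, stab),
                         ab_error = function(e) NA_real_)
    data.frame(
      algorithm = alg, smoothing = sm,
      recall_top = r$micro, precision_top = p$precision,
      consistency = stab,
      composite = comp_val,
      stringsAsFactors = FALSE
    )
  })
  manifest <- list(
    config = unclass(cfg),
    composite_threshold = q1,
    val_r = list(recall = rec$val_r, precision = prec$val_r,
                 consistency = cons$val_r),
    spike_diagnostics = data$spikes$diagnostics
  )
  log_stage("composite", t0)
  structure(
    list(recall = rec$recall, precision = prec$precision,
         consistency = cons$consistency,
         composite = do.call(rbind, comp), tau = tau, manifest = manifest),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\n")
  cat(sprintf("  tau (half-life constant): %.5f\n", x$tau))
  cat("  composite (threshold ", x$manifest$composite_threshold, "):\n", sep = "")
  print(x$composite, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a benchmark report
#'
#' Writes the four tables as TSV plus a single JSON document (tables and
#' manifest). The JSON serialization is deterministic, so identical
#' configurations produce byte-identical reports.
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("recall", "precision", "consistency", "composite")) {
    utils::write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(report_json(report), file.path(dir, "report.json"))
  invisible(dir)
}

#' Deterministic JSON form of a report
#'
#' @param report A `benchmark_report`.
#' @return A single JSON string.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(
    list(recall = report$recall, precision = report$precision,
         consistency = report$consistency, composite = report$composite,
         tau = report$tau, manifest = report$manifest),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  ))
}
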