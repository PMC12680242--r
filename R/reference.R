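# Reference biobank-scale benchmark tables shipped with the package, and the
# composite arithmetic chain that recomputes the composite table from the
# recall, precision, and consistency tables.
#
# The reference values come from a published biobank-scale run of this
# benchmark design (standing-height regression on ~240k participants and
# ~550k variants); they serve as printed inputs for validating the metric
# arithmetic, not as quantities this package can regenerate at desk scale.

#' Load a shipped reference benchmark table
#'
#' @param which One of `"recall"`, `"precision"`, `"consistency"`,
#'   `"composite"`.
#' @return A `data.frame` of the reference table.
#' @export
reference_table <- function(which = c("recall", "precision", "consistency",
                                      "composite")) {
  which <- match.arg(which)
  path <- system.file("extdata", "reference",
                      paste0(which, "_biobank.tsv"), package = "attribench")
  if (path == "") ab_stop("reference table not found", "ab_io_error")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Recompute the composite table from reference inputs
#'
#' Runs the full composite arithmetic chain on the shipped reference tables:
#' micro-averages the top-1% per-effect recalls (100 spike-ins per effect
#' class), takes the top-1% precisions, sets the half-life constant tau to the
#' median of the method-variant median RSDs, applies the half-life transform,
#' and combines the three components by geometric mean.
#'
#' @param class_sizes Spike-in count per effect class (default 100 each).
#' @return `data.frame` with one row per method variant: the computed
#'   `recall_top1`, `precision_top1`, `consistency`, `composite`, plus `tau`.
#' @export
composite_from_reference <- function(class_sizes = c(additive = 100,
                                                     dominant = 100,
                                                     recessive = 100,
                                                     epistatic = 100)) {
  rec <- reference_table("recall")
  prec <- reference_table("precision")
  cons <- reference_table("consistency")
  rec1 <- rec[rec$top_pct == 1 & rec$algorithm != "gwas", ]
  tau <- stats::median(cons$median_rsd)
  out <- lapply(seq_len(nrow(cons)), function(i) {
    alg <- cons$algorithm[i]
    sm <- cons$smoothing[i]
    r <- rec1[rec1$algorithm == alg & rec1$smoothing == sm, ]
    p <- prec[prec$algorithm == alg & prec$smoothing == sm, ]
    recalls <- c(additive = r$additive, dominant = r$dominant,
                 recessive = r$recessive, epistatic = r$epistatic)
    mr <- micro_recall(recalls, class_sizes)
    stab <- half_life_transform(cons$median_rsd[i], tau)
    data.frame(
      algorithm = alg, smoothing = sm,
      recall_top1 = mr, precision_top1 = p$top1,
      consistency = stab,
      composite = composite_score(mr, p$top1, stab),
      tau = tau, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
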