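# Permutation decoy features: null copies of real genotype columns produced by
# deterministic within-chunk sample-index permutation. Decoys preserve every
# per-SNP genotype multiset (hence allele frequencies) and within-chunk
# structure while destroying genotype-phenotype correspondence.

#' Decoy generation configuration
#'
#' The permutation for a chunk is seeded by
#' `decoy_seed + split_offsets[split] + chunk_idx`, which makes decoys a pure
#' function of (data, seed, split, chunk index): reproducible across epochs
#' within a split, independent across splits. Split offsets are large and
#' pairwise distinct so seeds never collide across chunk indices.
#'
#' @param decoy_seed Integer base seed.
#' @param split_offsets Named integer vector mapping split to offset.
#' @param chunk_size SNP columns per chunk; one row permutation is shared by
#'   all columns of a chunk, which preserves within-chunk linkage structure.
#' @return Object of class `decoy_config`.
#' @export
decoy_config <- function(decoy_seed = 1L,
                         split_offsets = c(train = 0L,
                                           validation = 1000003L,
                                           test = 2000003L),
                         chunk_size = 10000L) {
  if (chunk_size < 1) ab_config_error("chunk_size must be >= 1")
  if (anyDuplicated(split_offsets)) {
    ab_config_error("split_offsets must be pairwise distinct")
  }
  structure(list(decoy_seed = as.integer(decoy_seed),
                 split_offsets = split_offsets,
                 chunk_size = as.integer(chunk_size)),
            class = "decoy_config")
}

#' Permute one genotype chunk into its decoy
#'
#' Applies a single seeded permutation of row (sample) indices to every SNP
#' column of the chunk. Per-SNP genotype counts are exactly preserved.
#'
#' @param chunk Genotype sub-matrix (samples x SNPs).
#' @param split Split label, one of `names(cfg$split_offsets)`.
#' @param chunk_idx Integer chunk index (0-based or 1-based, as long as it is
#'   used consistently).
#' @param cfg A [decoy_config()].
#' @return The decoy sub-matrix, same dimensions as `chunk`.
#' @export
permute_chunk <- function(chunk, split, chunk_idx, cfg) {
  if (!split %in% names(cfg$split_offsets)) {
    ab_config_error(sprintf("unknown split '%s'", split))
  }
  seed <- (cfg$decoy_seed + as.numeric(cfg$split_offsets[[split]]) +
             as.numeric(chunk_idx)) %% 2147483647
  perm <- with_seed(as.integer(seed), sample.int(nrow(chunk)))
  chunk[perm, , drop = FALSE]
}

#' Expand a genotype matrix with decoy features
#'
#' Concatenates `[real | decoy]` along the feature dimension, doubling the
#' number of SNP features. Decoys are generated chunk by chunk with
#' [permute_chunk()]; nothing is persisted.
#'
#' @param G A `genotype_matrix` or plain dosage matrix.
#' @param cfg A [decoy_config()].
#' @param split Split label used to select the permutation stream.
#' @return List with `features` (n x 2m matrix), `labels` (character vector
#'   `"real"`/`"decoy"` per column), and `real_idx`/`decoy_idx`.
#' @export
expand_features <- function(G, cfg, split) {
  X <- if (inherits(G, "genotype_matrix")) G$dosages else G
  m <- ncol(X)
  if (m == 0) {
    return(list(features = X, labels = character(0),
                real_idx = integer(0), decoy_idx = integer(0)))
  }
  chunks <- split(seq_len(m), ceiling(seq_len(m) / cfg$chunk_size))
  decoy <- X
  for (ci in seq_along(chunks)) {
    cols <- chunks[[ci]]
    decoy[, cols] <- permute_chunk(X[, cols, drop = FALSE], split, ci, cfg)
  }
  if (!is.null(colnames(decoy))) {
    colnames(decoy) <- paste0("DECOY_", colnames(decoy))
  }
  list(
    features = cbind(X, decoy),
    labels = c(rep("real", m), rep("decoy", m)),
    real_idx = seq_len(m),
    decoy_idx = m + seq_len(m)
  )
}
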