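# Minimal PLINK 1 binary I/O (bed/bim/fam) for exporting synthetic cohorts
# and spike-in columns. SNP-major bed layout; dosage codes the count of the
# A1 (minor) allele, so bed 2-bit codes are 00 = 2, 10 = 1, 11 = 0,
# 01 = missing (never produced by the generators).

#' Write a genotype matrix as a PLINK 1 binary file set
#'
#' @param G A `genotype_matrix`, or a plain 0/1/2 dosage matrix with column
#'   names as SNP ids.
#' @param prefix Output path prefix; writes `prefix.bed/.bim/.fam`.
#' @param pheno Optional phenotype vector for the fam file (defaults to -9).
#' @param sex Optional sex vector (0/1 coded; written as 2/1 per convention).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(G, prefix, pheno = NULL, sex = NULL) {
  X <- if (inherits(G, "genotype_matrix")) G$dosages else G
  n <- nrow(X); m <- ncol(X)
  snp_ids <- colnames(X) %||% sprintf("SNP_%06d", seq_len(m))
  sample_ids <- rownames(X) %||% sprintf("S%06d", seq_len(n))
  # bim: chr, id, cM, bp, A1 (minor), A2
  bim <- data.frame(chr = 1L, id = snp_ids, cm = 0L, bp = seq_len(m),
                    a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(
    fid = sample_ids, iid = sample_ids, pat = 0L, mat = 0L,
    sex = if (is.null(sex)) 0L else ifelse(sex == 1, 1L, 2L),
    pheno = if (is.null(pheno)) -9 else pheno
  )
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # bed: magic bytes, then SNP-major packed genotypes
  code <- c(3L, 2L, 0L) # dosage 0,1,2 -> 2-bit code (11, 10, 00)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  for (j in seq_len(m)) {
    codes <- code[X[, j] + 1L]
    length(codes) <- bytes_per_snp * 4L # pad with NA
    codes[is.na(codes)] <- 0L
    mat <- matrix(codes, nrow = 4)
    packed <- mat[1, ] + mat[2, ] * 4L + mat[3, ] * 16L + mat[4, ] * 64L
    writeBin(as.raw(packed), con)
  }
  invisible(prefix)
}

#' Read a PLINK 1 binary file set
#'
#' Supports the SNP-major layout written by [write_plink()] (and standard
#' tooling). Missing genotypes (2-bit code 01) are returned as NA.
#'
#' @param prefix Path prefix of the `.bed/.bim/.fam` files.
#' @return A `genotype_matrix` (with `maf` recomputed from the data).
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           stringsAsFactors = FALSE)
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    ab_stop("not a SNP-major PLINK 1 bed file", "ab_io_error")
  }
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * m)
  ints <- as.integer(raw)
  # unpack 2-bit codes: 00->2, 10->1, 11->0, 01->NA
  lut <- c(2L, NA_integer_, 1L, 0L) # index = code + 1
  dos <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    b <- ints[((j - 1) * bytes_per_snp + 1):(j * bytes_per_snp)]
    codes <- c(rbind(b %% 4, (b %/% 4) %% 4, (b %/% 16) %% 4, (b %/% 64) %% 4))
    dos[, j] <- lut[codes[seq_len(n)] + 1L]
  }
  dimnames(dos) <- list(fam[[2]], bim[[2]])
  structure(
    list(dosages = dos, snp_ids = bim[[2]],
         maf = unname(colMeans(dos, na.rm = TRUE) / 2),
         sample_ids = fam[[2]]),
    class = "genotype_matrix"
  )
}

#' Write phenotype and covariates as a tab-separated file
#'
#' @param pheno A `phenotype` object.
#' @param cov Covariate table.
#' @param path Output path.
#' @export
write_pheno_tsv <- function(pheno, cov, path) {
  out <- data.frame(sample_id = cov$sample_id, age = cov$age, sex = cov$sex,
                    raw = pheno$raw,
                    adjusted = pheno$adjusted %||% NA_real_)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
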