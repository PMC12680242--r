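# Internal helpers: classed errors, reproducible local RNG, seed derivation.

ab_stop <- function(msg, class = "ab_error", data = NULL) {
  cond <- structure(
    class = c(class, "ab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

ab_config_error <- function(msg, data = NULL) ab_stop(msg, "ab_config_error", data)
ab_generation_error <- function(msg, data = NULL) ab_stop(msg, "ab_generation_error", data)

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded sub-computations never perturb the ambient random stream. All
#' stochastic operations in the package draw their randomness through this
#' gate, which is what makes a whole benchmark run a pure function of its
#' master seed.
#'
#' @param seed Integer seed (must be below 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash used for hierarchical seed management: every
#' random draw in a benchmark run receives a seed derived from the master seed
#' and a stage/index offset. A Lehmer-style multiplicative mix keeps children
#' well separated for nearby offsets; results stay below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param offset Integer offset identifying the consumer (stage, SNP index...).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, offset = 0) {
  m <- 2147483563
  x <- (as.numeric(master) %% m) + 1
  x <- (x * 40014) %% m
  x <- (x + (as.numeric(offset) %% m) * 40692) %% m
  x <- (x * 40014) %% m
  as.integer(x %% (m - 2)) + 1L
}

# Pearson correlation that tolerates zero-variance inputs (returns 0).
safe_cor <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(0)
  stats::cor(a, b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
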