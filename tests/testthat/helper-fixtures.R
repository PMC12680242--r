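# Shared fixtures, built in code at test time.

# A small synthetic cohort with adjusted phenotype and splits.
tiny_cohort <- function(n = 400, m = 60, seed = 101, h2 = 0.5,
                        n_background = 20) {
  G <- generate_base_genotypes(n, m, seed = derive_seed(seed, 1))
  cov <- generate_covariates(n, seed = derive_seed(seed, 2))
  ph <- generate_phenotype(G, cov, n_background = n_background, h2 = h2,
                           seed = derive_seed(seed, 3))
  split <- stratified_split(cov, seed = derive_seed(seed, 4))
  ph <- adjust_phenotype(ph, cov, fit_mask = split == "train")
  list(G = G, cov = cov, pheno = ph, y = ph$adjusted, split = split)
}

# A purely linear model f(x) = w . x + b in folded affine form.
linear_net <- function(w, b = 0) {
  structure(list(layers = list(list(W = matrix(w, ncol = 1), b = b))),
            class = "affine_net")
}

# A random ReLU network in folded affine form (for completeness checks).
# Fan-in-scaled weights keep the function on an O(1) scale, as after training.
random_relu_net <- function(d, hidden = c(8, 6, 4), seed = 1) {
  with_seed(seed, {
    dims <- c(d, hidden, 1)
    layers <- lapply(seq_len(length(dims) - 1), function(l) {
      list(W = matrix(stats::rnorm(dims[l] * dims[l + 1], sd = 1 / sqrt(dims[l])),
                      dims[l], dims[l + 1]),
           b = stats::rnorm(dims[l + 1], sd = 0.2))
    })
    structure(list(layers = layers), class = "affine_net")
  })
}

# Standardized synthetic phenotype vector for spike-in tests.
std_pheno <- function(n, seed = 1) {
  with_seed(seed, as.numeric(scale(stats::rnorm(n))))
}
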