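# Shared fixtures, built in code.

# wi map with every sense codon at 1 except where overridden
toy_wi <- function(...) {
  w <- stats::setNames(rep(1, length(sense_codons())), sense_codons())
  over <- c(...)
  w[names(over)] <- over
  w
}

# concatenate codons into a CDS string
cds <- function(...) paste(c(...), collapse = "")

# brute-force stAI oracle: plain product, no log space
stai_oracle <- function(seq, w, code = genetic_code()) {
  codons <- split_codons(seq)[-1]
  codons <- codons[!(codons %in% code$stop_codons)]
  prod(w[codons])^(1 / length(codons))
}

# random valid CDS of n codons (ATG + random sense codons)
random_cds <- function(n_codons) {
  cds("ATG", sample(sense_codons(), n_codons, replace = TRUE))
}

# GLS slope by explicit Cholesky whitening of the Brownian covariance:
# through-origin regression after whitening and phylogenetic centering
gls_whitening_slope <- function(tree, x, y) {
  V <- ape::vcv(tree)
  sp <- tree$tip.label
  L <- chol(V)
  one <- rep(1, length(sp))
  wx <- backsolve(L, cbind(one, x[sp], y[sp]), transpose = TRUE)
  mu_x <- sum(wx[, 1] * wx[, 2]) / sum(wx[, 1]^2)
  mu_y <- sum(wx[, 1] * wx[, 3]) / sum(wx[, 1]^2)
  cx <- wx[, 2] - mu_x * wx[, 1]
  cy <- wx[, 3] - mu_y * wx[, 1]
  sum(cx * cy) / sum(cx^2)
}

# small shared synthetic dataset (generated once per test run)
small_sim <- local({
  ds <- NULL
  function() {
    if (is.null(ds))
      ds <<- generate_dataset(sim_config(seed = 11, n_species = 20,
                                         n_genes = 60))
    ds
  }
})
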