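# shared fixture builders for the test suite

# a clean (corruption-free) simulator configuration
clean_config <- function(n_reads, seed = 101L, ...) {
  sim_config(n_reads = n_reads, seed = seed, ...)
}

# peptides with an exact residue count: `n_res` residues of `residue`,
# filler elsewhere, chunked into `n_pep` peptides of length 15
peptides_with_count <- function(n_pep, n_res, residue, filler = "A") {
  total <- n_pep * 15L
  stopifnot(n_res <= total)
  res <- c(rep(residue, n_res), rep(filler, total - n_res))
  apply(matrix(res, nrow = n_pep, byrow = TRUE), 1, paste, collapse = "")
}

# random 15-mer peptides from the uniform residue distribution
random_peptides <- function(n, seed = 7L, length_aa = 15L) {
  set.seed(seed)
  replicate(n, sample_peptide(uniform_aa_probs(), length_aa))
}

# 5-sigma binomial half-width for a proportion
binom_5se <- function(p, n) 5 * sqrt(p * (1 - p) / n)
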