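# small in-code fixtures shared across test files

# a handful of hand-written records with known labels
tiny_records <- function() {
  list(protein_record("p1", "ACDEFGHIKL", c(0, 1, 1, 0, 0, 0, 1, 0, 0, 0)),
       protein_record("p2", "MNPQRSTVWY", c(1, 0, 0, 0, 0, 0, 0, 0, 0, 1)),
       protein_record("p3", "AAAACCCC", c(0, 0, 1, 1, 1, 0, 0, 0)))
}

# random record over the standard alphabet
random_record <- function(id, L, seed, p = 0.2) {
  with_seed <- ppistack:::with_seed
  with_seed(seed, {
    protein_record(id, paste(sample(AA_ALPHABET, L, replace = TRUE),
                             collapse = ""),
                   rbinom(L, 1, p))
  })
}

# a small, cheap network configuration used where only mechanics matter
tiny_net_config <- function(fmod = 0, W = 4, ...) {
  net_config(window = W, fmod = fmod, fc_sizes = c(32, 16, 1), ...)
}

# quick synthetic dataset for training-mechanics tests
tiny_synth <- function(n = 24, seed = 11, ...) {
  generate_dataset(synthetic_config(n_sequences = n, seed = seed, ...))
}
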