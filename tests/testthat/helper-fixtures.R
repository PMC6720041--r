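# Small fixtures built in code at test time.

tiny_exy <- function() {
  m <- matrix(c(5, 1, 0, 2,
                0, 4, 1, 1,
                1, 0, 6, 0,
                2, 2, 2, 2,
                0, 1, 0, 5), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  m
}

tiny_db <- function() {
  gene_set_db(list(A = c("g1", "g4"), B = c("g2"), C = c("g3", "g5")))
}

# Deterministic block-structured profile signature: each type's markers sit
# in a disjoint block at a high value over a varying background.
block_signature <- function(n_genes = 30, n_types = 3, block = 5,
                            high = 10) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  sig <- matrix(rep(seq_len(n_genes) %% 3 + 1, n_types), n_genes, n_types,
                dimnames = list(genes, paste0("T", seq_len(n_types))))
  for (t in seq_len(n_types)) {
    sig[(t - 1) * block + seq_len(block), t] <- high
  }
  sig
}

small_dataset <- function(seed = 7) {
  generate_dataset(
    synthetic_config(n_genes = 400, n_types = 4, markers_per_type = 15,
                     cells_per_cluster = 20),
    seed = seed)
}
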