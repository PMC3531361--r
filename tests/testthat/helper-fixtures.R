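# Fixtures are built in code; nothing is read from disk except files the
# tests write themselves.

# Tiny hand-written alignment with a gapped reference.
toy_alignment <- function() {
  aa_alignment(c(ref = "MA-LWC", s2 = "MAGLWC", s3 = "MVGIWC"),
               reference_id = "ref")
}

# Exchangeable (tree-free) random alignment: rows i.i.d. uniform residues.
iid_alignment <- function(n = 32, L = 60, seed = 1) {
  set.seed(seed)
  mat <- matrix(sample(coevoscan:::AA20, n * L, replace = TRUE), n, L)
  aa_alignment(apply(mat, 1, paste, collapse = ""), ids = paste0("s", seq_len(n)))
}

# Simulated alignment under the package's generator; optionally with planted
# compensatory pairs (defaults are the calibration conditions).
sim_fixture <- function(seed, n_taxa = 32, L = 60, pairs = list()) {
  tr <- simulate_tree(n_taxa, seed = seed)
  simulate_alignment(tr, sim_config(n_taxa = n_taxa, length = L,
                                    coupled_pairs = pairs, seed = seed + 1))
}

# Alignment whose records all set the first record as reference so column
# numbering equals residue numbering (gap-free).
with_reference <- function(aln) {
  aln$reference_id <- aln$ids[1]
  aln
}

expect_symmetric <- function(m, tol = 1e-12) {
  expect_lt(max(abs(m - t(m))), tol)
}
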