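#!/usr/bin/env Rscript

# Build the synthetic study set used by the downstream analysis scripts:
#
#  * a 27-taxon "hormone" family of 110 residues with the domain layout of
#    a preproinsulin-like precursor (signal 1-24, B 25-54, C 57-87,
#    A 90-110) and three planted compensatory pairs -- two inside the
#    C-peptide-like linker (86, 87) and one linking it to the B-chain-like
#    region (37, 59), plus a signal-peptide pair (10, 16) -- the site pattern
#    an intramolecular coevolution scan is expected to recover;
#  * a 12-taxon ligand/receptor family pair evolved on a shared tree with
#    strongly shared per-branch rates (s = 0.9), sliced into a 110-column
#    ligand and a 400-column receptor, plus an independent-rate control
#    family standing in for an unrelated protein.
#
# Everything is written under results/data/ as FASTA + Newick + TSV.

suppressMessages(library(coevoscan))

out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## intramolecular study family (27 taxa, like the ortholog set a curated
## vertebrate alignment provides)
tr27 <- simulate_tree(27, seed = 101)
planted <- list(coupled_pair(86, 87, rho = 0.9, property = "volume"),
                coupled_pair(37, 59, rho = 0.9, property = "volume"),
                coupled_pair(10, 16, rho = 0.9, property = "volume"))
sim <- simulate_alignment(tr27, sim_config(27, 110, coupled_pairs = planted,
                                           seed = 102),
                          reference_id = "t1")
write_alignment(sim$alignment, file.path(out, "hormone27.fasta"))
write_ground_truth(sim, file.path(out, "hormone27_truth.tsv"))
ape::write.tree(sim$tree, file.path(out, "tree27.nwk"))
cat(sprintf("hormone family: %d taxa x %d columns, %d planted pairs (%d widened draws)\n",
            n_records(sim$alignment), alignment_length(sim$alignment),
            nrow(sim$truth), sim$n_widened))

## ligand/receptor pair at the 12-species scale + independent control
tr12 <- simulate_tree(12, seed = 201)
fp <- simulate_family_pair(tr12, s = 0.9, seed = 202, length = 510)
seqs <- alignment_sequences(fp$A)
ligand <- aa_alignment(substr(seqs, 1, 110), ids = names(seqs),
                       reference_id = names(seqs)[1])
receptor <- aa_alignment(substr(alignment_sequences(fp$B), 111, 510),
                         ids = fp$B$ids, reference_id = fp$B$ids[1])
control <- simulate_family_pair(tr12, s = 0, seed = 203, length = 400)$B

write_alignment(ligand, file.path(out, "ligand12.fasta"))
write_alignment(receptor, file.path(out, "receptor12.fasta"))
write_alignment(control, file.path(out, "control12.fasta"))
ape::write.tree(tr12, file.path(out, "tree12.nwk"))
cat(sprintf("ligand %d x %d, receptor %d x %d, control %d x %d (shared tree, s = 0.9)\n",
            n_records(ligand), alignment_length(ligand),
            n_records(receptor), alignment_length(receptor),
            n_records(control), alignment_length(control)))
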