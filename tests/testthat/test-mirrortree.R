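test_that("p-distance counts mismatches over jointly valid columns", {
  expect_equal(p_distance("MALW", "MALW"), 0)
  expect_equal(p_distance("AAAA", "AATT"), 0.5)
  expect_equal(p_distance("A-CD", "AB-D"), 0)   # columns 1 and 4 only
  expect_equal(p_distance("AXCD", "AACD"), 0)   # X treated as missing
  expect_error(p_distance("A-", "-A"), "no comparable sites")
  expect_error(p_distance("AA", "AAA"), "unequal length")
})

test_that("Poisson correction maps p to -ln(1 - p)", {
  expect_equal(poisson_distance("MALW", "MALW"), 0)
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("C", 50), strrep("A", 50))
  expect_equal(poisson_distance(s1, s2), -log(0.5), tolerance = 1e-12)
  expect_error(poisson_distance("AA", "CC"), "saturated")
})

test_that("Poisson distance dominates p with equality only at zero", {
  set.seed(12)
  p <- c(0, runif(10000, 0, 0.999))
  d <- coevoscan:::poisson_correct(p)
  expect_true(all(d >= p))
  expect_true(all(d[p > 0] > p[p > 0]))
  expect_identical(d[1], 0)
})

test_that("distance matrices are symmetric and match a brute-force loop", {
  aln <- aa_alignment(c(a = "MALWCD", b = "MALWCE", c = "GALWCD",
                        d = "MKLWTD"))
  d <- distance_matrix(aln)
  expect_symmetric(d)
  expect_equal(unname(diag(d)), rep(0, 4))
  seqs <- alignment_sequences(aln)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(d[i, j], poisson_distance(seqs[i], seqs[j]))
  }

  same <- aa_alignment(c(a = "MALW", b = "MALW", c = "MALW"))
  expect_true(all(distance_matrix(same) == 0))
})

test_that("complete deletion equals pairwise deletion on gap-free data", {
  aln <- sim_fixture(201, n_taxa = 6, L = 40)$alignment
  expect_equal(distance_matrix(aln, "complete"), distance_matrix(aln, "pairwise"))
  # and differs once gaps force column removal
  gappy <- aa_alignment(c(a = "MA-WCD", b = "MALWCE", c = "GALWCD",
                          d = "MKLWTD"))
  dc <- distance_matrix(gappy, "complete")
  dp <- distance_matrix(gappy, "pairwise")
  expect_false(isTRUE(all.equal(dc, dp)))
})

test_that("saturated pairs abort the distance matrix with a named error", {
  aln <- aa_alignment(c(a = "AAA", b = "CCC", c = "AAC"))
  expect_error(distance_matrix(aln), "saturated pair: a vs b")
})

test_that("mirrortree correlation reproduces hand-derived cases", {
  sp <- letters[1:3]
  mk <- function(v) {
    m <- matrix(0, 3, 3, dimnames = list(sp, sp))
    m[upper.tri(m)] <- v
    m + t(m)
  }
  X <- mk(c(1, 2, 3))
  expect_equal(mirrortree_r(X, X)$r, 1)
  expect_equal(mirrortree_r(X, mk(c(6, 4, 2)))$r, -1)
  r <- mirrortree_r(X, mk(c(1, 3, 2)))
  expect_equal(r$r, 0.5, tolerance = 1e-12)
  expect_equal(r$n_species, 3L)
  expect_equal(r$n_pairs, 3L)
})

test_that("mirrortree correlation is invariant to species order and affine maps", {
  d <- distance_matrix(sim_fixture(211, n_taxa = 8, L = 50)$alignment)
  perm <- sample(rownames(d))
  expect_equal(mirrortree_r(d, d[perm, perm])$r, 1)
  expect_equal(mirrortree_r(d, 2.5 * d + 0.3)$r, 1)
  expect_equal(mirrortree_r(d, -1.5 * d + 9)$r, -1)

  d2 <- d; rownames(d2) <- colnames(d2) <- paste0("z", 1:8)
  expect_error(mirrortree_r(d, d2), "unmatched species")
  expect_error(mirrortree_r(d, matrix(1, 8, 8, dimnames = dimnames(d))),
               "degenerate")
})

test_that("identical families give a correlation table of ones", {
  aln <- sim_fixture(221, n_taxa = 6, L = 40)$alignment
  tab <- correlation_table(list(l1 = aln, l2 = aln), list(r1 = aln),
                          control = aln)
  expect_true(all(abs(tab$r - 1) < 1e-12))
})

test_that("shared-rate families beat an independent control in the table", {
  ok <- 0
  for (i in 1:5) {
    tr <- simulate_tree(12, seed = 230 + i)
    fp <- simulate_family_pair(tr, s = 1, seed = 240 + i)
    ctl <- simulate_family_pair(tr, s = 0, seed = 250 + i)$B
    tab <- correlation_table(list(ligand = fp$A), list(receptor = fp$B),
                             control = ctl)
    if (isTRUE(tab$exceeds_control["receptor", "ligand"])) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("the correlation table maps species ids between families", {
  aln <- sim_fixture(261, n_taxa = 6, L = 40)$alignment
  renamed <- aa_alignment(alignment_sequences(aln),
                          ids = paste0("sp_", seq_len(6)))
  smap <- list(receptor = stats::setNames(aln$ids, paste0("sp_", 1:6)))
  tab <- correlation_table(list(ligand = aln), list(receptor = renamed),
                           species_map = smap)
  expect_equal(unname(tab$r["receptor", "ligand"]), 1)
  expect_error(correlation_table(list(ligand = aln), list(receptor = renamed)),
               "unmatched species")
})

test_that("PHYLIP square matrices round-trip", {
  d <- distance_matrix(sim_fixture(271, n_taxa = 5, L = 60)$alignment)
  tmp <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(d, tmp)
  back <- read_phylip_dist(tmp)
  expect_identical(rownames(back), rownames(d))
  expect_equal(back, d, tolerance = 1e-6)
})

test_that("mirrortree table TSV carries receptor rows, mean row and control", {
  aln <- sim_fixture(281, n_taxa = 6, L = 40)$alignment
  tab <- correlation_table(list(lig = aln), list(rec = aln), control = aln)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_mirrortree_tsv(tab, tmp)
  out <- read.delim(tmp)
  expect_identical(out$family, c("rec", "Mean", "control"))
  expect_identical(names(out), c("family", "lig", "control"))
})
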