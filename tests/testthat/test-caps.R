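test_that("divergence times are Poisson distances with zero diagonal", {
  # a and b differ at half of their 100 shared columns
  tail50 <- strrep("A", 50)
  aln <- aa_alignment(c(
    a = paste0(strrep("A", 50), tail50),
    b = paste0(strrep("C", 50), tail50),
    c = paste0(strrep("G", 25), strrep("A", 25), tail50),
    d = paste0(strrep("A", 25), strrep("W", 25), tail50)))
  tm <- divergence_times(aln)
  expect_equal(tm["a", "b"], -log(0.5), tolerance = 1e-12)
  expect_symmetric(tm)
  expect_equal(unname(diag(tm)), rep(0, 4))
  expect_error(divergence_times(aa_alignment(c(a = "MAL", b = "MAL"))),
               "need >=4")
})

test_that("identical and saturated sequence pairs are excluded from profiles", {
  aln <- aa_alignment(c(a = "AAAA", b = "AAAA", c = "CAAA", d = "AWAA"))
  tm <- divergence_times(aln)
  prof <- caps_profile(aln, 1, t = tm)
  # pair (a, b) has t = 0 and must be excluded
  k_ab <- which(prof$pairs[, 1] == 1 & prof$pairs[, 2] == 2)
  expect_false(prof$included[k_ab])
  expect_true(is.na(prof$theta[k_ab]))
  # a fully mismatching pair gets t = Inf, a warning, and is excluded
  sat <- aa_alignment(c(a = "AA", b = "CC", c = "AC", d = "CA"))
  expect_warning(tm2 <- divergence_times(sat), "saturated")
  expect_true(is.infinite(tm2["a", "b"]))
  prof2 <- suppressWarnings(caps_profile(sat, 1, t = tm2))
  expect_false(prof2$included[1])
})

test_that("profiles match an independent brute-force evaluation", {
  sim <- sim_fixture(51, n_taxa = 8, L = 15)
  aln <- sim$alignment
  S <- blosum62()
  tm <- divergence_times(aln)
  for (j in c(1, 7, 15)) {
    prof <- caps_profile(aln, j, S = S, t = tm)
    # brute force: loop every pair, score B / t, then squared deviations
    theta <- c()
    for (i1 in 1:7) for (i2 in (i1 + 1):8) {
      if (tm[i1, i2] > 0) {
        theta <- c(theta, S[aln$mat[i1, j], aln$mat[i2, j]] / tm[i1, i2])
      }
    }
    expect_equal(unname(prof$theta[prof$included]), theta)
    expect_equal(unname(prof$D[prof$included]), (theta - mean(theta))^2)
  }
})

test_that("an invariant column's theta varies only through divergence time", {
  aln <- aa_alignment(c(a = "AMAL", b = "ACDW", c = "AWKV", d = "AGHN"))
  tm <- divergence_times(aln)
  prof <- caps_profile(aln, 1, t = tm)
  th <- prof$theta[prof$included]
  tv <- tm[prof$pairs][prof$included]
  expect_equal(unname(th * tv), rep(blosum62()["A", "A"], sum(prof$included)))
})

test_that("identical residue patterns give r_coev = 1 and are significant", {
  # columns 1 and 2 share a pattern; the rest come from the tree simulator
  base <- c("G", "A", "W", "S", "L", "F", "K", "D")
  seqs <- alignment_sequences(sim_fixture(41, n_taxa = 8, L = 20)$alignment)
  seqs <- paste0(base, base, substring(seqs, 3))
  aln <- aa_alignment(seqs, ids = paste0("s", 1:8))
  cs <- caps_scan(aln, n_resample = 200, seed = 2)
  p <- cs$pairs[cs$pairs$col1 == 1 & cs$pairs$col2 == 2, ]
  expect_equal(p$r_coev, 1, tolerance = 1e-9)
  expect_true(p$significant)
})

test_that("r_coev is invariant under joint record reordering", {
  sim <- sim_fixture(61, n_taxa = 8, L = 16)
  aln <- sim$alignment
  cs <- caps_scan(aln, n_resample = 50, seed = 4)
  perm <- c(5, 2, 8, 1, 3, 7, 4, 6)
  alnp <- aa_alignment(alignment_sequences(aln)[perm], ids = aln$ids[perm])
  csp <- caps_scan(alnp, n_resample = 50, seed = 4)
  m <- merge(cs$pairs[, c("col1", "col2", "r_coev")],
             csp$pairs[, c("col1", "col2", "r_coev")],
             by = c("col1", "col2"))
  expect_equal(m$r_coev.x, m$r_coev.y, tolerance = 1e-9)
})

test_that("the column-sample null keeps the false-positive rate near alpha", {
  rates <- vapply(1:3, function(i) {
    sim <- sim_fixture(700 + i)
    cs <- caps_scan(sim$alignment, n_resample = 1000, alpha = 0.05,
                    seed = 70 + i)
    mean(cs$pairs$significant)
  }, numeric(1))
  expect_lte(mean(rates), 0.1)
})

test_that("planted compensatory pairs are detected at high coupling", {
  found <- 0; total <- 0
  for (i in 1:5) {
    sim <- sim_fixture(300 + i,
                       pairs = list(coupled_pair(5, 12, rho = 0.9),
                                    coupled_pair(20, 40, rho = 0.9)))
    cs <- caps_scan(sim$alignment, n_resample = 1000, seed = 30 + i)
    p <- cs$pairs
    for (pp in list(c(5, 12), c(20, 40))) {
      total <- total + 1
      hit <- p$significant[p$col1 == pp[1] & p$col2 == pp[2]]
      if (length(hit) == 1 && hit) found <- found + 1
    }
  }
  expect_gte(found / total, 0.5)
})

test_that("oversized coevolution groups are flagged, small ones are not", {
  # three columns with one shared pattern -> one group of three sites
  base <- c("G", "A", "W", "S", "L", "F", "K", "D")
  seqs <- alignment_sequences(sim_fixture(43, n_taxa = 8, L = 20)$alignment)
  seqs <- paste0(base, base, base, substring(seqs, 4))
  aln <- aa_alignment(seqs, ids = paste0("s", 1:8))
  cs <- caps_scan(aln, n_resample = 200, seed = 6, group_cap = 0.05)
  # the group containing site 1 holds the three patterned sites
  g1 <- which(vapply(cs$groups, function(g) "1" %in% g, logical(1)))
  expect_length(g1, 1)
  expect_gte(length(cs$groups[[g1]]), 3)
  # cap = ceiling(0.05 * 20) = 1, so the group must carry the oversize flag
  expect_true(cs$group_flagged[g1])
  # every flag reflects its group's size against the cap
  expect_identical(cs$group_flagged, lengths(cs$groups) > 1)
  cs2 <- caps_scan(aln, n_resample = 200, seed = 6, group_cap = 0.5)
  expect_identical(cs2$group_flagged, lengths(cs2$groups) > 10)
})

test_that("compensation correlations are 1 for duplicated sites", {
  set.seed(3)
  base <- sample(coevoscan:::AA20, 8, replace = TRUE)
  mat <- cbind(base, base,
               matrix(sample(coevoscan:::AA20, 8 * 6, replace = TRUE), 8))
  aln <- aa_alignment(apply(mat, 1, paste, collapse = ""),
                      ids = paste0("s", 1:8))
  cc <- compensation_correlations(aln, 1, 2)
  expect_equal(cc$r_hydro, 1, tolerance = 1e-12)
  expect_equal(cc$r_mw, 1, tolerance = 1e-12)
})

test_that("compensation correlations are unchanged by reversing record order", {
  sim <- sim_fixture(81, n_taxa = 8, L = 10)
  aln <- sim$alignment
  rev_aln <- aa_alignment(rev(alignment_sequences(aln)), ids = rev(aln$ids))
  c1 <- compensation_correlations(aln, 2, 7)
  c2 <- compensation_correlations(rev_aln, 2, 7)
  expect_equal(attr(c1, "raw_hydro"), attr(c2, "raw_hydro"), tolerance = 1e-9)
  expect_equal(attr(c1, "raw_mw"), attr(c2, "raw_mw"), tolerance = 1e-9)
})

test_that("uncorrelated random sites rarely earn a compensation value", {
  hits <- 0
  for (i in 1:10) {
    aln <- iid_alignment(12, 6, seed = 500 + i)
    cc <- compensation_correlations(aln, 1, 4)
    if (!is.na(cc$r_hydro)) hits <- hits + 1
  }
  expect_lte(hits, 3)
})

test_that("intermolecular scan against itself recovers the diagonal", {
  sim <- sim_fixture(91, n_taxa = 8, L = 12)
  aln <- sim$alignment
  cs <- caps_intermolecular(aln, aln, n_resample = 100, seed = 8)
  diag_pairs <- cs$pairs[cs$pairs$col1 == cs$pairs$col2, ]
  expect_true(all(abs(diag_pairs$r_coev - 1) < 1e-9))
})

test_that("intermolecular scan finds a planted cross-family pair", {
  found <- 0
  for (i in 1:4) {
    # one family of 24 columns with a coupled (3, 15) pair, split in half:
    # the pair becomes intermolecular between columns 3 of A and 3 of B
    tr <- simulate_tree(32, seed = 150 + i)
    sim <- simulate_alignment(tr, sim_config(32, 24, seed = 151 + i,
      coupled_pairs = list(coupled_pair(3, 15, rho = 0.9))))
    seqs <- alignment_sequences(sim$alignment)
    A <- aa_alignment(substr(seqs, 1, 12), ids = names(seqs))
    B <- aa_alignment(substr(seqs, 13, 24), ids = names(seqs))
    cs <- suppressWarnings(  # a few saturated pairs are expected on 12 columns
      caps_intermolecular(A, B, n_resample = 500, seed = 15 + i))
    hit <- cs$pairs$significant[cs$pairs$col1 == 3 & cs$pairs$col2 == 3]
    if (length(hit) == 1 && hit) found <- found + 1
  }
  expect_gte(found, 2)
})

test_that("intermolecular scan validates the species mapping", {
  sim <- sim_fixture(95, n_taxa = 6, L = 10)
  aln <- sim$alignment
  other <- aa_alignment(alignment_sequences(aln), ids = paste0("x", 1:6))
  expect_error(caps_intermolecular(aln, other), "unmatched species")
  map <- stats::setNames(paste0("x", 1:6), aln$ids)
  cs <- caps_intermolecular(aln, other, species_map = map,
                            n_resample = 50, seed = 1)
  expect_s3_class(cs, "caps_result")
})

test_that("CAPS TSV output renders non-significant compensation as No", {
  sim <- sim_fixture(301, pairs = list(coupled_pair(5, 12, rho = 0.9)))
  cs <- caps_scan(sim$alignment, n_resample = 500, seed = 31)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_caps_tsv(cs, tmp)
  tab <- read.delim(tmp, colClasses = "character")
  expect_identical(names(tab),
                   c("Site1", "Site2", "Coevolution_correlation",
                     "Hydrophobicities_correlation",
                     "Molecular_weights_correlation"))
  expect_equal(nrow(tab), sum(cs$pairs$significant))
})
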