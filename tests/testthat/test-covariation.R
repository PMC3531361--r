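test_that("Vingron-Argos weights down-weight redundant sequences", {
  two <- aa_alignment(c(a = "MALW", b = "MALW"))
  expect_equal(unname(vingron_argos_weights(two)), c(0.5, 0.5))

  three <- aa_alignment(c(a = "MALW", b = "MALW", c = "GCST"))
  w <- vingron_argos_weights(three)
  expect_equal(sum(w), 1)
  expect_true(w[["c"]] > max(w[["a"]], w[["b"]]))

  expect_error(vingron_argos_weights(aa_alignment(c(a = "MALW"))),
               "need >=2")
})

test_that("Vingron-Argos weights commute with record permutation", {
  aln <- sim_fixture(31, n_taxa = 8, L = 30)$alignment
  w <- vingron_argos_weights(aln)
  perm <- c(3, 1, 8, 2, 6, 4, 7, 5)
  wp <- vingron_argos_weights(
    aa_alignment(alignment_sequences(aln)[perm], ids = aln$ids[perm]))
  expect_equal(wp, w[perm])
})

test_that("column property values are scale lookups with gaps masked", {
  aln <- aa_alignment(c(a = "GA", b = "GW", c = "G-"))
  vol <- aa_scale("volume")
  v1 <- position_property_values(aln, 1, vol)
  expect_equal(unname(v1), rep(vol[["G"]], 3))
  v2 <- position_property_values(aln, 2, vol)
  expect_equal(sum(is.na(v2)), 1L)
  expect_equal(unname(v2[1:2]), unname(vol[c("A", "W")]))
  expect_error(position_property_values(aln, 5, vol), "out of range")
})

test_that("weighted correlation matches hand-computed values", {
  w <- rep(1 / 3, 3)
  expect_equal(as.numeric(weighted_correlation(1:3, 1:3, w)), 1)
  expect_equal(as.numeric(weighted_correlation(1:3, -(1:3) + 7, w)), -1)
  expect_equal(as.numeric(weighted_correlation(c(1, 2, 3), c(1, 3, 2), w)), 0.5)
  # agrees with stats::cor under uniform weights
  set.seed(5)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(as.numeric(weighted_correlation(x, y, rep(1 / 20, 20))),
               cor(x, y))
  # masked entries reduce the joint sample
  x[3] <- NA
  expect_equal(attr(weighted_correlation(x, y, rep(1 / 20, 20)), "n"), 19L)
  expect_true(is.na(weighted_correlation(c(1, NA, NA), 1:3, w)))
})

test_that("perfectly covarying columns are found with r = 1", {
  # columns 1 and 2 carry the same residues -> identical volume vectors
  aln <- aa_alignment(c(a = "GGA", b = "AAA", c = "WWC", d = "SSC",
                        e = "LLT", f = "FFT"))
  sc <- covariation_scan(aln, aa_scale("volume"), variability_min = 3)
  p <- sc$pairs[sc$pairs$pos1 == 1 & sc$pairs$pos2 == 2, ]
  expect_equal(p$r, 1)
  expect_true(p$significant)
})

test_that("a fully conserved alignment yields an empty scan with warning", {
  aln <- aa_alignment(c(a = "MMAA", b = "MMAA", c = "MMAA", d = "MMAA"))
  expect_warning(sc <- covariation_scan(aln, aa_scale("volume")),
                 "variability")
  expect_equal(nrow(sc$pairs), 0L)
})

test_that("scan reports reference numbering when a reference is set", {
  aln <- aa_alignment(c(r = "G-GA", a = "A-AC", b = "WRWT", c = "SDSY",
                        d = "LELW", e = "FIFH"), reference_id = "r")
  sc <- covariation_scan(aln, aa_scale("volume"))
  # column 2 is a reference gap and is dropped; columns 3,4 -> residues 2,3
  expect_true(all(sc$positions %in% 1:3))
  expect_true(all(sc$pairs$pos2 <= 3))
})

test_that("covariation r is invariant under joint record permutation", {
  sim <- sim_fixture(17, n_taxa = 10, L = 20)
  aln <- sim$alignment
  sc <- covariation_scan(aln, aa_scale("volume"))
  perm <- sample(seq_len(10))
  alnp <- aa_alignment(alignment_sequences(aln)[perm], ids = aln$ids[perm])
  scp <- covariation_scan(alnp, aa_scale("volume"))
  expect_equal(scp$pairs$r, sc$pairs$r)
})

test_that("duplicating a sequence perturbs r only within the weight bound", {
  sim <- sim_fixture(23, n_taxa = 12, L = 25)
  aln <- sim$alignment
  sc <- covariation_scan(aln, aa_scale("volume"))
  seqs <- alignment_sequences(aln)
  dup <- aa_alignment(c(seqs, dup1 = unname(seqs[1])),
                      ids = c(aln$ids, "dup1"))
  scd <- covariation_scan(dup, aa_scale("volume"))
  shared <- merge(sc$pairs, scd$pairs, by = c("pos1", "pos2"))
  expect_gt(nrow(shared), 0)
  # numeric regression bound for this fixture
  expect_lt(max(abs(shared$r.x - shared$r.y)), 0.25)
})

test_that("the critical-value test is calibrated on exchangeable sequences", {
  rates <- vapply(1:5, function(i) {
    sc <- covariation_scan(iid_alignment(32, 60, seed = 100 + i),
                           aa_scale("volume"))
    mean(sc$pairs$significant, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(rates), 0.005)
  expect_lte(mean(rates), 0.02)
})

test_that("clustering groups correlated positions at the cutoff", {
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(1:2, 1:2))
  cl <- cluster_positions(r2, cutoff = 0.55)
  expect_equal(max(cl$clusters), 1L)

  r2b <- matrix(c(1, 0.1, 0.1, 1), 2, dimnames = list(1:2, 1:2))
  expect_equal(max(cluster_positions(r2b, 0.55)$clusters), 2L)

  r3 <- matrix(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1), 3,
               dimnames = list(1:3, 1:3))
  cl3 <- cluster_positions(r3, 0.55)
  expect_equal(unname(cl3$clusters[1]), unname(cl3$clusters[2]))
  expect_false(cl3$clusters[3] == cl3$clusters[1])
  # merge correlations annotate the tree, first merge at r = 0.9
  expect_equal(max(cl3$merge_r), 0.9)
  expect_match(cl3$newick, "^\\(")
})

test_that("domain summary counts significant pairs by domain and sign", {
  doms <- list(C = domain_annotation("C", 1, 10),
               A = domain_annotation("A", 11, 20))
  empty <- data.frame(pos1 = integer(0), pos2 = integer(0), r = numeric(0),
                      n_eff = numeric(0), significant = logical(0),
                      sign = character(0))
  ds0 <- domain_pair_summary(empty, doms)
  expect_true(all(ds0$total == 0))

  one <- data.frame(pos1 = 2, pos2 = 7, r = 0.8, n_eff = 10,
                    significant = TRUE, sign = "positive")
  ds1 <- domain_pair_summary(one, doms)
  expect_equal(ds1$positive["C", "C"], 1L)
  expect_equal(sum(ds1$negative), 0L)

  out <- data.frame(pos1 = 2, pos2 = 25, r = -0.8, n_eff = 10,
                    significant = TRUE, sign = "negative")
  ds2 <- domain_pair_summary(out, doms)
  expect_equal(ds2$negative["C", "unassigned"], 1L)
})

test_that("planted cross-domain coupling dominates the domain summary", {
  pairs <- list(coupled_pair(31, 46, rho = 0.9), coupled_pair(33, 48, rho = 0.9),
                coupled_pair(35, 50, rho = 0.9), coupled_pair(37, 52, rho = 0.9),
                coupled_pair(40, 55, rho = 0.9), coupled_pair(43, 58, rho = 0.9))
  doms <- list(signal = domain_annotation("signal", 1, 15),
               B = domain_annotation("B", 16, 30),
               C = domain_annotation("C", 31, 45),
               A = domain_annotation("A", 46, 60))
  total <- NULL
  for (i in 1:4) {
    sim <- sim_fixture(400 + i, pairs = pairs)
    aln <- with_reference(sim$alignment)
    sc <- covariation_scan(aln, aa_scale("volume"))
    ds <- domain_pair_summary(sc, doms)
    total <- if (is.null(total)) ds$total else total + ds$total
  }
  ca <- total["C", "A"]
  total["C", "A"] <- total["A", "C"] <- -1L
  expect_gt(ca, max(total))
})
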