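## Synthetic-data generator: protein families evolved along a shared
## phylogeny, with optional planted compensatory site pairs (covariation /
## CAPS ground truth) and tunable inter-family rate sharing (mirrortree
## ground truth).  Sites evolve by a Poisson substitution process with
## uniform replacement among the 20 amino acids; no indels are simulated, so
## outputs are gap-free and valid under all downstream preconditions.

#' Simulate a random phylogeny
#'
#' Topology is Yule-distributed (generated by uniform pair joining, which
#' yields the Yule labelled-topology distribution); branch lengths are drawn
#' i.i.d. from an exponential with mean `branch_mean` (expected substitutions
#' per site).
#'
#' @param n_taxa Number of tips (>= 4).
#' @param seed Optional integer seed (deterministic output under a fixed
#'   seed).
#' @param branch_mean Mean branch length (default 0.1 substitutions/site).
#' @return An [ape::rtree()]-style `phylo` object with tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, branch_mean = 0.1) {
  if (n_taxa < 4L) stop("need >=4 taxa")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rcoal(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
  phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 1 / branch_mean)
  phy
}

#' Declare a planted compensatory site pair
#'
#' Whenever a substitution occurs at `site_a`, with probability `rho` a
#' compensatory substitution at `site_b` is drawn restricted to residues that
#' keep the pair's property sum within `tolerance` of its pre-substitution
#' value (widened to the nearest residue when no residue qualifies).
#'
#' @param site_a,site_b Distinct 1-based site indices.
#' @param rho Coupling probability in `[0, 1]` (default 0.9).
#' @param property Name of the conserved property scale (default
#'   `"volume"`).
#' @param tolerance Allowed deviation of the property sum (default 10, in the
#'   scale's units; 10 A^3 for volume).
#' @return A list of class `coupled_pair`.
#' @export
coupled_pair <- function(site_a, site_b, rho = 0.9, property = "volume",
                         tolerance = 10) {
  if (site_a == site_b) stop("coupled sites must be distinct")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  structure(list(site_a = as.integer(site_a), site_b = as.integer(site_b),
                 rho = rho, property = property, tolerance = tolerance),
            class = "coupled_pair")
}

#' Simulation configuration
#'
#' Bundles the generator's parameters. Defaults are the calibration
#' conditions used throughout the package's tests: 32 taxa, 60 columns, rate
#' 1 substitution per site per unit branch length.
#'
#' @param n_taxa Number of taxa (>= 4).
#' @param length Number of alignment columns.
#' @param base_rate Substitution rate per site per unit branch length.
#' @param coupled_pairs List of [coupled_pair()]s.
#' @param family_rate_share Rate-sharing parameter `s` in `[0, 1]` for
#'   [simulate_family_pair()].
#' @param seed Optional integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 32L, length = 60L, base_rate = 1,
                       coupled_pairs = list(), family_rate_share = 1,
                       seed = NULL) {
  if (n_taxa < 4L) stop("need >=4 taxa")
  if (length < 1L) stop("length must be positive")
  if (family_rate_share < 0 || family_rate_share > 1) {
    stop("family_rate_share must be in [0, 1]")
  }
  for (cp in coupled_pairs) {
    if (!inherits(cp, "coupled_pair")) stop("coupled_pairs must be coupled_pair objects")
    if (cp$site_a > length || cp$site_b > length) {
      stop("coupled site outside alignment length")
    }
  }
  sites <- unlist(lapply(coupled_pairs, function(cp) c(cp$site_a, cp$site_b)))
  if (anyDuplicated(sites)) stop("coupled sites must be distinct across pairs")
  structure(list(n_taxa = as.integer(n_taxa), length = as.integer(length),
                 base_rate = base_rate, coupled_pairs = coupled_pairs,
                 family_rate_share = family_rate_share, seed = seed),
            class = "sim_config")
}

#' Evolve an alignment along a tree with planted compensatory pairs
#'
#' Independent sites evolve by a Poisson process (event count per branch
#' `~ Poisson(rate * branch length)`, each event replacing the residue by a
#' uniform draw among the 20 amino acids). For each coupled pair, the two
#' sites additionally evolve their own events, and every substitution at
#' `site_a` triggers, with probability `rho`, a compensatory replacement at
#' `site_b` restricted to residues keeping the property sum within tolerance
#' of its pre-substitution value. Pairs with `rho = 0` take exactly the
#' independent-sites code path.
#'
#' @param tree A `phylo` from [simulate_tree()].
#' @param cfg A [sim_config()].
#' @param reference_id Optional record id to mark as reference (alignments
#'   are gap-free, so reference numbering equals column numbering).
#' @return List of class `sim_alignment`: `alignment` (an
#'   [aa_alignment()]), `truth` (data frame of planted pairs: `site_a`,
#'   `site_b`, `rho`, `property`, `tolerance`), `tree`, `n_widened` (count of
#'   compensation events where no residue met the tolerance and the nearest
#'   was used).
#' @export
simulate_alignment <- function(tree, cfg, reference_id = NULL) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config")
  if (ape::Ntip(tree) != cfg$n_taxa) {
    stop("tree has ", ape::Ntip(tree), " tips but cfg expects ", cfg$n_taxa)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- cfg$length
  rate <- cfg$base_rate

  ## rho = 0 pairs are exactly independent sites: drop them up front so the
  ## code path (and RNG stream) is identical to the uncoupled generator
  cps <- Filter(function(cp) cp$rho > 0, cfg$coupled_pairs)
  coupled_sites <- unlist(lapply(cps, function(cp) c(cp$site_a, cp$site_b)))
  free_sites <- setdiff(seq_len(L), coupled_sites)
  scales <- lapply(cps, function(cp) unname(aa_scale(cp$property)[AA20]))

  tree <- stats::reorder(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, L)
  root <- ntip + 1L
  states[root, ] <- sample.int(20L, L, replace = TRUE)
  n_widened <- 0L
  ## the conserved constraint of each coupled pair: its ancestral property
  ## sum, fixed over the whole tree (compensation restores toward it, so the
  ## constraint does not random-walk as uncompensated changes accumulate)
  pair_sum <- vapply(seq_along(cps), function(ci) {
    pv <- scales[[ci]]
    pv[states[root, cps[[ci]]$site_a]] + pv[states[root, cps[[ci]]$site_b]]
  }, numeric(1))

  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    st <- states[par, ]
    if (length(free_sites) > 0L) {
      nev <- stats::rpois(length(free_sites), len * rate)
      hit <- which(nev > 0L)
      if (length(hit) > 0L) {
        st[free_sites[hit]] <- sample.int(20L, length(hit), replace = TRUE)
      }
    }
    for (ci in seq_along(cps)) {
      cp <- cps[[ci]]; pv <- scales[[ci]]
      ## draw a residue whose property value lands within tolerance of
      ## `target` (widened to the nearest residue when none qualifies)
      draw_comp <- function(target) {
        cand <- which(abs(pv - target) <= cp$tolerance)
        if (length(cand) == 0L) {
          cand <- which.min(abs(pv - target))
          n_widened <<- n_widened + 1L
        }
        if (length(cand) > 1L) sample(cand, 1L) else cand
      }
      ## site_b's own substitution process: with probability rho the draw is
      ## itself sum-conserving, so at rho = 1 (tight tolerance) the pair's
      ## property sum is conserved along every branch
      for (ev in seq_len(stats::rpois(1L, len * rate))) {
        if (stats::runif(1L) < cp$rho) {
          st[cp$site_b] <- draw_comp(pair_sum[ci] - pv[st[cp$site_a]])
        } else {
          st[cp$site_b] <- sample.int(20L, 1L)
        }
      }
      ## site_a events, each triggering compensation at site_b w.p. rho
      for (ev in seq_len(stats::rpois(1L, len * rate))) {
        new_a <- sample.int(20L, 1L)
        st[cp$site_a] <- new_a
        if (stats::runif(1L) < cp$rho) {
          st[cp$site_b] <- draw_comp(pair_sum[ci] - pv[new_a])
        }
      }
    }
    states[child, ] <- st
  }

  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                function(s) paste(AA20[s], collapse = ""))
  aln <- aa_alignment(seqs, ids = tree$tip.label, reference_id = reference_id)
  truth <- if (length(cfg$coupled_pairs) > 0L) {
    data.frame(
      site_a = vapply(cfg$coupled_pairs, `[[`, integer(1), "site_a"),
      site_b = vapply(cfg$coupled_pairs, `[[`, integer(1), "site_b"),
      rho = vapply(cfg$coupled_pairs, `[[`, numeric(1), "rho"),
      property = vapply(cfg$coupled_pairs, `[[`, character(1), "property"),
      tolerance = vapply(cfg$coupled_pairs, `[[`, numeric(1), "tolerance"))
  } else {
    data.frame(site_a = integer(0), site_b = integer(0), rho = numeric(0),
               property = character(0), tolerance = numeric(0))
  }
  structure(list(alignment = aln, truth = truth, tree = tree,
                 n_widened = n_widened),
            class = "sim_alignment")
}

#' Simulate a pair of families with shared per-branch rates
#'
#' Both families evolve on the same topology; each branch of family A gets a
#' log-normal rate multiplier `m_A`, and family B's multiplier is
#' `m_B = m_A^s * exp((1 - s) * eps)` with independent noise
#' `eps ~ N(0, sdlog^2)`. At `s = 1` the multipliers are identical (maximal
#' mirrortree correlation); at `s = 0` they are independent. The expected
#' mirrortree correlation between the families increases monotonically with
#' `s`.
#'
#' @param tree A `phylo` from [simulate_tree()].
#' @param s Rate-sharing parameter in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param length Alignment length per family (default 300 columns).
#' @param base_rate Substitution rate (default 1).
#' @param sdlog Log-sd of the branch rate multipliers (default 0.6).
#' @return List of class `sim_family_pair`: `A`, `B` ([aa_alignment()]s),
#'   `m_A`, `m_B` (per-branch multipliers), `s`, `tree`.
#' @export
simulate_family_pair <- function(tree, s, seed = NULL, length = 300L,
                                 base_rate = 1, sdlog = 0.6) {
  if (s < 0 || s > 1) stop("s must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ne <- nrow(tree$edge)
  log_mA <- stats::rnorm(ne, 0, sdlog)
  eps <- stats::rnorm(ne, 0, sdlog)
  log_mB <- s * log_mA + (1 - s) * eps
  treeA <- tree; treeA$edge.length <- tree$edge.length * exp(log_mA)
  treeB <- tree; treeB$edge.length <- tree$edge.length * exp(log_mB)
  cfg <- sim_config(n_taxa = ape::Ntip(tree), length = length,
                    base_rate = base_rate)
  A <- simulate_alignment(treeA, cfg)$alignment
  B <- simulate_alignment(treeB, cfg)$alignment
  structure(list(A = A, B = B, m_A = exp(log_mA), m_B = exp(log_mB),
                 s = s, tree = tree),
            class = "sim_family_pair")
}

#' Write a simulation's ground truth as TSV
#'
#' @param sim A `sim_alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
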