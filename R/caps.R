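## CAPS-style coevolution engine.  For each alignment column, every sequence
## pair (i, j) contributes a substitution score for the observed residue pair,
## corrected by the pair's divergence time; two columns coevolve when their
## corrected scores covary across sequence pairs.  Two corrections are
## carried per column:
##   * the classical rate ratio theta_k = B(a_i, a_j) / t(i, j) and its
##     squared deviations D_k = (theta_k - mean(theta))^2, kept as
##     descriptors (theta is dominated by a 1/t factor shared by all
##     columns, so D profiles of unrelated columns correlate strongly);
##   * the residual of the self-match-normalised score
##     B'(a, b) = B(a, b) - [B(a, a) + B(b, b)] / 2 after regressing out a
##     quadratic trend in t -- the statistic the scan correlates, because it
##     removes both the shared divergence trend and the diagonal-score noise.

## Unordered sequence pairs (i < j), row-major.
seq_pairs <- function(n) {
  if (n < 2L) stop("need >=2 records")
  t(utils::combn(n, 2L))
}

## B'(a, b) = B(a, b) - [B(a, a) + B(b, b)] / 2: 0 on the diagonal, negative
## for substitutions in proportion to their severity.
normalize_submat <- function(S) {
  d <- diag(S)
  Sn <- S - (d %o% rep(1, length(d)) + rep(1, length(d)) %o% d) / 2
  dimnames(Sn) <- dimnames(S)
  Sn
}

#' Pairwise divergence times of an alignment
#'
#' Divergence time between two sequences is their Poisson-corrected
#' amino-acid distance over jointly valid columns (pairwise deletion).
#' Identical pairs get `t = 0` and saturated pairs (p = 1) get `t = Inf`
#' (with a warning); both are excluded from all downstream
#' substitution-score computations.
#'
#' @param aln An [aa_alignment()] with at least 4 records.
#' @return Symmetric matrix of divergence times, zero diagonal.
#' @export
divergence_times <- function(aln) {
  if (n_records(aln) < 4L) stop("need >=4 records")
  p <- pairwise_mismatch(aln)
  if (any(is.na(p))) stop("no comparable sites for some sequence pair")
  if (any(p >= 1)) {
    warning(sum(p >= 1 & upper.tri(p)),
            " saturated sequence pair(s) excluded (p = 1)")
  }
  t <- -log(1 - p)  # Inf where saturated
  diag(t) <- 0
  t
}

#' Substitution-score profile of one column
#'
#' @param aln An [aa_alignment()].
#' @param column 1-based alignment column.
#' @param S Substitution matrix (default [blosum62()]).
#' @param t Divergence-time matrix from [divergence_times()].
#' @return List of class `caps_site_profile` with vectors over the
#'   n(n-1)/2 sequence pairs (`NA` for excluded pairs): `theta`
#'   (`B(a_i, a_j) / t(i, j)`), `D` (squared deviations of `theta` from its
#'   mean over included pairs), `resid` (time-corrected normalised score
#'   residuals used by [caps_scan()]), plus `included` (logical mask),
#'   `column` and `pairs` (the i<j index matrix). Pairs with a gap/`X` at
#'   the column or zero divergence time are excluded.
#' @export
caps_profile <- function(aln, column, S = blosum62(), t = divergence_times(aln)) {
  if (column < 1L || column > alignment_length(aln)) {
    stop("column out of range: ", column)
  }
  P <- seq_pairs(n_records(aln))
  prof <- column_profile(aln$mat[, column], P, S, normalize_submat(S), t)
  structure(c(list(column = column), prof, list(pairs = P)),
            class = "caps_site_profile")
}

## Core per-column computation for a residue vector.
column_profile <- function(res, P, S, Sn, t) {
  a <- res[P[, 1L]]
  b <- res[P[, 2L]]
  tv <- t[P]
  ok <- !(a %in% GAP_CHARS) & !(b %in% GAP_CHARS) & tv > 0 & is.finite(tv)
  theta <- D <- resid <- rep(NA_real_, nrow(P))
  m <- sum(ok)
  if (m > 0L) {
    th <- S[cbind(a[ok], b[ok])] / tv[ok]
    theta[ok] <- th
    D[ok] <- (th - mean(th))^2
    y <- Sn[cbind(a[ok], b[ok])]
    x <- tv[ok]
    if (m >= 4L) {
      fit <- stats::.lm.fit(cbind(1, x, x * x), y)
      resid[ok] <- fit$residuals
    } else {
      resid[ok] <- y - mean(y)
    }
  }
  list(theta = theta, D = D, resid = resid, included = ok)
}

## Residual-profile matrix for all columns: n_pairs x L, NA for excluded
## pairs.  Usable columns have >= min_pairs included pairs and non-zero
## residual variance.
caps_resid_matrix <- function(aln, S, t, min_pairs = 3L) {
  n <- n_records(aln)
  L <- alignment_length(aln)
  P <- seq_pairs(n)
  Sn <- normalize_submat(S)
  M <- matrix(NA_real_, nrow(P), L)
  usable <- logical(L)
  for (j in seq_len(L)) {
    prof <- column_profile(aln$mat[, j], P, S, Sn, t)
    M[, j] <- prof$resid
    m <- sum(prof$included)
    usable[j] <- m >= min_pairs &&
      isTRUE(stats::var(prof$resid[prof$included]) > 0)
  }
  list(M = M, usable = which(usable), pairs = P, Sn = Sn)
}

#' Scan an alignment for coevolving site pairs (CAPS statistic)
#'
#' Computes the coevolution correlation `r_coev` -- the product-moment
#' correlation of the two columns' time-corrected substitution-score
#' residuals over jointly included sequence pairs -- for every usable column
#' pair. Two null constructions are available:
#'
#' * `"column_sample"` (default): `n_resample` random draws of distinct
#'   usable column pairs from the observed alignment; under independence of
#'   columns the tested pairs are themselves draws from this null, so the
#'   test is self-calibrating even though sequences share a phylogeny.
#' * `"permutation"`: residues of two random usable columns are
#'   independently permuted across sequences and the permuted profiles
#'   correlated; this breaks the shared-tree structure and is therefore more
#'   powerful but anticonservative on phylogenetically structured data.
#'
#' A pair is significant when `r_coev >= min_R` and `r_coev` exceeds the
#' `1 - alpha` quantile of the null. Significant pairs are joined into
#' coevolution groups (connected components); groups larger than
#' `ceil(group_cap * protein length)` are flagged. For significant pairs the
#' compensatory-substitution correlations in hydrophobicity and molecular
#' weight are reported (see [compensation_correlations()]).
#'
#' @param aln An [aa_alignment()] with at least 4 records.
#' @param S Substitution matrix (default [blosum62()]).
#' @param n_resample Number of null resampling draws (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param min_R Minimum coevolution correlation to report a pair (default
#'   0.1).
#' @param group_cap Maximum group size as a fraction of the protein length
#'   (default 0.05); larger groups are flagged, not truncated.
#' @param seed Optional integer seed for the resampling null.
#' @param null_method `"column_sample"` or `"permutation"` (see above).
#' @return Object of class `caps_result`: `pairs` (data frame with `site1`,
#'   `site2` in reference numbering where available, `col1`, `col2`,
#'   `r_coev`, `significant`, `r_hydro`, `r_mw`), `groups` (list of site
#'   vectors), `group_flagged` (logical, `TRUE` where a group exceeds the
#'   cap), `null_quantile`, `null_r`, `usable_columns`.
#' @export
caps_scan <- function(aln, S = blosum62(), n_resample = 1000L, alpha = 0.05,
                      min_R = 0.1, group_cap = 0.05, seed = NULL,
                      null_method = c("column_sample", "permutation")) {
  null_method <- match.arg(null_method)
  if (n_records(aln) < 4L) stop("need >=4 records")
  if (!is.null(seed)) set.seed(seed)
  tmat <- divergence_times(aln)
  rm_ <- caps_resid_matrix(aln, S, tmat)
  if (length(rm_$usable) < 2L) stop("insufficient variability")

  Mu <- rm_$M[, rm_$usable, drop = FALSE]
  R <- suppressWarnings(stats::cor(Mu, use = "pairwise.complete.obs"))

  null_r <- if (null_method == "column_sample") {
    null_column_sample(R, n_resample)
  } else {
    null_permutation(aln$mat, rm_$usable, rm_$pairs, S, rm_$Sn, tmat,
                     n_resample)
  }
  qthr <- stats::quantile(null_r, 1 - alpha, na.rm = TRUE, names = FALSE)

  cols <- rm_$usable
  sites <- column_to_site(aln, cols)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  pairs <- data.frame(
    site1 = sites[idx[, 1L]], site2 = sites[idx[, 2L]],
    col1 = cols[idx[, 1L]], col2 = cols[idx[, 2L]],
    r_coev = R[idx])
  pairs$significant <- !is.na(pairs$r_coev) &
    pairs$r_coev >= min_R & pairs$r_coev >= qthr

  pairs$r_hydro <- NA_real_
  pairs$r_mw <- NA_real_
  sig <- which(pairs$significant)
  for (k in sig) {
    cc <- compensation_correlations(aln, pairs$col1[k], pairs$col2[k],
                                    alpha = alpha)
    pairs$r_hydro[k] <- cc$r_hydro
    pairs$r_mw[k] <- cc$r_mw
  }

  plen <- protein_length(aln)
  grp <- coevolution_groups(pairs[sig, , drop = FALSE],
                            cap = ceiling(group_cap * plen))
  structure(list(pairs = pairs, groups = grp$groups,
                 group_flagged = grp$flagged, null_quantile = qthr,
                 null_r = null_r, usable_columns = cols,
                 alpha = alpha, min_R = min_R, null_method = null_method),
            class = "caps_result")
}

## Null r draws: random distinct usable column pairs of the observed
## alignment (their correlations are already in R).
null_column_sample <- function(R, n_resample) {
  m <- nrow(R)
  j1 <- sample.int(m, n_resample, replace = TRUE)
  j2 <- sample.int(m - 1L, n_resample, replace = TRUE)
  j2 <- ifelse(j2 >= j1, j2 + 1L, j2)
  R[cbind(j1, j2)]
}

## Null r draws: within-column permutation of residues + random column
## pairing.
null_permutation <- function(mat, usable, P, S, Sn, t, n_resample) {
  n <- nrow(mat)
  vapply(seq_len(n_resample), function(b) {
    jk <- if (length(usable) == 2L) usable else sample(usable, 2L)
    d1 <- column_profile(mat[sample(n), jk[1L]], P, S, Sn, t)$resid
    d2 <- column_profile(mat[sample(n), jk[2L]], P, S, Sn, t)$resid
    suppressWarnings(stats::cor(d1, d2, use = "pairwise.complete.obs"))
  }, numeric(1))
}

## Columns -> reference residue numbering when a reference exists (NA for
## columns gapped in the reference), else the column index itself.
column_to_site <- function(aln, cols) {
  if (is.null(aln$reference_id)) return(cols)
  build_column_map(aln)$col_to_ref[cols]
}

## Ungapped reference length if a reference is set, else alignment length.
protein_length <- function(aln) {
  if (is.null(aln$reference_id)) return(alignment_length(aln))
  sum(aln$mat[aln$reference_id, ] != "-")
}

## Connected components of significant pairs (site labels).
coevolution_groups <- function(sig_pairs, cap) {
  if (nrow(sig_pairs) == 0L) return(list(groups = list(), flagged = logical(0)))
  lab1 <- ifelse(is.na(sig_pairs$site1), paste0("col", sig_pairs$col1),
                 as.character(sig_pairs$site1))
  lab2 <- ifelse(is.na(sig_pairs$site2), paste0("col", sig_pairs$col2),
                 as.character(sig_pairs$site2))
  g <- igraph::graph_from_edgelist(cbind(lab1, lab2), directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  names(groups) <- NULL
  flagged <- vapply(groups, function(gg) length(gg) > cap, logical(1))
  list(groups = groups, flagged = flagged)
}

#' @export
print.caps_result <- function(x, ...) {
  cat(sprintf(
    "caps_result: %d usable columns, %d tested pairs, %d significant, %d groups\n",
    length(unlist(x$usable_columns)), nrow(x$pairs),
    sum(x$pairs$significant), length(x$groups)))
  invisible(x)
}

#' Compensatory-substitution correlations between two sites
#'
#' For every included sequence pair (i, j), i < j in record order, the signed
#' property difference `p(a_i) - p(a_j)` is computed at each site; the
#' compensation correlation is the product-moment correlation of the two
#' difference vectors. A value is reported only when it passes a two-sided
#' critical-value test at `alpha`; non-significant correlations are returned
#' as `NA` (rendered `"No"` in TSV output).
#'
#' @param aln An [aa_alignment()].
#' @param site1,site2 1-based alignment columns.
#' @param hydro,mw Property scales for hydrophobicity and molecular weight.
#' @param alpha Two-sided significance level (default 0.05).
#' @param aln2 Optional second alignment carrying `site2` (for
#'   intermolecular pairs); record order must match `aln`.
#' @return List with `r_hydro` and `r_mw` (`NA` when non-significant or
#'   undefined) and attributes `raw_hydro`, `raw_mw` carrying the unfiltered
#'   correlations.
#' @export
compensation_correlations <- function(aln, site1, site2,
                                      hydro = aa_scale("hydrophobicity"),
                                      mw = aa_scale("mw"), alpha = 0.05,
                                      aln2 = NULL) {
  if (is.null(aln2)) aln2 <- aln
  if (n_records(aln) != n_records(aln2)) {
    stop("alignments must have matching records")
  }
  P <- seq_pairs(n_records(aln))
  ## the n(n-1)/2 sequence pairs are not independent observations; the
  ## critical value uses the number of sequences as the effective sample size
  n_eff <- n_records(aln)
  comp_one <- function(scale) {
    d1 <- pair_property_diff(aln$mat[, site1], P, scale)
    d2 <- pair_property_diff(aln2$mat[, site2], P, scale)
    ok <- !is.na(d1) & !is.na(d2)
    m <- sum(ok)
    if (m < 3L) return(c(NA_real_, NA_real_))
    if (stats::var(d1[ok]) <= 0 || stats::var(d2[ok]) <= 0) {
      return(c(NA_real_, NA_real_))
    }
    r <- stats::cor(d1[ok], d2[ok])
    rc <- r_critical(n_eff, 1 - alpha)
    c(r, rc)
  }
  h <- comp_one(hydro)
  w <- comp_one(mw)
  keep <- function(v) if (!is.na(v[1L]) && !is.na(v[2L]) && abs(v[1L]) > v[2L])
    v[1L] else NA_real_
  structure(list(r_hydro = keep(h), r_mw = keep(w)),
            raw_hydro = h[1L], raw_mw = w[1L])
}

## Signed property difference p(a_i) - p(a_j) per sequence pair.
pair_property_diff <- function(res, P, scale) {
  v <- unname(scale[res])
  v[P[, 1L]] - v[P[, 2L]]
}

#' Intermolecular CAPS scan between two families
#'
#' Runs the CAPS statistic across molecules: divergence times are computed
#' per family, sequence pairs are indexed identically after restricting both
#' alignments to the shared species, and every usable column of family A is
#' tested against every usable column of family B. The `"column_sample"`
#' null draws random cross-family column pairs; `"permutation"` permutes
#' residues within columns of both families before pairing.
#'
#' @param alnA,alnB [aa_alignment()]s of the two families.
#' @param species_map Optional named character vector translating record ids
#'   of `alnA` to record ids of `alnB`; by default records are matched by
#'   identical ids.
#' @param S Substitution matrix (default [blosum62()]).
#' @param n_resample,alpha,min_R Null-distribution and threshold parameters
#'   as in [caps_scan()].
#' @param seed Optional integer seed.
#' @param null_method `"column_sample"` or `"permutation"`.
#' @return Object of class `caps_result` whose `pairs` have `site1` in A's
#'   reference numbering and `site2` in B's; groups are the bipartite
#'   connected components of significant pairs.
#' @export
caps_intermolecular <- function(alnA, alnB, species_map = NULL,
                                S = blosum62(), n_resample = 1000L,
                                alpha = 0.05, min_R = 0.1, seed = NULL,
                                null_method = c("column_sample", "permutation")) {
  null_method <- match.arg(null_method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(species_map)) {
    shared <- intersect(alnA$ids, alnB$ids)
    if (length(shared) < 4L) stop("unmatched species sets")
    idsA <- shared; idsB <- shared
  } else {
    idsA <- intersect(alnA$ids, names(species_map))
    idsA <- idsA[species_map[idsA] %in% alnB$ids]
    if (length(idsA) < 4L) stop("unmatched species sets")
    idsB <- unname(species_map[idsA])
  }
  A <- subset_alignment(alnA, records = idsA)
  B <- subset_alignment(alnB, records = idsB)

  tA <- divergence_times(A)
  tB <- divergence_times(B)
  rA <- caps_resid_matrix(A, S, tA)
  rB <- caps_resid_matrix(B, S, tB)
  if (length(rA$usable) < 1L || length(rB$usable) < 1L) {
    stop("insufficient variability")
  }

  MA <- rA$M[, rA$usable, drop = FALSE]
  MB <- rB$M[, rB$usable, drop = FALSE]
  R <- suppressWarnings(stats::cor(MA, MB, use = "pairwise.complete.obs"))

  null_r <- if (null_method == "column_sample") {
    ja <- sample.int(nrow(R), n_resample, replace = TRUE)
    jb <- sample.int(ncol(R), n_resample, replace = TRUE)
    R[cbind(ja, jb)]
  } else {
    nA <- n_records(A)
    vapply(seq_len(n_resample), function(b) {
      ja <- if (length(rA$usable) == 1L) rA$usable else sample(rA$usable, 1L)
      jb <- if (length(rB$usable) == 1L) rB$usable else sample(rB$usable, 1L)
      d1 <- column_profile(A$mat[sample(nA), ja], rA$pairs, S, rA$Sn, tA)$resid
      d2 <- column_profile(B$mat[sample(nA), jb], rB$pairs, S, rB$Sn, tB)$resid
      suppressWarnings(stats::cor(d1, d2, use = "pairwise.complete.obs"))
    }, numeric(1))
  }
  qthr <- stats::quantile(null_r, 1 - alpha, na.rm = TRUE, names = FALSE)

  sitesA <- column_to_site(A, rA$usable)
  sitesB <- column_to_site(B, rB$usable)
  grid <- expand.grid(a = seq_along(rA$usable), b = seq_along(rB$usable))
  pairs <- data.frame(
    site1 = sitesA[grid$a], site2 = sitesB[grid$b],
    col1 = rA$usable[grid$a], col2 = rB$usable[grid$b],
    r_coev = R[cbind(grid$a, grid$b)])
  pairs$significant <- !is.na(pairs$r_coev) &
    pairs$r_coev >= min_R & pairs$r_coev >= qthr

  pairs$r_hydro <- NA_real_
  pairs$r_mw <- NA_real_
  for (k in which(pairs$significant)) {
    cc <- compensation_correlations(A, pairs$col1[k], pairs$col2[k],
                                    alpha = alpha, aln2 = B)
    pairs$r_hydro[k] <- cc$r_hydro
    pairs$r_mw[k] <- cc$r_mw
  }

  sig <- pairs[pairs$significant, , drop = FALSE]
  grp <- list(groups = list(), flagged = logical(0))
  if (nrow(sig) > 0L) {
    lab1 <- paste0("A:", ifelse(is.na(sig$site1), paste0("col", sig$col1),
                                sig$site1))
    lab2 <- paste0("B:", ifelse(is.na(sig$site2), paste0("col", sig$col2),
                                sig$site2))
    g <- igraph::graph_from_edgelist(cbind(lab1, lab2), directed = FALSE)
    comp <- igraph::components(g)
    groups <- split(names(comp$membership), comp$membership)
    names(groups) <- NULL
    grp <- list(groups = groups, flagged = rep(FALSE, length(groups)))
  }
  structure(list(pairs = pairs, groups = grp$groups,
                 group_flagged = grp$flagged, null_quantile = qthr,
                 null_r = null_r,
                 usable_columns = list(A = rA$usable, B = rB$usable),
                 alpha = alpha, min_R = min_R, null_method = null_method),
            class = "caps_result")
}

#' Write significant CAPS pairs as TSV
#'
#' Mirrors the layout Site1, Site2, coevolution correlation, hydrophobicity
#' correlation, molecular-weight correlation; non-significant compensation
#' correlations are rendered `"No"`.
#'
#' @param x A `caps_result`.
#' @param path Output path.
#' @param all_pairs Write all tested pairs rather than significant only.
#' @return Invisibly, `path`.
#' @export
write_caps_tsv <- function(x, path, all_pairs = FALSE) {
  tab <- if (all_pairs) x$pairs else x$pairs[x$pairs$significant, , drop = FALSE]
  fmt <- function(v) ifelse(is.na(v), "No", formatC(v, digits = 4, format = "f"))
  out <- data.frame(
    Site1 = tab$site1, Site2 = tab$site2,
    Coevolution_correlation = formatC(tab$r_coev, digits = 4, format = "f"),
    Hydrophobicities_correlation = fmt(tab$r_hydro),
    Molecular_weights_correlation = fmt(tab$r_mw))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write coevolution groups as TSV
#'
#' @param x A `caps_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_caps_groups_tsv <- function(x, path) {
  if (length(x$groups) == 0L) {
    out <- data.frame(group = integer(0), sites = character(0),
                      size = integer(0), oversize = logical(0))
  } else {
    out <- data.frame(
      group = seq_along(x$groups),
      sites = vapply(x$groups, paste, character(1), collapse = ","),
      size = lengths(x$groups),
      oversize = x$group_flagged)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
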