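## Covariation engine: correlated physicochemical substitutions between
## alignment columns.  Each column is mapped to per-record property values
## (gaps/'X' masked); pairs of sufficiently variable columns are tested by a
## weighted product-moment correlation, with Vingron-Argos sequence weights
## and an effective-sample-size critical-value test.

#' Vingron--Argos sequence weights
#'
#' Each record's weight is proportional to the sum of its pairwise distances
#' (fraction of mismatching, jointly valid columns) to all other records, so
#' redundant near-duplicate sequences are down-weighted. Weights are
#' normalised to sum to one; a set of identical sequences gets uniform
#' weights.
#'
#' @param aln An [aa_alignment()] with at least two records.
#' @return Numeric vector of weights, named by record id, summing to 1.
#' @export
vingron_argos_weights <- function(aln) {
  n <- n_records(aln)
  if (n < 2L) stop("need >=2 sequences")
  d <- pairwise_mismatch(aln)
  w <- rowSums(d, na.rm = TRUE)
  if (sum(w) <= 0) {
    w <- rep(1 / n, n)
  } else {
    w <- w / sum(w)
  }
  stats::setNames(w, aln$ids)
}

## Pairwise fraction of mismatching columns over jointly valid
## (non-gap, non-'X') positions.  NA where two records share no valid column.
pairwise_mismatch <- function(aln) {
  n <- n_records(aln)
  ok <- valid_mask(aln)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- ok[i, ] & ok[j, ]
      ns <- sum(shared)
      d[i, j] <- d[j, i] <- if (ns == 0L) NA_real_ else
        sum(aln$mat[i, shared] != aln$mat[j, shared]) / ns
    }
  }
  d
}

#' Property values of one alignment column
#'
#' Looks up the property value of each record's residue at a column; gaps and
#' `X` yield `NA` (missing).
#'
#' @param aln An [aa_alignment()].
#' @param column 1-based alignment column.
#' @param scale Named numeric property scale (see [aa_scale()]).
#' @return Numeric vector, one value per record (`NA` = masked), named by id.
#' @export
position_property_values <- function(aln, column, scale) {
  if (column < 1L || column > alignment_length(aln)) {
    stop("column out of range: ", column)
  }
  res <- aln$mat[, column]
  v <- unname(scale[res])   # gap/'X' are absent from the scale -> NA
  stats::setNames(as.numeric(v), aln$ids)
}

#' Weighted product-moment correlation with missing-data masking
#'
#' Weights are renormalised over the jointly unmasked records before the
#' weighted Pearson correlation is computed.
#'
#' @param x,y Numeric vectors (`NA` = masked).
#' @param w Nonnegative weights, same length.
#' @return The correlation, in `[-1, 1]`, with attributes `n_eff` (effective
#'   sample size `1 / sum(w_joint^2)`) and `n` (number of jointly unmasked
#'   records). `NA` if fewer than 3 joint records or either side has zero
#'   weighted variance (a "constant position").
#' @examples
#' weighted_correlation(c(1, 2, 3), c(1, 3, 2), rep(1 / 3, 3))  # 0.5
#' @export
weighted_correlation <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(w) == length(x))
  keep <- !is.na(x) & !is.na(y)
  n <- sum(keep)
  if (n < 3L) return(structure(NA_real_, n_eff = NA_real_, n = n))
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    return(structure(NA_real_, n_eff = 1 / sum(w^2), n = n))
  }
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  structure(max(-1, min(1, r)), n_eff = 1 / sum(w^2), n = n)
}

## Two-sided critical value of the product-moment correlation at the given
## confidence, using df = n_eff - 2 (t approximation).
r_critical <- function(n_eff, confidence) {
  df <- n_eff - 2
  if (is.na(df) || df <= 0) return(NA_real_)
  tc <- stats::qt(1 - (1 - confidence) / 2, df)
  tc / sqrt(df + tc^2)
}

#' Scan all column pairs for correlated physicochemical substitutions
#'
#' Tests every unordered pair of sufficiently variable columns for a weighted
#' correlation of property values. A column enters the scan when it carries at
#' least `variability_min` distinct amino acids among unmasked records. A pair
#' is significant when `|r|` exceeds the two-sided critical value of the
#' product-moment correlation at the requested confidence, with degrees of
#' freedom derived from the effective sample size `1 / sum(w^2)` of the
#' renormalised joint weights (so duplicated sequences do not inflate
#' significance).
#'
#' @param aln An [aa_alignment()].
#' @param scale Property scale (see [aa_scale()]).
#' @param confidence Confidence level of the two-sided test (default 0.99).
#' @param variability_min Minimum number of distinct amino acids per column
#'   (default 3).
#' @param weights Optional precomputed sequence weights; defaults to
#'   [vingron_argos_weights()].
#' @return An object of class `covariation_result`: list with `pairs` (data
#'   frame `pos1`, `pos2`, `r`, `n_eff`, `significant`, `sign`), `r_matrix`
#'   (symmetric correlation matrix over analysed positions), `positions`
#'   (reference residue indices, or columns if no reference), `columns`,
#'   `weights`, `confidence` and `scale_name`. Positions are reported in
#'   reference numbering when the alignment has a reference record.
#' @export
covariation_scan <- function(aln, scale = aa_scale("volume"),
                             confidence = 0.99, variability_min = 3L,
                             weights = NULL) {
  n <- n_records(aln)
  L <- alignment_length(aln)
  if (is.null(weights)) weights <- vingron_argos_weights(aln)
  scale_name <- attr(scale, "scale_name")
  if (is.null(scale_name)) scale_name <- "custom"

  ok <- valid_mask(aln)
  n_distinct <- vapply(seq_len(L), function(j) {
    length(unique(aln$mat[ok[, j], j]))
  }, integer(1))
  cols <- which(n_distinct >= variability_min)

  ## column -> reference numbering where available
  positions <- cols
  if (!is.null(aln$reference_id)) {
    cmap <- build_column_map(aln)
    positions <- cmap$col_to_ref[cols]
    keep <- !is.na(positions)  # columns gapped in the reference are dropped
    cols <- cols[keep]
    positions <- positions[keep]
  }
  m <- length(cols)
  if (m == 0L) {
    warning("no position passes the variability filter")
    empty <- data.frame(pos1 = integer(0), pos2 = integer(0), r = numeric(0),
                        n_eff = numeric(0), significant = logical(0),
                        sign = character(0))
    return(structure(list(pairs = empty, r_matrix = matrix(numeric(0), 0, 0),
                          positions = integer(0), columns = integer(0),
                          weights = weights, confidence = confidence,
                          scale_name = scale_name),
                     class = "covariation_result"))
  }

  vals <- vapply(cols, function(j) unname(scale[aln$mat[, j]]), numeric(n))
  vals <- matrix(as.numeric(vals), nrow = n)

  rmat <- matrix(NA_real_, m, m, dimnames = list(positions, positions))
  diag(rmat) <- 1
  pairs <- vector("list", m * (m - 1L) / 2L)
  k <- 0L
  for (a in seq_len(m - 1L)) {
    for (b in seq.int(a + 1L, m)) {
      r <- weighted_correlation(vals[, a], vals[, b], weights)
      n_eff <- attr(r, "n_eff")
      rc <- r_critical(n_eff, confidence)
      rv <- as.numeric(r)
      rmat[a, b] <- rmat[b, a] <- rv
      k <- k + 1L
      pairs[[k]] <- data.frame(
        pos1 = positions[a], pos2 = positions[b], r = rv, n_eff = n_eff,
        significant = !is.na(rv) && !is.na(rc) && abs(rv) > rc,
        sign = if (is.na(rv)) NA_character_ else
          if (rv >= 0) "positive" else "negative")
    }
  }
  pairs <- do.call(rbind, pairs)
  structure(list(pairs = pairs, r_matrix = rmat, positions = positions,
                 columns = cols, weights = weights, confidence = confidence,
                 scale_name = scale_name),
            class = "covariation_result")
}

#' @export
print.covariation_result <- function(x, ...) {
  cat(sprintf(
    "covariation_result (%s): %d positions, %d tested pairs, %d significant\n",
    x$scale_name, length(x$positions), nrow(x$pairs),
    sum(x$pairs$significant, na.rm = TRUE)))
  invisible(x)
}

#' Cluster analysed positions by their correlation profile
#'
#' Agglomerative (average-linkage) clustering with similarity equal to the
#' pairwise correlation; the merge tree is annotated with the correlation at
#' which children join, and flat clusters are obtained by cutting at the
#' similarity cutoff.
#'
#' @param x A `covariation_result` or a symmetric correlation matrix with
#'   positions as dimnames.
#' @param cutoff Similarity cutoff for flat clusters (default 0.55).
#' @return List of class `position_clusters`: `tree` (an [stats::hclust]),
#'   `merge_r` (correlation at each merge, `1 - height`), `clusters` (named
#'   integer vector of cluster labels) and `newick` (the merge tree as a
#'   Newick string with merge correlations as internal node labels).
#' @export
cluster_positions <- function(x, cutoff = 0.55) {
  rmat <- if (inherits(x, "covariation_result")) x$r_matrix else as.matrix(x)
  if (nrow(rmat) < 2L) stop("need >=2 positions to cluster")
  rmat[is.na(rmat)] <- 0  # untestable pairs treated as uncorrelated
  d <- stats::as.dist(1 - rmat)
  tree <- stats::hclust(d, method = "average")
  merge_r <- 1 - tree$height
  clusters <- stats::cutree(tree, h = 1 - cutoff)
  phy <- annotate_merge_r(tree)
  structure(list(tree = tree, merge_r = merge_r, clusters = clusters,
                 cutoff = cutoff,
                 newick = ape::write.tree(phy)),
            class = "position_clusters")
}

## Convert an hclust tree to phylo with node labels = merge correlation.
annotate_merge_r <- function(tree) {
  phy <- ape::as.phylo(tree)
  nh <- ape::node.depth.edgelength(phy)
  root_h <- max(nh)
  internal <- (ape::Ntip(phy) + 1L):(ape::Ntip(phy) + phy$Nnode)
  ## height of internal node above the leaves = root_h - depth; merge
  ## similarity r = 1 - height
  h <- root_h - nh[internal]
  phy$node.label <- formatC(1 - h, digits = 4, format = "f")
  phy
}

#' @export
print.position_clusters <- function(x, ...) {
  cat(sprintf("position_clusters: %d positions, %d clusters at cutoff %.2f\n",
              length(x$clusters), max(x$clusters), x$cutoff))
  invisible(x)
}

#' Cross-tabulate significant covariation pairs by domain
#'
#' Counts significant pairs in each domain-by-domain cell, split by the sign
#' of the correlation. Positions outside every domain are counted under
#' `"unassigned"`.
#'
#' @param x A `covariation_result` or its `pairs` data frame.
#' @param domains Named list of [domain_annotation()]s.
#' @return List of class `domain_pair_summary` with integer matrices
#'   `positive`, `negative` and `total` (symmetric, domains as dimnames).
#' @export
domain_pair_summary <- function(x, domains) {
  pairs <- if (inherits(x, "covariation_result")) x$pairs else x
  dnames <- c(vapply(domains, `[[`, character(1), "name"), "unassigned")
  zero <- matrix(0L, length(dnames), length(dnames),
                 dimnames = list(dnames, dnames))
  pos <- zero; neg <- zero
  sig <- pairs[!is.na(pairs$significant) & pairs$significant, , drop = FALSE]
  if (nrow(sig) > 0L) {
    d1 <- assign_domain(sig$pos1, domains)
    d2 <- assign_domain(sig$pos2, domains)
    for (k in seq_len(nrow(sig))) {
      tgt <- if (sig$sign[k] == "positive") "pos" else "neg"
      if (tgt == "pos") {
        pos[d1[k], d2[k]] <- pos[d1[k], d2[k]] + 1L
        if (d1[k] != d2[k]) pos[d2[k], d1[k]] <- pos[d2[k], d1[k]] + 1L
      } else {
        neg[d1[k], d2[k]] <- neg[d1[k], d2[k]] + 1L
        if (d1[k] != d2[k]) neg[d2[k], d1[k]] <- neg[d2[k], d1[k]] + 1L
      }
    }
  }
  structure(list(positive = pos, negative = neg, total = pos + neg),
            class = "domain_pair_summary")
}

#' Write covariation pairs as TSV
#'
#' Columns: pos1, pos2, r, significant, sign and (when `domains` is given)
#' domain1, domain2.
#'
#' @param x A `covariation_result`.
#' @param path Output path.
#' @param domains Optional named list of [domain_annotation()]s.
#' @return Invisibly, `path`.
#' @export
write_covariation_tsv <- function(x, path, domains = NULL) {
  tab <- x$pairs[, c("pos1", "pos2", "r", "significant", "sign")]
  if (!is.null(domains)) {
    tab$domain1 <- assign_domain(tab$pos1, domains)
    tab$domain2 <- assign_domain(tab$pos2, domains)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
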