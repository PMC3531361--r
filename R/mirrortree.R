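## Mirrortree module: Poisson-corrected evolutionary distance matrices per
## protein/domain alignment and the correlation between matched matrices.
## The coevolution score of a ligand/receptor pair is the product-moment
## correlation of their interspecies distances over the N(N-1)/2 unordered
## species pairs.

#' Observed proportion of differing sites between two aligned sequences
#'
#' Columns where either sequence has a gap or `X` are excluded (pairwise
#' deletion).
#'
#' @param s1,s2 Gapped amino-acid strings of equal length.
#' @return Fraction of mismatching columns among jointly valid columns.
#' @export
p_distance <- function(s1, s2) {
  a <- strsplit(toupper(s1), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(s2), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("sequences of unequal length")
  ok <- !(a %in% GAP_CHARS) & !(b %in% GAP_CHARS)
  if (!any(ok)) stop("no comparable sites")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Poisson-corrected amino-acid distance between two aligned sequences
#'
#' Converts the observed mismatch proportion `p` into expected substitutions
#' per site under the Poisson correction `d = -ln(1 - p)`.
#'
#' @param s1,s2 Gapped amino-acid strings of equal length.
#' @return Distance in substitutions per site (`>= p`, equal iff `p = 0`).
#' @export
poisson_distance <- function(s1, s2) {
  poisson_correct(p_distance(s1, s2))
}

## p -> -ln(1-p); p = 1 is a saturated pair (infinite distance).
poisson_correct <- function(p) {
  if (any(p >= 1)) stop("saturated pair: p = 1")
  -log(1 - p)
}

#' Poisson-corrected pairwise distance matrix of an alignment
#'
#' @param aln An [aa_alignment()] with at least 3 records.
#' @param deletion `"pairwise"` (default): each pair is compared over its own
#'   jointly valid columns; `"complete"`: columns with any gap/`X` are dropped
#'   once for all pairs.
#' @return Symmetric numeric matrix (substitutions per site), zero diagonal,
#'   dimnames = record ids.
#' @export
distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (n_records(aln) < 3L) stop("need >=3 records")
  if (deletion == "complete") {
    keep <- apply(valid_mask(aln), 2L, all)
    if (!any(keep)) stop("no comparable sites under complete deletion")
    aln <- subset_alignment(aln, columns = which(keep))
  }
  p <- pairwise_mismatch(aln)
  if (any(is.na(p))) {
    bad <- which(is.na(p) & upper.tri(p), arr.ind = TRUE)[1L, ]
    stop("no comparable sites between ", aln$ids[bad[1L]], " and ",
         aln$ids[bad[2L]])
  }
  if (any(p >= 1)) {
    bad <- which(p >= 1 & upper.tri(p), arr.ind = TRUE)[1L, ]
    stop("saturated pair: ", aln$ids[bad[1L]], " vs ", aln$ids[bad[2L]])
  }
  d <- -log(1 - p)
  diag(d) <- 0
  d
}

## Upper-triangle (row-major, i < j) vectorisation of a symmetric matrix.
upper_vec <- function(m) t(m)[lower.tri(t(m))]

#' Mirrortree correlation between two matched distance matrices
#'
#' Computes the linear (Pearson) correlation between the interspecies
#' evolutionary distances of two families over the N(N-1)/2 unordered species
#' pairs, after aligning the matrices by species identifier:
#' \deqn{r = \frac{\sum_{i<j} (X_{ij} - \bar X)(Y_{ij} - \bar Y)}
#'            {\sqrt{\sum_{i<j} (X_{ij} - \bar X)^2}
#'             \sqrt{\sum_{i<j} (Y_{ij} - \bar Y)^2}}}
#' where \eqn{X_{ij}}, \eqn{Y_{ij}} are the distances between species i and j
#' in the two matrices and the means run over the same pairs.
#'
#' @param DX,DY Symmetric distance matrices with species ids as dimnames (as
#'   from [distance_matrix()]). The species sets must be identical; order may
#'   differ.
#' @param family_x,family_y Optional family names for reporting.
#' @return Object of class `mirrortree_result`: list with `r`, `n_species`,
#'   `n_pairs`, `family_x`, `family_y`.
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' mirrortree_r(d, d)$r  # 1
#' @export
mirrortree_r <- function(DX, DY, family_x = "X", family_y = "Y") {
  sx <- rownames(DX); sy <- rownames(DY)
  if (is.null(sx) || is.null(sy)) stop("distance matrices must carry species ids")
  if (!setequal(sx, sy)) stop("unmatched species")
  n <- length(sx)
  if (n < 3L) stop("need >=3 species")
  DY <- DY[sx, sx]
  x <- upper_vec(DX)
  y <- upper_vec(DY)
  dx <- x - mean(x); dy <- y - mean(y)
  ssx <- sum(dx^2); ssy <- sum(dy^2)
  if (ssx <= 0 || ssy <= 0) stop("degenerate matrix: zero variance")
  r <- sum(dx * dy) / sqrt(ssx * ssy)
  structure(list(r = max(-1, min(1, r)), n_species = n,
                 n_pairs = n * (n - 1L) / 2L,
                 family_x = family_x, family_y = family_y),
            class = "mirrortree_result")
}

#' @export
print.mirrortree_result <- function(x, ...) {
  cat(sprintf("mirrortree %s ~ %s: r = %.4f (N = %d species, %d pairs)\n",
              x$family_x, x$family_y, x$r, x$n_species, x$n_pairs))
  invisible(x)
}

#' Ligand-by-receptor mirrortree correlation table with a negative control
#'
#' Builds the full cross-table of mirrortree correlations between every
#' ligand form and every receptor form, appends the control protein as an
#' extra ligand column and receptor row, the per-receptor column means, and
#' flags every ligand/receptor pair whose correlation does not exceed both of
#' its control pairings (ligand~control and control~receptor).
#'
#' @param ligands Named list of [aa_alignment()]s (ligand forms).
#' @param receptors Named list of [aa_alignment()]s (receptor forms).
#' @param control Optional [aa_alignment()] of the negative-control family.
#' @param deletion Deletion policy passed to [distance_matrix()].
#' @param species_map Optional named list of per-family identifier maps; each
#'   element is a named character vector translating that family's record ids
#'   to the shared species labels.
#' @return Object of class `mirrortree_table`: list with `r` (matrix,
#'   receptors + control as rows, ligands + control as columns), `mean`
#'   (per-ligand mean over receptor rows), `exceeds_control` (logical matrix
#'   for the positive pairs; `NA` when no control was supplied) and
#'   `n_species`.
#' @export
correlation_table <- function(ligands, receptors, control = NULL,
                              deletion = "pairwise", species_map = NULL) {
  stopifnot(length(ligands) >= 1L, length(receptors) >= 1L)
  fams <- c(ligands, receptors)
  if (!is.null(control)) fams <- c(fams, list(control = control))
  if (is.null(names(fams)) || any(names(fams) == "")) {
    stop("ligand/receptor lists must be named")
  }
  dmats <- lapply(names(fams), function(nm) {
    d <- distance_matrix(fams[[nm]], deletion = deletion)
    if (!is.null(species_map) && !is.null(species_map[[nm]])) {
      mp <- species_map[[nm]]
      missing <- setdiff(rownames(d), names(mp))
      if (length(missing) > 0L) {
        stop("species map for ", nm, " missing ids: ",
             paste(missing, collapse = ", "))
      }
      dimnames(d) <- list(unname(mp[rownames(d)]), unname(mp[colnames(d)]))
    }
    d
  })
  names(dmats) <- names(fams)
  sp <- rownames(dmats[[1L]])
  for (d in dmats) {
    if (!setequal(rownames(d), sp)) stop("unmatched species across families")
  }

  lig_names <- names(ligands)
  rec_names <- names(receptors)
  col_names <- c(lig_names, if (!is.null(control)) "control")
  row_names <- c(rec_names, if (!is.null(control)) "control")
  r <- matrix(NA_real_, length(row_names), length(col_names),
              dimnames = list(row_names, col_names))
  for (rn in row_names) {
    for (cn in col_names) {
      if (rn == "control" && cn == "control") { r[rn, cn] <- 1; next }
      r[rn, cn] <- mirrortree_r(dmats[[cn]], dmats[[rn]],
                                family_x = cn, family_y = rn)$r
    }
  }
  means <- colMeans(r[rec_names, , drop = FALSE])

  exceeds <- matrix(NA, length(rec_names), length(lig_names),
                    dimnames = list(rec_names, lig_names))
  if (!is.null(control)) {
    for (rn in rec_names) {
      for (cn in lig_names) {
        exceeds[rn, cn] <- r[rn, cn] > max(r["control", cn], r[rn, "control"])
      }
    }
  }
  structure(list(r = r, mean = means, exceeds_control = exceeds,
                 n_species = length(sp)),
            class = "mirrortree_table")
}

#' @export
print.mirrortree_table <- function(x, ...) {
  cat(sprintf("mirrortree_table over %d species\n", x$n_species))
  print(round(x$r, 3))
  cat("means over receptor rows:\n")
  print(round(x$mean, 3))
  invisible(x)
}

#' Write a mirrortree correlation table as TSV
#'
#' Layout: receptor rows (plus the control row), ligand columns (plus the
#' control column), with a `Mean` row of per-ligand means over the receptor
#' rows.
#'
#' @param x A `mirrortree_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mirrortree_tsv <- function(x, path) {
  rec <- setdiff(rownames(x$r), "control")
  tab <- rbind(x$r[rec, , drop = FALSE], Mean = x$mean)
  if ("control" %in% rownames(x$r)) {
    tab <- rbind(tab, control = x$r["control", ])
  }
  out <- data.frame(family = rownames(tab), round(tab, 4),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Symmetric matrix with species ids as dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phylip_dist <- function(d, path) {
  n <- nrow(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    writeLines(paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path Path to a PHYLIP square matrix file.
#' @return Symmetric numeric matrix with species ids as dimnames.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  ids <- character(n)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    ids[i] <- parts[1L]
    d[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(d) <- list(ids, ids)
  d
}
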