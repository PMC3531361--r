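## msa_io: alignment containers, FASTA I/O, reference-coordinate maps and
## domain slicing.  Coordinates are 1-based and inclusive throughout: residue
## indices count non-gap positions of the designated reference record,
## alignment columns count all columns.

#' Construct a protein alignment object
#'
#' An `aa_alignment` is an ordered set of equal-length gapped amino-acid
#' sequences with unique identifiers and an optional designated reference
#' record (used to translate between alignment columns and residue numbering
#' on the ungapped reference).
#'
#' @param seqs Character vector of aligned sequences (equal length, residues
#'   from the 20-letter amino-acid alphabet plus `-` for gaps and `X` for
#'   unknown residues, which are treated as missing data downstream).
#' @param ids Character vector of unique record identifiers; defaults to
#'   `names(seqs)`.
#' @param reference_id Optional identifier of the reference record.
#' @return An object of class `aa_alignment` with elements `ids`, `mat` (an
#'   n-by-L character matrix of residues, rows named by id) and
#'   `reference_id`.
#' @examples
#' aln <- aa_alignment(c(h = "MA-LW", m = "MAGLW"), reference_id = "h")
#' n_records(aln)
#' alignment_length(aln)
#' @export
aa_alignment <- function(seqs, ids = names(seqs), reference_id = NULL) {
  ids <- ids  # force before transforming seqs (string ops drop names)
  seqs <- toupper(trimws(as.character(seqs)))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ids <- as.character(ids)
  if (length(ids) != length(seqs)) {
    stop("ids and seqs must have equal length")
  }
  if (length(seqs) == 0L) stop("alignment has no records")
  if (anyDuplicated(ids)) {
    stop("duplicate identifier: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  if (is.null(mat)) mat <- matrix(character(0), nrow = length(seqs), ncol = 0)
  rownames(mat) <- ids
  bad <- setdiff(unique(as.vector(mat)), c(AA20, GAP_CHARS))
  if (length(bad) > 0L) {
    stop("invalid residue: ", paste(bad, collapse = ", "))
  }
  if (!is.null(reference_id) && !reference_id %in% ids) {
    stop("unknown reference: ", reference_id)
  }
  structure(list(ids = ids, mat = mat, reference_id = reference_id),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d records x %d columns", n_records(x),
              alignment_length(x)))
  if (!is.null(x$reference_id)) cat(sprintf(", reference '%s'", x$reference_id))
  cat("\n")
  invisible(x)
}

#' Number of records in an alignment
#' @param aln An [aa_alignment()].
#' @return Integer count of records.
#' @export
n_records <- function(aln) nrow(aln$mat)

#' Number of alignment columns
#' @param aln An [aa_alignment()].
#' @return Integer count of columns.
#' @export
alignment_length <- function(aln) ncol(aln$mat)

#' Sequences of an alignment as a character vector
#' @param aln An [aa_alignment()].
#' @return Named character vector of gapped sequences.
#' @export
alignment_sequences <- function(aln) {
  out <- apply(aln$mat, 1L, paste, collapse = "")
  if (alignment_length(aln) == 0L) out <- stats::setNames(rep("", n_records(aln)), aln$ids)
  out
}

## Subset records and/or columns, preserving order and reference (if kept).
subset_alignment <- function(aln, records = NULL, columns = NULL) {
  mat <- aln$mat
  if (!is.null(records)) mat <- mat[records, , drop = FALSE]
  if (!is.null(columns)) mat <- mat[, columns, drop = FALSE]
  ref <- aln$reference_id
  if (!is.null(ref) && !ref %in% rownames(mat)) ref <- NULL
  structure(list(ids = rownames(mat), mat = mat, reference_id = ref),
            class = "aa_alignment")
}

#' Read a protein multiple sequence alignment from FASTA
#'
#' Sequence identifiers are the first whitespace-delimited token of each FASTA
#' header. Sequences are upper-cased and validated: all records must be the
#' same length and use the 20 amino-acid letters plus `-` (gap) and `X`
#' (unknown, treated as missing).
#'
#' @param path Path to a FASTA file (single-line or wrapped).
#' @param reference_id Optional identifier of the reference record.
#' @return An [aa_alignment()].
#' @export
read_alignment <- function(path, reference_id = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  aa_alignment(as.character(set), ids = ids, reference_id = reference_id)
}

#' Write an alignment to FASTA
#'
#' @param aln An [aa_alignment()].
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  set <- Biostrings::AAStringSet(alignment_sequences(aln))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Map reference residue numbering to alignment columns
#'
#' Builds the bidirectional map between 1-based residue indices on the
#' ungapped reference sequence and 1-based alignment columns. The forward map
#' is strictly increasing; columns that are gaps in the reference have no
#' reverse image.
#'
#' @param aln An [aa_alignment()] with `reference_id` set.
#' @return A list of class `column_map` with `ref_to_col` (integer vector,
#'   one entry per reference residue) and `col_to_ref` (integer vector, one
#'   entry per column, `NA` where the reference has a gap).
#' @examples
#' aln <- aa_alignment(c(r = "A-CD"), reference_id = "r")
#' build_column_map(aln)$ref_to_col  # 1 3 4
#' @export
build_column_map <- function(aln) {
  if (is.null(aln$reference_id)) stop("reference required")
  refrow <- aln$mat[aln$reference_id, ]
  is_res <- refrow != "-"
  ref_to_col <- which(is_res)
  col_to_ref <- rep(NA_integer_, length(refrow))
  col_to_ref[ref_to_col] <- seq_along(ref_to_col)
  structure(list(ref_to_col = as.integer(ref_to_col),
                 col_to_ref = col_to_ref),
            class = "column_map")
}

#' Define a named domain on the reference sequence
#'
#' @param name Domain name.
#' @param start,end 1-based inclusive residue indices on the ungapped
#'   reference sequence.
#' @return A list of class `domain_annotation`.
#' @export
domain_annotation <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid domain range [", start, ", ", end, "]")
  }
  structure(list(name = as.character(name), start = start, end = end),
            class = "domain_annotation")
}

#' Default human preproinsulin domain configuration
#'
#' Residue ranges on human preproinsulin (P01308 numbering): signal peptide
#' 1-24, B chain 25-54, C-peptide 57-87, A chain 90-110. The dibasic
#' processing sites (55-56 and 88-89) that flank the C-peptide are excluded
#' from all domains by default, matching the UniProt chain annotations;
#' set `include_linkers = TRUE` to fold them into the preceding chain.
#'
#' @param include_linkers Assign the dibasic linker residues to the preceding
#'   domain instead of excluding them.
#' @return A named list of [domain_annotation()] objects.
#' @export
insulin_domains <- function(include_linkers = FALSE) {
  if (include_linkers) {
    doms <- list(
      signal = domain_annotation("signal", 1, 24),
      B = domain_annotation("B", 25, 56),
      C = domain_annotation("C", 57, 89),
      A = domain_annotation("A", 90, 110))
  } else {
    doms <- list(
      signal = domain_annotation("signal", 1, 24),
      B = domain_annotation("B", 25, 54),
      C = domain_annotation("C", 57, 87),
      A = domain_annotation("A", 90, 110))
  }
  doms
}

#' Read a domain configuration file
#'
#' The config is YAML: a top-level `reference` key (optional) and a `domains`
#' list of entries with `name`, `start`, `end`.
#'
#' @param path Path to a YAML file.
#' @param allow_overlap Permit overlapping domains (otherwise an error).
#' @return Named list of [domain_annotation()]s, with the reference id (if
#'   any) attached as attribute `reference`.
#' @export
read_domain_config <- function(path, allow_overlap = FALSE) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$domains)) cfg$domains else cfg
  doms <- lapply(entries, function(e) domain_annotation(e$name, e$start, e$end))
  names(doms) <- vapply(doms, `[[`, character(1), "name")
  check_domains(doms, allow_overlap = allow_overlap)
  attr(doms, "reference") <- cfg$reference
  doms
}

#' Check a set of domains for overlap
#'
#' @param domains Named list of [domain_annotation()]s.
#' @param allow_overlap If `FALSE` (default), overlapping domains raise an
#'   error.
#' @return Invisibly, `domains`.
#' @export
check_domains <- function(domains, allow_overlap = FALSE) {
  if (length(domains) >= 2L && !allow_overlap) {
    rng <- t(vapply(domains, function(d) c(d$start, d$end), integer(2)))
    o <- order(rng[, 1L])
    rng <- rng[o, , drop = FALSE]
    for (k in seq_len(nrow(rng) - 1L)) {
      if (rng[k + 1L, 1L] <= rng[k, 2L]) {
        stop("overlapping domains: ", rownames(rng)[k], " and ", rownames(rng)[k + 1L])
      }
    }
  }
  invisible(domains)
}

#' Extract the sub-alignment spanned by a domain
#'
#' Returns the alignment columns spanned by the domain's residue range on the
#' reference, inclusive of interior columns that are gaps in the reference.
#' With `extend_right = TRUE` the slice also takes the reference-gap columns
#' that follow the domain's last residue (up to the next reference residue),
#' so that slicing a set of adjacent, exhaustive domains partitions all
#' alignment columns, each inter-domain gap column going to the preceding
#' domain.
#'
#' @param aln An [aa_alignment()] with a reference record.
#' @param dom A [domain_annotation()].
#' @param extend_right Assign trailing reference-gap columns to this domain
#'   (default `FALSE`: the slice ends at the domain's last residue column).
#' @return An [aa_alignment()] over the domain's columns, record order
#'   preserved.
#' @export
slice_domain <- function(aln, dom, extend_right = FALSE) {
  cmap <- build_column_map(aln)
  nref <- length(cmap$ref_to_col)
  if (dom$start > nref || dom$end > nref) {
    stop("domain outside reference: [", dom$start, ", ", dom$end,
         "] on reference of length ", nref)
  }
  last <- if (!extend_right) {
    cmap$ref_to_col[dom$end]
  } else if (dom$end < nref) {
    cmap$ref_to_col[dom$end + 1L] - 1L
  } else {
    length(cmap$col_to_ref)
  }
  cols <- seq.int(cmap$ref_to_col[dom$start], last)
  subset_alignment(aln, columns = cols)
}

#' Assign reference residue positions to domains
#'
#' Positions outside every domain are labelled `"unassigned"`.
#'
#' @param positions Integer vector of reference residue indices.
#' @param domains Named list of [domain_annotation()]s.
#' @return Character vector of domain names, same length as `positions`.
#' @export
assign_domain <- function(positions, domains) {
  out <- rep("unassigned", length(positions))
  for (d in domains) {
    hit <- positions >= d$start & positions <= d$end
    out[hit] <- d$name
  }
  out
}

## Logical matrix of valid (non-gap, non-'X') residues.
valid_mask <- function(aln) {
  m <- aln$mat != "-" & aln$mat != "X"
  dimnames(m) <- dimnames(aln$mat)
  m
}
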