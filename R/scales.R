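## Physicochemical property scales.  The covariation engine correlates
## per-column property values, so the choice of scale defines "compensation":
## volume-compensating pairs anticorrelate on the volume scale, etc.
## Defaults: residue volume (Zamyatnin 1972, A^3), hydropathy
## (Kyte & Doolittle 1982), polarity (Grantham 1974), average flexibility
## (Bhaskaran & Ponnuswamy 1988) and residue molecular weight (Da).
## Any scale can be replaced by a user table via read_scale().

.aa_scales <- list(
  volume = c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
             Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
             L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
             S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0),
  hydrophobicity = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                     Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                     L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                     S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2),
  polarity = c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5,
               Q = 10.5, E = 12.3, G = 9.0, H = 10.4, I = 5.2,
               L = 4.9, K = 11.3, M = 5.7, F = 5.2, P = 8.0,
               S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9),
  flexibility = c(A = 0.357, R = 0.529, N = 0.463, D = 0.511, C = 0.346,
                  Q = 0.493, E = 0.497, G = 0.544, H = 0.323, I = 0.462,
                  L = 0.365, K = 0.466, M = 0.295, F = 0.314, P = 0.509,
                  S = 0.507, T = 0.444, W = 0.305, Y = 0.420, V = 0.386),
  mw = c(A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
         Q = 146.15, E = 147.13, G = 75.07, H = 155.16, I = 131.17,
         L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
         S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15))

#' Built-in amino-acid property scales
#'
#' @param name One of `"volume"` (residue volume, A^3, Zamyatnin),
#'   `"hydrophobicity"` (Kyte--Doolittle hydropathy), `"polarity"`
#'   (Grantham), `"flexibility"` (Bhaskaran--Ponnuswamy average flexibility)
#'   or `"mw"` (residue molecular weight, Da).
#' @return Named numeric vector over the 20 amino acids. Gap and `X` have no
#'   value (lookups yield `NA`).
#' @examples
#' aa_scale("volume")[["G"]]
#' @export
aa_scale <- function(name = c("volume", "hydrophobicity", "polarity",
                              "flexibility", "mw")) {
  name <- match.arg(name)
  sc <- .aa_scales[[name]]
  attr(sc, "scale_name") <- name
  sc
}

#' Names of the built-in property scales
#' @return Character vector of scale names accepted by [aa_scale()].
#' @export
aa_scale_names <- function() names(.aa_scales)

#' Read a property scale from a two-column TSV
#'
#' The file has one row per amino acid: residue letter, numeric value
#' (AAindex-style flat table). All 20 amino acids must be present.
#'
#' @param path Path to the TSV (no header).
#' @param name Name to attach to the scale.
#' @return Named numeric vector over the 20 amino acids.
#' @export
read_scale <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("aa", "value"),
                           colClasses = c("character", "numeric"))
  sc <- stats::setNames(tab$value, toupper(tab$aa))
  missing <- setdiff(AA20, names(sc))
  if (length(missing) > 0L) {
    stop("scale missing amino acids: ", paste(missing, collapse = ", "))
  }
  sc <- sc[AA20]
  attr(sc, "scale_name") <- name
  sc
}

#' Write a property scale as a two-column TSV
#' @param scale Named numeric vector over the 20 amino acids.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scale <- function(scale, path) {
  utils::write.table(data.frame(aa = names(scale), value = as.numeric(scale)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' BLOSUM62 substitution matrix restricted to the 20 amino acids
#'
#' @return Symmetric 20x20 numeric matrix of BLOSUM62 scores, rows and
#'   columns named by amino acid.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  storage.mode(m) <- "double"
  m
}
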