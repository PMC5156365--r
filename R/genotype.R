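## Genotype encoding
##
## A genotype is a fixed-length binary haplotype of L loci. The canonical
## user-facing form is the bitstring ("0011"); internally genotypes are
## integer indices in [0, 2^L). Locus 1 is the leftmost bitstring character,
## so the integer encoding is big-endian on the string ("1100" -> 12).

#' Convert bitstrings to integer genotype indices
#'
#' @param g character vector of bitstrings (each of identical length L made
#'   of "0"/"1" characters), or an already-integer index vector (returned
#'   unchanged after range checks).
#' @param L locus count; required when `g` is integer, inferred from string
#'   width otherwise.
#' @return integer vector of genotype indices in `[0, 2^L)`.
#' @examples
#' genotypeIndex(c("0011", "1100"))
#' @export
genotypeIndex <- function(g, L = NULL) {
  if (is.numeric(g)) {
    g <- as.integer(g)
    if (is.null(L)) stop("L is required for integer genotype input")
    if (any(is.na(g)) || any(g < 0L) || any(g >= 2L^L))
      stop("integer genotype index out of [0, 2^L)")
    return(g)
  }
  g <- as.character(g)
  w <- unique(nchar(g))
  if (length(w) != 1L) stop("genotype bitstrings must share one length")
  if (!is.null(L) && w != L)
    stop(sprintf("genotype length %d does not match landscape L = %d", w, L))
  if (any(grepl("[^01]", g))) stop("genotype bitstrings must contain only 0/1")
  strtoi(g, base = 2L)
}

#' Convert integer genotype indices to bitstrings
#'
#' @param idx integer indices in `[0, 2^L)`.
#' @param L locus count.
#' @return character vector of width-`L` bitstrings.
#' @examples
#' genotypeString(c(3L, 12L), 4L)
#' @export
genotypeString <- function(idx, L) {
  idx <- as.integer(idx)
  if (any(idx < 0L, na.rm = TRUE) || any(idx >= 2L^L, na.rm = TRUE))
    stop("genotype index out of [0, 2^L)")
  vapply(idx, function(i) {
    if (is.na(i)) return(NA_character_)
    paste(rev(as.integer(intToBits(i)[seq_len(L)])), collapse = "")
  }, character(1))
}

#' All genotypes of a locus count
#'
#' @param L locus count.
#' @return character vector of the `2^L` bitstrings in index order.
#' @export
allGenotypes <- function(L) genotypeString(seq_len(2L^L) - 1L, L)

#' Hamming distance between genotypes
#'
#' Number of loci at which two equal-length genotypes differ.
#'
#' @param g1,g2 bitstrings (vectorized, recycled to common length).
#' @return integer vector of distances.
#' @examples
#' hammingDistance("0011", "1100")
#' @export
hammingDistance <- function(g1, g2) {
  g1 <- as.character(g1); g2 <- as.character(g2)
  if (!all(nchar(g1) == nchar(g2)))
    stop("genotypes must have equal length")
  L <- nchar(g1)[1]
  i1 <- genotypeIndex(g1)
  i2 <- genotypeIndex(g2)
  vapply(bitwXor(i1, i2), function(x) sum(as.integer(intToBits(x)[seq_len(L)])),
         integer(1))
}

#' Bitwise complement of a genotype
#'
#' @param g bitstring vector.
#' @return bitstrings with every allele flipped.
#' @export
complementGenotype <- function(g) {
  chartr("01", "10", as.character(g))
}
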