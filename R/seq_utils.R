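#' Random nucleotide sequence at a given GC content
#'
#' @param n Sequence length in bp.
#' @param gc Target GC fraction in (0, 1).
#' @return A single character string of A/C/G/T.
#' @keywords internal
random_sequence <- function(n, gc = 0.45) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x Character vector of sequences (A/C/G/T/N, case preserved as upper).
#' @return Character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# GC fraction of one or more sequences, ignoring N.
gc_content <- function(x) {
  s <- paste(x, collapse = "")
  tab <- table(strsplit(toupper(s), "")[[1]])
  gc <- sum(tab[names(tab) %in% c("G", "C")])
  at <- sum(tab[names(tab) %in% c("A", "T")])
  gc / (gc + at)
}

# Split an alignment row into a character vector.
aln_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Identity of a pairwise alignment, excluding columns that contain N
#'
#' Matches divided by the number of alignment columns after dropping every
#' column in which either row carries an N (unsequenced gap). Gap columns
#' count in the denominator.
#' @param a,b Aligned rows (equal length, "-" for gaps).
#' @return Fraction in [0, 1] (NaN when no scorable column remains).
#' @export
alignment_identity <- function(a, b) {
  ca <- aln_chars(a); cb <- aln_chars(b)
  stopifnot(length(ca) == length(cb))
  keep <- ca != "N" & cb != "N"
  bases <- c("A", "C", "G", "T")
  matches <- sum(keep & ca == cb & ca %in% bases)
  matches / sum(keep)
}
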