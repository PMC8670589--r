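## Low-level sequence helpers shared across modules. Sequences are plain
## uppercase character scalars over {A,C,G,T,N}; Biostrings is used for the
## heavy lifting (reverse complement, translation, letter counting).

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet letterFrequency GENETIC_CODE
#' @importFrom stats cor rbinom rgeom runif setNames
#' @importFrom utils read.delim write.table
NULL

# split a sequence string into a character vector of single bases
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

c2s <- function(x) paste0(x, collapse = "")

#' Reverse complement of a DNA string
#'
#' @param x character scalar over {A,C,G,T,N}.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# complement without reversal (needed for "complement"-kind repeats)
complement_seq <- function(x) chartr("ACGTN", "TGCAN", x)

reverse_seq <- function(x) c2s(rev(s2c(x)))

# GC fraction with N excluded from numerator and denominator
gc_fraction <- function(x) {
  f <- Biostrings::letterFrequency(Biostrings::DNAString(x), c("G", "C", "A", "T"))
  tot <- sum(f)
  if (tot == 0L) return(NA_real_)
  unname((f[["G"]] + f[["C"]]) / tot)
}

# normalize raw sequence text: uppercase, RNA U -> T, anything odd -> N
normalize_sequence <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGTN]", "N", x)
}

# rotate a circular sequence so that position `offset + 1` becomes position 1
rotate_sequence <- function(x, offset) {
  n <- nchar(x)
  offset <- offset %% n
  if (offset == 0L) return(x)
  paste0(substring(x, offset + 1L, n), substring(x, 1L, offset))
}

# all k-mer start strings of a sequence (vectorized substring)
kmer_strings <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1L:(n - k + 1L), k:n)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
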