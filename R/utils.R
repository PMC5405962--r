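BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c(TAG = "stop_gain_amber", TAA = "stop_gain_ochre",
                 TGA = "stop_gain_opal")

#' Round half away from zero
#'
#' Fixed-point rounding with halves rounded up, as used for the percentage
#' columns of read-statistics tables (base `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @export
#' @examples
#' roundHalfUp(2.675, 2)  # 2.68, not 2.67
roundHalfUp <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# random DNA string of length n (uses the current RNG stream)
randomDna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# reverse complement of plain character strings
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complementBase <- function(x) c(A = "T", C = "G", G = "C", T = "A")[x]

# translate a codon with the standard (bacterial) genetic code
translateCodon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# single-letter amino acid, with '*' rendered as 'Stop' for notation strings
aaSymbol <- function(aa) ifelse(aa == "*", "Stop", aa)

`%||%` <- function(a, b) if (is.null(a)) b else a

# substring replacement that returns the modified string
replaceAt <- function(s, at, value) {
  paste0(substr(s, 1L, at - 1L), value,
         substr(s, at + nchar(value), nchar(s)))
}
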