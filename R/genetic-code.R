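#' @import methods
#' @importFrom stats coef cor.test lm pt runif setNames var
#' @importFrom utils read.delim write.table packageVersion
NULL

# Invertebrate mitochondrial genetic code (NCBI translation table 5).
# Taken from Biostrings so the table is never transcribed by hand.
geneticCode5 <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("5")
    code
  }
})

#' Sense codons of the invertebrate mitochondrial code
#'
#' The 62 non-stop codons of NCBI translation table 5 (TAA and TAG are the
#' only stops; TGA encodes Trp, ATA Met, AGA/AGG Ser).
#'
#' @return Character vector of 62 DNA codons.
#' @export
senseCodons <- function() {
  code <- geneticCode5()
  names(code)[code != "*"]
}

stopCodons <- function() c("TAA", "TAG")

#' Synonymous codon families under translation table 5
#'
#' @return Named list mapping each amino acid (one-letter code) to its set of
#'   synonymous DNA codons. Ser has 8 codons (TCN plus AGN), Met is
#'   \{ATA, ATG\} and Trp \{TGA, TGG\}; the table has no single-codon family.
#' @export
codonFamilies <- function() {
  code <- geneticCode5()
  sense <- code[code != "*"]
  split(names(sense), unname(sense))
}

#' Convert codons between DNA and RNA alphabets
#'
#' Codon-facing outputs use the RNA alphabet (U); internally all sequence is
#' DNA. These helpers translate between the two spellings.
#'
#' @param x Character vector of codons.
#' @return Character vector of the same length.
#' @export
dnaToRna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dnaToRna
#' @export
rnaToDna <- function(x) chartr("Uu", "Tt", x)

#' Kyte-Doolittle hydropathy scale
#'
#' The standard per-residue hydropathy indices (Kyte & Doolittle 1982),
#' embedded as a versioned constant: Ile is the most hydrophobic (4.5) and
#' Arg the most hydrophilic (-4.5).
#'
#' @return Named numeric vector of length 20 (one-letter amino acid codes).
#' @export
kyteDoolittleScale <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

# Canonical mitochondrial feature classes.
featureClasses <- function() c("PCG", "tRNA", "rRNA", "control_region")

# The 13 canonical protein-coding genes of an animal mitogenome.
pcgNames <- function() {
  c("ATP6", "ATP8", "COX1", "COX2", "COX3", "CYTB",
    "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6")
}
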