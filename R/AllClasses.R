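#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom S4Vectors DataFrame
NULL

#' Annotated mitochondrial genome
#'
#' Container for one (usually circular) mitochondrial genome: the nucleotide
#' sequence plus its gene annotations. Coordinates in the feature table are
#' 1-based inclusive, following the GenBank convention; a feature whose start
#' exceeds its end wraps the origin and is only legal on a circular genome.
#'
#' @slot accession Accession or other identifier.
#' @slot species Species (or taxon label).
#' @slot sequence A [Biostrings::DNAString] over \{A,C,G,T,N\}.
#' @slot circular Logical; whether the molecule is circular.
#' @slot features An [S4Vectors::DataFrame] with columns `gene`, `class`
#'   (one of PCG, tRNA, rRNA, control_region), `start`, `end` (1-based
#'   inclusive) and `strand` (`+`/`-`).
#'
#' @seealso [mitogenome()] for the user-facing constructor,
#'   [readGenBank()], [generateMitogenome()].
#' @export
setClass("Mitogenome",
  representation(
    accession = "character",
    species   = "character",
    sequence  = "DNAString",
    circular  = "logical",
    features  = "DataFrame"
  )
)

setValidity("Mitogenome", function(object) {
  msgs <- character()
  len <- length(object@sequence)
  if (len < 1L) msgs <- c(msgs, "sequence must be non-empty")
  ft <- object@features
  needed <- c("gene", "class", "start", "end", "strand")
  if (!all(needed %in% colnames(ft))) {
    return(paste("features must have columns:", paste(needed, collapse = ", ")))
  }
  if (nrow(ft)) {
    if (any(ft$start < 1L) || any(ft$end < 1L) ||
        any(ft$start > len) || any(ft$end > len)) {
      msgs <- c(msgs, "feature coordinates must lie within [1, genome length]")
    }
    if (!all(ft$class %in% featureClasses())) {
      msgs <- c(msgs, "unknown feature class")
    }
    if (!all(ft$strand %in% c("+", "-"))) {
      msgs <- c(msgs, "strand must be '+' or '-'")
    }
    wraps <- ft$start > ft$end
    if (any(wraps) && !isTRUE(object@circular)) {
      msgs <- c(msgs, "origin-wrapping feature (start > end) on a non-circular genome")
    }
    key <- paste(ft$gene, ft$class)
    if (anyDuplicated(key)) {
      msgs <- c(msgs, "duplicate (gene, class) labels; distinguish duplicated tRNAs (e.g. trnL1/trnL2)")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Coding sequence split into codons
#'
#' A gene's nucleotide sequence in sense orientation, split into consecutive
#' triplets from the first position. One or two leftover nucleotides are kept
#' as `trailing`, interpreted downstream as an incomplete stop codon
#' (completed to TAA by polyadenylation in mitochondrial transcripts).
#'
#' @slot gene Gene name.
#' @slot codons Character vector of 3-mers over \{A,C,G,T,N\}.
#' @slot trailing Leftover nucleotides (`""`, one or two characters).
#' @slot strand Source strand of the gene on the genome (`+`/`-`).
#'
#' @seealso [codingSequence()], [codingSequences()]
#' @export
setClass("CodingSequence",
  representation(
    gene     = "character",
    codons   = "character",
    trailing = "character",
    strand   = "character"
  ),
  prototype(trailing = "", strand = "+")
)

setValidity("CodingSequence", function(object) {
  msgs <- character()
  if (length(object@codons) && any(nchar(object@codons) != 3L)) {
    msgs <- c(msgs, "codons must be 3-mers")
  }
  if (length(object@codons) &&
      any(grepl("[^ACGTN]", object@codons))) {
    msgs <- c(msgs, "codons must be over {A,C,G,T,N}")
  }
  if (nchar(object@trailing) > 2L) {
    msgs <- c(msgs, "trailing must have at most 2 nucleotides")
  }
  if (!object@strand %in% c("+", "-")) msgs <- c(msgs, "strand must be '+' or '-'")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Codon count table
#'
#' Pooled codon counts for a set of coding sequences. Stop codons (TAA, TAG
#' under translation table 5) are tracked in a separate slot when excluded
#' from the main counts, and codons containing N are skipped entirely.
#'
#' @slot counts Named integer vector over the counted codons.
#' @slot stopCounts Named integer vector of excluded stop-codon tallies.
#' @slot scope Label for the codon set (a gene name or `"all-PCGs"`).
#' @slot species Species label.
#'
#' @seealso [countCodons()], [rscu()]
#' @export
setClass("CodonCounts",
  representation(
    counts     = "integer",
    stopCounts = "integer",
    scope      = "character",
    species    = "character"
  )
)

setValidity("CodonCounts", function(object) {
  msgs <- character()
  if (any(object@counts < 0L)) msgs <- c(msgs, "counts must be nonnegative")
  if (is.null(names(object@counts))) msgs <- c(msgs, "counts must be named by codon")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Correspondence analysis result
#'
#' Classical correspondence analysis of a nonnegative matrix: principal
#' coordinates for rows and columns, per-axis inertia (squared singular
#' values of the standardized residual matrix) and the percentage of total
#' inertia carried by each axis.
#'
#' @slot rowCoords Matrix of row principal coordinates (rows x axes).
#' @slot colCoords Matrix of column principal coordinates (columns x axes).
#' @slot inertia Numeric vector of per-axis inertias.
#' @slot percent Numeric vector, percentage of total inertia per axis.
#' @slot dropped List with the row/column names removed before analysis
#'   (stop codons, all-zero rows/columns).
#'
#' @seealso [correspondenceAnalysis()]
#' @export
setClass("CAResult",
  representation(
    rowCoords = "matrix",
    colCoords = "matrix",
    inertia   = "numeric",
    percent   = "numeric",
    dropped   = "list"
  )
)

setValidity("CAResult", function(object) {
  msgs <- character()
  k <- length(object@inertia)
  if (length(object@percent) != k) msgs <- c(msgs, "percent and inertia lengths differ")
  if (k && ncol(object@rowCoords) != k) msgs <- c(msgs, "rowCoords axis count mismatch")
  if (k && ncol(object@colCoords) != k) msgs <- c(msgs, "colCoords axis count mismatch")
  if (any(object@inertia < -1e-12)) msgs <- c(msgs, "inertia must be nonnegative")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
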