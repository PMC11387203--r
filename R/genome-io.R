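#' Read nucleotide sequences from a FASTA file
#'
#' Thin validating wrapper around [Biostrings::readBStringSet()]: sequences
#' are uppercased, U is mapped to T, and any character outside
#' \{A,C,G,T,N\} (plus `-` when `allowGaps = TRUE`) is rejected.
#'
#' @param path Path to a FASTA file.
#' @param allowGaps Allow the alignment gap character `-`.
#' @return A named [Biostrings::DNAStringSet]; names are the first
#'   whitespace-delimited token of each header.
#' @export
readFasta <- function(path, allowGaps = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA parse error: no sequences in '", path, "'")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("FASTA parse error: duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  allowed <- if (allowGaps) "[^ACGTN-]" else "[^ACGTN]"
  bad <- grepl(allowed, seqs)
  if (any(bad)) {
    stop("FASTA parse error: illegal character(s) in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param x A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a gene feature table
#'
#' Reads tab-separated annotations with columns `gene` (name), `class`,
#' `start`, `end`, `strand`; coordinates are 1-based inclusive. A header
#' line is detected and skipped automatically. The Unicode minus sign is
#' accepted for `-`.
#'
#' @param path Path to the TSV file.
#' @return An [S4Vectors::DataFrame] of validated annotations, suitable for
#'   the `features` argument of [mitogenome()].
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#", blank.lines.skip = TRUE,
                    colClasses = "character")
  if (nrow(raw) == 0L) stop("feature table parse error: empty file")
  if (ncol(raw) < 5L) stop("feature table parse error: expected 5 columns ",
                           "(gene, class, start, end, strand)")
  first <- tolower(unlist(raw[1L, 1:2], use.names = FALSE))
  if (first[1L] %in% c("gene", "name") && first[2L] == "class") {
    raw <- raw[-1L, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop("feature table parse error: header only")
  featureTable(
    gene   = raw[[1L]],
    class  = raw[[2L]],
    start  = raw[[3L]],
    end    = raw[[4L]],
    strand = raw[[5L]]
  )
}

#' Construct a validated feature table
#'
#' @param gene,class,start,end,strand Parallel vectors of annotations;
#'   coordinates 1-based inclusive, `strand` in `+`/`-`.
#' @return An [S4Vectors::DataFrame].
#' @export
featureTable <- function(gene, class, start, end, strand) {
  strand <- chartr("−", "-", as.character(strand))
  start <- suppressWarnings(as.integer(start))
  end <- suppressWarnings(as.integer(end))
  if (anyNA(start) || anyNA(end)) {
    stop("feature table parse error: non-integer coordinate")
  }
  if (any(start < 1L) || any(end < 1L)) {
    stop("feature table parse error: coordinates must be >= 1")
  }
  if (!all(class %in% featureClasses())) {
    stop("feature table parse error: unknown class: ",
         paste(setdiff(class, featureClasses()), collapse = ", "))
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("feature table parse error: strand must be '+' or '-'")
  }
  S4Vectors::DataFrame(gene = as.character(gene), class = class,
                       start = start, end = end, strand = strand)
}

#' Assemble an annotated mitogenome
#'
#' @param accession Identifier.
#' @param sequence A [Biostrings::DNAString] or character sequence over
#'   \{A,C,G,T,N\}.
#' @param features Feature table from [featureTable()], [readFeatureTable()]
#'   or an equivalent data.frame.
#' @param species Species label.
#' @param circular Whether the molecule is circular. Origin-wrapping
#'   features (start > end) are only accepted when `TRUE`.
#' @return A [Mitogenome-class] object.
#' @export
mitogenome <- function(accession, sequence, features = featureTable(
                         character(), character(), integer(), integer(),
                         character()),
                       species = "", circular = TRUE) {
  if (is.character(sequence)) {
    sequence <- toupper(sequence)
    if (grepl("[^ACGTN]", sequence)) stop("sequence must be over {A,C,G,T,N}")
    sequence <- Biostrings::DNAString(sequence)
  }
  if (is.data.frame(features)) {
    features <- featureTable(features$gene, features$class, features$start,
                             features$end, features$strand)
  }
  new("Mitogenome", accession = as.character(accession),
      species = as.character(species), sequence = sequence,
      circular = isTRUE(circular), features = features)
}

#' Extract a gene's sequence in sense orientation
#'
#' Minus-strand features are reverse-complemented so the returned sequence
#' reads 5'->3' in the gene's own sense. Features that wrap the circular
#' origin (start > end) concatenate the tail and head of the genome.
#'
#' @param record A [Mitogenome-class].
#' @param feature A gene name present in `features(record)`, or a list/row
#'   with elements `start`, `end` and optionally `strand` (default `+`).
#' @return Character string with the gene sequence in sense orientation.
#' @export
extractGene <- function(record, feature) {
  stopifnot(is(record, "Mitogenome"))
  if (is.character(feature) && length(feature) == 1L) {
    ft <- features(record)
    i <- which(ft$gene == feature)
    if (length(i) != 1L) stop("feature '", feature, "' not found uniquely in record")
    feature <- as.list(ft[i, , drop = FALSE])
  }
  start <- as.integer(feature$start)
  end <- as.integer(feature$end)
  strand <- if (is.null(feature$strand)) "+" else as.character(feature$strand)
  len <- length(record@sequence)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L ||
      start > len || end > len) {
    stop("feature coordinates outside record [1, ", len, "]")
  }
  seq <- as.character(record@sequence)
  if (start <= end) {
    out <- substr(seq, start, end)
  } else {
    if (!record@circular) {
      stop("origin-wrapping feature (start > end) on a non-circular record")
    }
    out <- paste0(substr(seq, start, len), substr(seq, 1L, end))
  }
  if (strand == "-") {
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(out)))
  }
  out
}

#' Split a gene sequence into codons
#'
#' Splits from the first position into consecutive triplets; one or two
#' leftover nucleotides are recorded as the trailing partial (an incomplete
#' stop codon in mitochondrial annotation practice).
#'
#' @param geneSeq Nucleotide string in sense orientation.
#' @param gene Gene name for the label.
#' @param strand Source strand on the genome.
#' @return A [CodingSequence-class].
#' @export
codingSequence <- function(geneSeq, gene = "", strand = "+") {
  geneSeq <- toupper(as.character(geneSeq))
  if (!nzchar(geneSeq)) stop("empty gene sequence")
  if (grepl("[^ACGTN]", geneSeq)) stop("gene sequence must be over {A,C,G,T,N}")
  n <- nchar(geneSeq)
  k <- n %/% 3L
  cods <- if (k) substring(geneSeq, 3L * seq_len(k) - 2L, 3L * seq_len(k)) else character()
  trailing <- if (n %% 3L) substr(geneSeq, 3L * k + 1L, n) else ""
  new("CodingSequence", gene = as.character(gene), codons = cods,
      trailing = trailing, strand = as.character(strand))
}

#' Extract all coding sequences of a genome
#'
#' @param record A [Mitogenome-class].
#' @param classes Feature classes to extract (default the protein-coding
#'   genes).
#' @return Named list of [CodingSequence-class] objects, one per feature,
#'   in annotation order.
#' @export
codingSequences <- function(record, classes = "PCG") {
  ft <- features(record)
  keep <- which(ft$class %in% classes)
  out <- lapply(keep, function(i) {
    codingSequence(extractGene(record, as.list(ft[i, , drop = FALSE])),
                   gene = ft$gene[i], strand = ft$strand[i])
  })
  names(out) <- ft$gene[keep]
  out
}
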