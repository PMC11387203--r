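#' Nucleotide composition and strand skews
#'
#' Base counts, A+T and G+C content, and the strand-asymmetry skews
#' AT skew = (A - T)/(A + T) and GC skew = (G - C)/(G + C). Contents and
#' skews are computed over the non-N bases; an all-N sequence is an error.
#'
#' @param seq Nucleotide string or [Biostrings::DNAString] over
#'   \{A,C,G,T,N\}.
#' @param region Region label carried into the output.
#' @return One-row data.frame with columns `region`, `A`, `C`, `G`, `T`,
#'   `N`, `length`, `atContent`, `gcContent`, `atSkew`, `gcSkew`. Skews are
#'   `NA` when their denominator is zero.
#' @examples
#' baseComposition("AAAT")$atSkew  # (3 - 1)/(3 + 1) = 0.5
#' @export
baseComposition <- function(seq, region = "whole") {
  if (is(seq, "DNAString") || is(seq, "DNAStringSet")) seq <- as.character(seq)
  seq <- toupper(paste(seq, collapse = ""))
  if (!nzchar(seq)) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over {A,C,G,T,N}")
  counts <- vapply(c("A", "C", "G", "T", "N"),
                   function(b) nchar(seq) - nchar(gsub(b, "", seq, fixed = TRUE)),
                   0L)
  tot <- sum(counts[c("A", "C", "G", "T")])
  if (tot == 0L) stop("undefined composition: sequence is all N")
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  data.frame(
    region = region,
    A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
    T = counts[["T"]], N = counts[["N"]],
    length = nchar(seq),
    atContent = at / tot,
    gcContent = gc / tot,
    atSkew = if (at > 0L) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gcSkew = if (gc > 0L) (counts[["G"]] - counts[["C"]]) / gc else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Composition of one region class of a genome
#'
#' Concatenates the sense-orientation sequences of all features of the
#' requested class (minus-strand features are reverse-complemented first)
#' and applies [baseComposition()]. `region = "whole"` uses the full genome
#' sequence.
#'
#' @param record A [Mitogenome-class].
#' @param region One of `"whole"`, `"PCG"`, `"tRNA"`, `"rRNA"`,
#'   `"control_region"`.
#' @return One-row data.frame as from [baseComposition()].
#' @export
regionComposition <- function(record, region = "whole") {
  stopifnot(is(record, "Mitogenome"))
  region <- match.arg(region, c("whole", featureClasses()))
  if (region == "whole") {
    return(baseComposition(as.character(genomeSequence(record)), region))
  }
  ft <- features(record)
  idx <- which(ft$class == region)
  if (!length(idx)) stop("no features of class '", region, "' in record")
  seqs <- vapply(idx, function(i) {
    extractGene(record, as.list(ft[i, , drop = FALSE]))
  }, "")
  baseComposition(paste(seqs, collapse = ""), region)
}

#' Composition table across genomes and region classes
#'
#' @param records List of [Mitogenome-class] objects.
#' @param regions Region classes to tabulate.
#' @return data.frame, one row per (species, region) present.
#' @export
compositionTable <- function(records,
                             regions = c("whole", "PCG", "tRNA", "rRNA")) {
  rows <- lapply(records, function(rec) {
    avail <- c("whole", unique(features(rec)$class))
    do.call(rbind, lapply(intersect(regions, avail), function(rg) {
      cbind(accession = accession(rec), species = speciesName(rec),
            regionComposition(rec, rg), stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Positional (codon) composition
#'
#' Third-position base fractions (A3, T3, G3, C3) and per-position G+C
#' fractions (GC1, GC2, GC3) with their first/second-position mean GC12,
#' over the pooled codons of a coding-sequence set. Stop codons (TAA, TAG)
#' and codons containing N are excluded, matching their exclusion from
#' RSCU.
#'
#' @param cdsSet A [CodingSequence-class] or list thereof.
#' @return One-row data.frame with columns `A3`, `T3`, `G3`, `C3`, `GC1`,
#'   `GC2`, `GC3`, `GC12`, `nCodons`.
#' @export
positionalComposition <- function(cdsSet) {
  cods <- pooledCodons(cdsSet)
  cods <- cods[!cods %in% stopCodons() & !grepl("N", cods)]
  if (!length(cods)) stop("no usable codons after excluding stops and N")
  p1 <- substr(cods, 1L, 1L)
  p2 <- substr(cods, 2L, 2L)
  p3 <- substr(cods, 3L, 3L)
  n <- length(cods)
  frac3 <- vapply(c("A", "T", "G", "C"), function(b) sum(p3 == b) / n, 0)
  gcOf <- function(p) sum(p %in% c("G", "C")) / n
  gc1 <- gcOf(p1); gc2 <- gcOf(p2)
  data.frame(
    A3 = frac3[["A"]], T3 = frac3[["T"]], G3 = frac3[["G"]], C3 = frac3[["C"]],
    GC1 = gc1, GC2 = gc2, GC3 = gcOf(p3), GC12 = (gc1 + gc2) / 2,
    nCodons = n
  )
}

# Pool the codon vectors of a CodingSequence or list of them.
pooledCodons <- function(cdsSet) {
  if (is(cdsSet, "CodingSequence")) cdsSet <- list(cdsSet)
  stopifnot(all(vapply(cdsSet, is, TRUE, "CodingSequence")))
  unlist(lapply(cdsSet, codons), use.names = FALSE)
}
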