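#' Translate a coding sequence under translation table 5
#'
#' Codon-by-codon translation with the invertebrate mitochondrial code
#' (ATA = Met, TGA = Trp, AGA/AGG = Ser). A terminal stop codon is
#' consumed; an internal stop is kept as `*` with a warning giving its
#' position (it indicates an annotation error). Codons containing N
#' translate to `X`.
#'
#' @param cds A [CodingSequence-class].
#' @return Amino-acid string (one-letter codes, possibly containing `X`
#'   or `*`).
#' @export
translateCodons <- function(cds) {
  stopifnot(is(cds, "CodingSequence"))
  cods <- codons(cds)
  if (!length(cods)) stop("coding sequence has no codons")
  if (cods[length(cods)] %in% stopCodons()) cods <- cods[-length(cods)]
  if (!length(cods)) return("")
  code <- geneticCode5()
  aa <- ifelse(grepl("N", cods), "X", unname(code[cods]))
  internal <- which(aa == "*")
  if (length(internal)) {
    warning("internal stop codon(s) in ", cds@gene, " at codon position(s) ",
            paste(internal, collapse = ", "))
  }
  paste(aa, collapse = "")
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy per residue: positive values indicate a
#' hydrophobic protein, negative a hydrophilic one. Unscored residues
#' (`X`, `*`) are excluded from both numerator and denominator.
#'
#' @param protein Amino-acid string (one-letter codes).
#' @param scale Named numeric hydropathy scale (default
#'   [kyteDoolittleScale()]).
#' @return GRAVY value, bounded by the scale extremes.
#' @examples
#' gravy("VLI")  # (4.2 + 3.8 + 4.5) / 3
#' @export
gravy <- function(protein, scale = kyteDoolittleScale()) {
  stopifnot(is.character(protein), length(protein) == 1L)
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  vals <- scale[res[res %in% names(scale)]]
  if (!length(vals)) stop("no scored residues")
  mean(vals)
}

#' Species x gene GRAVY matrix
#'
#' Translates every protein-coding gene of every genome and computes GRAVY,
#' giving the species-by-gene hydropathy table.
#'
#' @param records List of [Mitogenome-class] objects.
#' @param scale Hydropathy scale passed to [gravy()].
#' @return Numeric matrix, rows = species (or accession), columns = genes.
#' @export
gravyTable <- function(records, scale = kyteDoolittleScale()) {
  rows <- lapply(records, function(rec) {
    cdss <- codingSequences(rec)
    vapply(cdss, function(cds) gravy(translateCodons(cds), scale), 0)
  })
  genes <- unique(unlist(lapply(rows, names)))
  mat <- matrix(NA_real_, length(records), length(genes),
                dimnames = list(
                  vapply(records, function(r) {
                    if (nzchar(speciesName(r))) speciesName(r) else accession(r)
                  }, ""),
                  genes))
  for (i in seq_along(rows)) mat[i, names(rows[[i]])] <- rows[[i]]
  mat
}
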