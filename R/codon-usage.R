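#' Count codons across a coding-sequence set
#'
#' Pools codons across the set. Codons containing N are skipped. With
#' `excludeStops = TRUE` the translation-table-5 stop codons (TAA, TAG) are
#' removed from the main counts but tallied in a side channel
#' ([stopCounts()]).
#'
#' @param cdsSet A [CodingSequence-class] or list thereof.
#' @param excludeStops Exclude stop codons from the main counts.
#' @param scope Label for the codon set (e.g. a gene name or `"all-PCGs"`).
#' @param species Species label.
#' @return A [CodonCounts-class] whose counts cover the 62 sense codons
#'   (plus the stops when `excludeStops = FALSE`).
#' @export
countCodons <- function(cdsSet, excludeStops = TRUE, scope = "all-PCGs",
                        species = "") {
  cods <- pooledCodons(cdsSet)
  cods <- cods[!grepl("N", cods)]
  universe <- names(geneticCode5())
  tab <- table(factor(cods, levels = universe))
  counts <- setNames(as.integer(tab), universe)
  stops <- counts[stopCodons()]
  if (excludeStops) counts <- counts[setdiff(universe, stopCodons())]
  new("CodonCounts", counts = counts, stopCounts = stops,
      scope = scope, species = as.character(species))
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the count expected if
#' all codons of its synonymous family were used equally:
#' `RSCU_c = familySize * n_c / sum(n over family)`. A value of 1 means
#' unbiased usage; the family mean is 1 by construction. Codons of a family
#' with zero total count get `NA` (undefined), not 0.
#'
#' @param x A [CodonCounts-class] (from [countCodons()]) or a named integer
#'   vector of codon counts (DNA alphabet).
#' @return data.frame with one row per sense codon: `codon` (RNA alphabet,
#'   matching conventional RSCU displays), `codonDNA`, `aa`, `familySize`,
#'   `count`, `rscu`.
#' @examples
#' cc <- countCodons(codingSequence("GCTGCTGCTGCC"))
#' subset(rscu(cc), count > 0)  # GCU 3.0, GCC 1.0
#' @export
rscu <- function(x) {
  counts <- if (is(x, "CodonCounts")) codonCounts(x) else x
  stopifnot(!is.null(names(counts)))
  fams <- codonFamilies()
  rows <- lapply(names(fams), function(aa) {
    cods <- fams[[aa]]
    n <- counts[cods]
    n[is.na(n)] <- 0L
    tot <- sum(n)
    vals <- if (tot > 0) length(cods) * n / tot else rep(NA_real_, length(cods))
    data.frame(codon = dnaToRna(cods), codonDNA = cods, aa = aa,
               familySize = length(cods), count = as.integer(n),
               rscu = as.numeric(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$aa, out$codonDNA), ]
}

#' Classify codons as over- or underrepresented
#'
#' Strict thresholding of RSCU values: overrepresented when RSCU > `hi`
#' (default 1.6), underrepresented when RSCU < `lo` (default 0.6). Codons
#' with undefined RSCU (zero-count family) belong to neither set.
#'
#' @param rscuTable data.frame from [rscu()], or any data.frame with
#'   `codon` and `rscu` columns.
#' @param hi,lo Thresholds (must satisfy `hi > lo`).
#' @return List with character vectors `over` and `under` (RNA-alphabet
#'   codons); the two sets are disjoint.
#' @export
classifyRepresentation <- function(rscuTable, hi = 1.6, lo = 0.6) {
  stopifnot(hi > lo)
  ok <- !is.na(rscuTable$rscu)
  list(over  = rscuTable$codon[ok & rscuTable$rscu > hi],
       under = rscuTable$codon[ok & rscuTable$rscu < lo])
}

#' Mean RSCU across species
#'
#' Averages per-species RSCU tables codon-by-codon (undefined values
#' dropped from the mean). This is the aggregation used for the consensus
#' over/underrepresentation call across a set of genomes.
#'
#' @param rscuTables List of data.frames from [rscu()].
#' @return data.frame like [rscu()] output with `rscu` the across-species
#'   mean and `count` the summed counts.
#' @export
meanRscu <- function(rscuTables) {
  stopifnot(length(rscuTables) >= 1L)
  base <- rscuTables[[1L]][, c("codon", "codonDNA", "aa", "familySize")]
  key <- base$codonDNA
  vals <- vapply(rscuTables, function(tb) {
    tb$rscu[match(key, tb$codonDNA)]
  }, numeric(length(key)))
  cnts <- vapply(rscuTables, function(tb) {
    as.numeric(tb$count[match(key, tb$codonDNA)])
  }, numeric(length(key)))
  vals <- matrix(vals, nrow = length(key))
  cnts <- matrix(cnts, nrow = length(key))
  base$count <- as.integer(rowSums(cnts))
  base$rscu <- rowMeans(vals, na.rm = TRUE)
  base$rscu[is.nan(base$rscu)] <- NA_real_
  base
}

#' Start and stop codon usage summary
#'
#' Tallies the first codon of each coding sequence as its start, and its
#' terminus as TAA, TAG or a truncated stop: a trailing single `T` is
#' reported as `T--`, a trailing `TA` as `TA-` (both completed to TAA by
#' polyadenylation). Any other terminus is counted as `anomalous`.
#'
#' @param cdsSet A [CodingSequence-class] or list thereof (typically the
#'   same gene across many species, or all PCGs of one genome).
#' @return List with named integer vectors `startCounts` and `stopCounts`
#'   (including any `anomalous` tally); each sums to the number of input
#'   coding sequences with at least one codon.
#' @export
startStopSummary <- function(cdsSet) {
  if (is(cdsSet, "CodingSequence")) cdsSet <- list(cdsSet)
  starts <- character()
  stops <- character()
  for (cds in cdsSet) {
    if (!length(codons(cds))) next
    starts <- c(starts, codons(cds)[1L])
    trailing <- cds@trailing
    last <- codons(cds)[length(codons(cds))]
    stops <- c(stops, if (!nchar(trailing)) {
      if (last %in% stopCodons()) last else "anomalous"
    } else if (trailing == "T") {
      "T--"
    } else if (trailing == "TA") {
      "TA-"
    } else {
      "anomalous"
    })
  }
  list(startCounts = tabulateCodons(starts),
       stopCounts  = tabulateCodons(stops))
}

tabulateCodons <- function(x) {
  tab <- table(x)
  setNames(as.integer(tab), names(tab))
}

#' Start/stop codon table across genomes
#'
#' @param records List of [Mitogenome-class] objects.
#' @return data.frame with one row per (gene, kind, codon) giving the count
#'   across genomes, `kind` being `start` or `stop`.
#' @export
startStopTable <- function(records) {
  byGene <- list()
  for (rec in records) {
    for (cds in codingSequences(rec)) {
      byGene[[cds@gene]] <- c(byGene[[cds@gene]], list(cds))
    }
  }
  rows <- lapply(names(byGene), function(g) {
    ss <- startStopSummary(byGene[[g]])
    rbind(
      data.frame(gene = g, kind = "start", codon = names(ss$startCounts),
                 count = as.integer(ss$startCounts), stringsAsFactors = FALSE),
      data.frame(gene = g, kind = "stop", codon = names(ss$stopCounts),
                 count = as.integer(ss$stopCounts), stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Amino-acid usage frequencies
#'
#' Translates the pooled codons under translation table 5 (stop codons and
#' codons containing N excluded) and tabulates residue frequencies.
#'
#' @param cdsSet A [CodingSequence-class] or list thereof.
#' @return data.frame with columns `aa`, `count`, `freq` (frequencies sum
#'   to 1) over the 20 amino acids.
#' @export
aminoAcidUsage <- function(cdsSet) {
  cods <- pooledCodons(cdsSet)
  cods <- cods[!grepl("N", cods) & !cods %in% stopCodons()]
  if (!length(cods)) stop("no translatable codons")
  aas <- unname(geneticCode5()[cods])
  lv <- sort(unique(unname(geneticCode5()[senseCodons()])))
  tab <- table(factor(aas, levels = lv))
  data.frame(aa = names(tab), count = as.integer(tab),
             freq = as.integer(tab) / length(cods), stringsAsFactors = FALSE)
}
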