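# Synthetic annotated mitogenomes with known composition and codon-bias
# parameters, and a Jukes-Cantor star-phylogeny family simulator. Gene
# lengths and layout loosely follow the typical insect mitogenome
# (13 PCGs, 22 tRNAs, 2 rRNAs, control region).

.pcgLengths <- c(
  ATP6 = 648L, ATP8 = 150L, COX1 = 1533L, COX2 = 685L, COX3 = 786L,
  CYTB = 1134L, ND1 = 930L, ND2 = 945L, ND3 = 351L, ND4 = 1338L,
  ND4L = 285L, ND5 = 1720L, ND6 = 483L
)
# COX2 and ND5 lengths are 1 mod 3: they end on a truncated (T--) stop.
.truncatedStopGenes <- c("COX2", "ND5")

.geneOrder <- c(
  "trnI", "trnQ", "trnM", "ND2", "trnW", "trnC", "trnY", "COX1", "trnL2",
  "COX2", "trnK", "trnD", "ATP8", "ATP6", "COX3", "trnG", "ND3", "trnA",
  "trnR", "trnN", "trnS1", "trnE", "trnF", "ND5", "trnH", "ND4", "ND4L",
  "trnT", "trnP", "ND6", "CYTB", "trnS2", "ND1", "trnL1", "lrRNA", "trnV",
  "srRNA", "CR"
)

#' Parameters for synthetic mitogenome generation
#'
#' Defaults emulate an AT-rich insect mitogenome: about 78% A+T, strong
#' third-codon-position A/T enrichment (driving RSCU > 1.6 for A/U-ending
#' codons), a positive AT skew and negative GC skew on the plus strand, and
#' a subset of genes on the minus strand. Skew targets parameterize the
#' base distribution of plus-oriented material; realized whole-genome skews
#' attenuate toward 0 with minus-strand content but keep their sign under
#' the defaults.
#'
#' @param genomeLength Total genome length in bp (gene complement needs
#'   about 14.5 kb; the remainder becomes the control region).
#' @param atTarget Target A+T fraction of the whole genome.
#' @param atSkewTarget,gcSkewTarget Skews of the base distribution used for
#'   plus-oriented material.
#' @param thirdPositionAT Target A+T fraction at third codon positions;
#'   first/second positions compensate so the overall A+T matches
#'   `atTarget`.
#' @param trnaLength,srrnaLength,lrrnaLength Lengths of the RNA genes.
#' @param minusStrandGenes Genes placed on the minus strand.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return List of validated parameters for [generateMitogenome()].
#' @export
synthesisParams <- function(genomeLength = 15500L, atTarget = 0.78,
                            atSkewTarget = 0.18, gcSkewTarget = -0.20,
                            thirdPositionAT = 0.90,
                            trnaLength = 66L, srrnaLength = 775L,
                            lrrnaLength = 1245L,
                            minusStrandGenes = c("ND1", "ND4", "ND4L", "ND5",
                                                 "trnQ", "trnC", "trnY",
                                                 "trnH", "trnP"),
                            seed = 1L) {
  p <- list(genomeLength = as.integer(genomeLength), atTarget = atTarget,
            atSkewTarget = atSkewTarget, gcSkewTarget = gcSkewTarget,
            thirdPositionAT = thirdPositionAT, trnaLength = as.integer(trnaLength),
            srrnaLength = as.integer(srrnaLength),
            lrrnaLength = as.integer(lrrnaLength),
            minusStrandGenes = minusStrandGenes, seed = as.integer(seed))
  stopifnot(p$genomeLength > 0L, p$trnaLength > 0L)
  for (f in c("atTarget", "thirdPositionAT")) {
    if (p[[f]] <= 0 || p[[f]] >= 1) stop(f, " must be in (0,1)")
  }
  # every cell of every position-specific base distribution must be a
  # proper probability, and positions 1+2 must be able to compensate for
  # the third-position A/T enrichment
  at12 <- (3 * p$atTarget - p$thirdPositionAT) / 2
  if (at12 <= 0 || at12 >= 1) {
    stop("infeasible parameters: first/second-position A+T of ", round(at12, 3),
         " needed to reach atTarget ", p$atTarget, " with thirdPositionAT ",
         p$thirdPositionAT)
  }
  for (at in c(p$atTarget, at12, p$thirdPositionAT)) {
    probs <- baseProbs(at, p$atSkewTarget, p$gcSkewTarget)
    if (any(probs <= 0) || any(probs >= 1)) {
      stop("infeasible parameters: skew targets give a degenerate base ",
           "distribution at A+T = ", round(at, 3))
    }
  }
  p
}

# Base distribution (A, C, G, T) with given A+T fraction and skews.
baseProbs <- function(at, atSkew, gcSkew) {
  gc <- 1 - at
  c(A = at / 2 * (1 + atSkew), C = gc / 2 * (1 - gcSkew),
    G = gc / 2 * (1 + gcSkew), T = at / 2 * (1 - atSkew))
}

drawBases <- function(n, probs) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)
}

# Draw n sense codons avoiding in-frame stops. Stop codons are neutralized
# by an in-codon permutation (TAA -> AAT, TAG -> AGT), which preserves the
# drawn base multiset exactly, so overall composition targets are not
# disturbed by stop avoidance.
drawCodons <- function(n, p1, p2, p3) {
  cod <- paste0(drawBases(n, p1), drawBases(n, p2), drawBases(n, p3))
  cod[cod == "TAA"] <- "AAT"
  cod[cod == "TAG"] <- "AGT"
  cod
}

#' Generate a synthetic annotated mitogenome
#'
#' Builds a circular genome with 13 protein-coding genes, 22 tRNAs, 2 rRNAs
#' and a control region. Protein-coding genes are drawn codon by codon from
#' position-specific base distributions meeting the composition targets in
#' `params`; starts are ATN or TTG (ND5 and ATP8 get TTG), stops are TAA,
#' TAG or a truncated `T`; in-frame stops are avoided by a composition-
#' preserving in-codon permutation. RNA genes and the control region are
#' drawn i.i.d. from the whole-genome base distribution. Genes listed in
#' `minusStrandGenes` are reverse-complemented onto the genome strand.
#'
#' @param params From [synthesisParams()].
#' @return A [Mitogenome-class]; deterministic given `params$seed`.
#' @export
generateMitogenome <- function(params = synthesisParams()) {
  old <- globalenv()$.Random.seed
  on.exit(restoreSeed(old))
  set.seed(params$seed)

  at3 <- params$thirdPositionAT
  at12 <- (3 * params$atTarget - at3) / 2
  p12 <- baseProbs(at12, params$atSkewTarget, params$gcSkewTarget)
  p3 <- baseProbs(at3, params$atSkewTarget, params$gcSkewTarget)
  pg <- baseProbs(params$atTarget, params$atSkewTarget, params$gcSkewTarget)

  lens <- geneLengths(params)
  if (sum(lens) > params$genomeLength - 50L) {
    stop("infeasible parameters: genomeLength ", params$genomeLength,
         " too short for the gene complement (", sum(lens), " bp + control region)")
  }
  crLen <- params$genomeLength - sum(lens)

  starts <- setNames(rep("ATG", 13L), names(.pcgLengths))
  starts[c("ND5", "ATP8")] <- "TTG"
  starts[c("ND3", "ND6")] <- "ATT"
  starts[c("ND4L")] <- "ATA"

  pieces <- character(length(.geneOrder))
  names(pieces) <- .geneOrder
  for (g in .geneOrder) {
    if (g %in% names(.pcgLengths)) {
      len <- .pcgLengths[[g]]
      if (g %in% .truncatedStopGenes) {
        k <- (len - 4L) / 3L
        stop <- "T"
      } else {
        k <- (len - 6L) / 3L
        stop <- sample(c("TAA", "TAG"), 1L, prob = c(0.8, 0.2))
      }
      sense <- paste0(starts[[g]], paste(drawCodons(k, p12, p12, p3),
                                         collapse = ""), stop)
    } else if (g == "CR") {
      sense <- paste(drawBases(crLen, pg), collapse = "")
    } else {
      len <- if (g == "srRNA") params$srrnaLength
             else if (g == "lrRNA") params$lrrnaLength
             else params$trnaLength
      sense <- paste(drawBases(len, pg), collapse = "")
    }
    pieces[[g]] <- sense
  }

  genomeStrand <- vapply(.geneOrder, function(g) {
    if (g %in% params$minusStrandGenes) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(pieces[[g]])))
    } else {
      pieces[[g]]
    }
  }, "")
  widths <- nchar(genomeStrand)
  ends <- cumsum(widths)
  startsPos <- ends - widths + 1L

  cls <- vapply(.geneOrder, function(g) {
    if (g %in% names(.pcgLengths)) "PCG"
    else if (g %in% c("srRNA", "lrRNA")) "rRNA"
    else if (g == "CR") "control_region"
    else "tRNA"
  }, "")
  ft <- featureTable(
    gene = .geneOrder, class = unname(cls),
    start = unname(startsPos), end = unname(ends),
    strand = ifelse(.geneOrder %in% params$minusStrandGenes, "-", "+")
  )
  mitogenome(
    accession = sprintf("SYN%07d", params$seed),
    sequence = paste(genomeStrand, collapse = ""),
    features = ft,
    species = sprintf("Synthetica simulata %d", params$seed),
    circular = TRUE
  )
}

geneLengths <- function(params) {
  c(.pcgLengths,
    setNames(rep(params$trnaLength, 22L),
             grep("^trn", .geneOrder, value = TRUE)),
    srRNA = params$srrnaLength, lrRNA = params$lrrnaLength)
}

restoreSeed <- function(old) {
  if (is.null(old)) {
    rm(list = ".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Parameters for family simulation
#'
#' @param nTaxa Number of descendant taxa (default 26).
#' @param divergence Expected pairwise substitutions per site between any
#'   two taxa under the Jukes-Cantor model (each star-tree branch carries
#'   half of it).
#' @param rateMultipliers Named per-gene rate multipliers emulating
#'   among-gene rate heterogeneity; genes absent from the vector get 1.
#' @param seed Integer seed.
#' @return List of validated parameters for [evolveFamily()].
#' @export
familyParams <- function(nTaxa = 26L, divergence = 0.2,
                         rateMultipliers = c(ND2 = 1.4, ATP8 = 1.4,
                                             ND6 = 1.3, ATP6 = 1.2,
                                             COX1 = 0.7, ND1 = 0.7,
                                             srRNA = 0.9, lrRNA = 0.7),
                         seed = 1L) {
  stopifnot(nTaxa >= 2L, divergence >= 0, all(rateMultipliers > 0))
  list(nTaxa = as.integer(nTaxa), divergence = divergence,
       rateMultipliers = rateMultipliers, seed = as.integer(seed))
}

#' Simulate a family of related genomes as per-gene alignments
#'
#' Evolves each protein-coding and rRNA gene of `record` along a star
#' phylogeny under the Jukes-Cantor model: every taxon's branch substitutes
#' each site independently with probability
#' `(3/4) * (1 - exp(-4/3 * d * m / 2))`, where `d` is the expected
#' pairwise divergence and `m` the gene's rate multiplier (substitute bases
#' uniform among the other three). No indels are introduced, so the output
#' is already aligned, isolating diversity computations from aligner
#' behavior.
#'
#' @param record Ancestral [Mitogenome-class].
#' @param params From [familyParams()].
#' @return Named list (gene -> named character vector of `nTaxa` aligned
#'   sequences in sense orientation).
#' @seealso [jcExpectedDiversity()] for the analytic expectation of the
#'   resulting pairwise diversity.
#' @export
evolveFamily <- function(record, params = familyParams()) {
  stopifnot(is(record, "Mitogenome"))
  old <- globalenv()$.Random.seed
  on.exit(restoreSeed(old))
  set.seed(params$seed)
  ft <- features(record)
  idx <- which(ft$class %in% c("PCG", "rRNA"))
  taxa <- sprintf("taxon%02d", seq_len(params$nTaxa))
  out <- lapply(idx, function(i) {
    anc <- strsplit(extractGene(record, as.list(ft[i, , drop = FALSE])),
                    "", fixed = TRUE)[[1L]]
    mult <- params$rateMultipliers[ft$gene[i]]
    if (is.na(mult)) mult <- 1
    pSub <- 0.75 * (1 - exp(-4 / 3 * params$divergence * mult / 2))
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(taxa, function(tx) {
      s <- anc
      hit <- which(runif(length(s)) < pSub & s %in% bases)
      if (length(hit)) {
        # uniform among the three other bases: cycle by a random offset
        off <- sample.int(3L, length(hit), replace = TRUE)
        s[hit] <- bases[(match(s[hit], bases) - 1L + off) %% 4L + 1L]
      }
      paste(s, collapse = "")
    }, "")
    setNames(seqs, taxa)
  })
  names(out) <- ft$gene[idx]
  out
}

#' Expected pairwise diversity under Jukes-Cantor
#'
#' Analytic expectation of the proportion of differing sites between two
#' taxa separated by `divergence * multiplier` expected substitutions per
#' site: `(3/4) * (1 - exp(-4/3 * d))`.
#'
#' @param divergence Expected pairwise substitutions per site.
#' @param multiplier Gene rate multiplier.
#' @return Expected p-distance.
#' @export
jcExpectedDiversity <- function(divergence, multiplier = 1) {
  0.75 * (1 - exp(-4 / 3 * divergence * multiplier))
}

#' Write a mitogenome as FASTA plus feature table
#'
#' Emits the same two plain-text formats the readers consume, so a
#' generated genome round-trips through [readFasta()] /
#' [readFeatureTable()].
#'
#' @param record A [Mitogenome-class].
#' @param fastaPath,featurePath Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
writeMitogenome <- function(record, fastaPath, featurePath) {
  seqs <- Biostrings::DNAStringSet(as.character(genomeSequence(record)))
  names(seqs) <- paste(accession(record), speciesName(record))
  Biostrings::writeXStringSet(seqs, fastaPath)
  ft <- as.data.frame(features(record))
  write.table(ft[, c("gene", "class", "start", "end", "strand")],
              featurePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fastaPath, features = featurePath))
}
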