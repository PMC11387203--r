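# Alignment inputs are a named character vector, a character matrix
# (rows = taxa), or a DNAStringSet; rows must have equal length over
# {A,C,G,T,N,-}.
alignmentMatrix <- function(aln) {
  if (is(aln, "DNAStringSet") || is(aln, "BStringSet")) {
    aln <- as.character(aln)
  }
  if (is.character(aln) && !is.matrix(aln)) {
    aln <- toupper(aln)
    if (length(unique(nchar(aln))) != 1L) stop("alignment rows differ in length")
    m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
    rownames(m) <- names(aln)
    aln <- m
  }
  stopifnot(is.matrix(aln), is.character(aln))
  if (nrow(aln) < 2L) stop("alignment needs >= 2 rows")
  if (any(!aln %in% c("A", "C", "G", "T", "N", "-"))) {
    stop("alignment must be over {A,C,G,T,N,-}")
  }
  aln
}

# Per-column summary used by Pi: validity (no gap/N in any row) and the
# number of differing unordered row pairs.
columnPairDiffs <- function(m) {
  n <- nrow(m)
  nPairs <- n * (n - 1) / 2
  valid <- colSums(m == "N" | m == "-") == 0L
  samePairs <- vapply(seq_len(ncol(m)), function(j) {
    tab <- tabulate(factor(m[, j], levels = c("A", "C", "G", "T")), 4L)
    sum(tab * (tab - 1) / 2)
  }, 0)
  list(valid = valid, diffPairs = nPairs - samePairs, nPairs = nPairs)
}

#' Nucleotide diversity (Pi)
#'
#' The average pairwise proportion of differing sites:
#' `Pi = sum over unordered pairs of d_ij / choose(n, 2)` with
#' `d_ij = differences / analyzed sites`. By default analyzed sites are
#' alignment columns containing no gap and no N in any row (complete
#' deletion); `pairwiseDeletion = TRUE` instead drops sites per pair.
#'
#' @param aln Alignment: named character vector, character matrix (rows =
#'   taxa) or [Biostrings::DNAStringSet]; equal-length rows over
#'   \{A,C,G,T,N,-\}.
#' @param pairwiseDeletion Use pairwise instead of complete deletion.
#' @return Nucleotide diversity in `[0, 1]`.
#' @examples
#' nucleotideDiversity(c("AAAAAAAAAA", "AAAAAAAAAC"))  # 0.1
#' @export
nucleotideDiversity <- function(aln, pairwiseDeletion = FALSE) {
  m <- alignmentMatrix(aln)
  if (pairwiseDeletion) {
    n <- nrow(m)
    tot <- 0
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        ok <- !(m[i, ] %in% c("N", "-")) & !(m[j, ] %in% c("N", "-"))
        if (!any(ok)) stop("pair (", i, ",", j, ") has zero analyzed sites")
        tot <- tot + sum(m[i, ok] != m[j, ok]) / sum(ok)
      }
    }
    return(tot / (n * (n - 1) / 2))
  }
  cs <- columnPairDiffs(m)
  nValid <- sum(cs$valid)
  if (nValid == 0L) stop("zero analyzed sites after complete deletion")
  sum(cs$diffPairs[cs$valid]) / (cs$nPairs * nValid)
}

#' Sliding-window nucleotide diversity
#'
#' Windows are anchored at column 1 and advance by `step`; each window's Pi
#' is computed on its columns (complete deletion within the window). A final
#' partial window shorter than `window` is dropped. Window coordinates refer
#' to alignment columns before any deletion.
#'
#' @param aln Alignment (see [nucleotideDiversity()]).
#' @param window Window width in alignment columns (default 200).
#' @param step Step between window starts (default 20).
#' @return data.frame with columns `start`, `end`, `midpoint`, `pi`, one
#'   row per window. Windows whose every column is excluded get `NA`.
#' @export
slidingWindowPi <- function(aln, window = 200L, step = 20L) {
  m <- alignmentMatrix(aln)
  L <- ncol(m)
  window <- as.integer(window); step <- as.integer(step)
  stopifnot(window >= 1L, step >= 1L)
  if (L < window) {
    stop("alignment length (", L, ") is shorter than the window (", window,
         "); compute nucleotideDiversity() on the whole alignment instead")
  }
  starts <- seq.int(1L, L - window + 1L, by = step)
  cs <- columnPairDiffs(m)
  pis <- vapply(starts, function(s) {
    cols <- s:(s + window - 1L)
    nValid <- sum(cs$valid[cols])
    if (nValid == 0L) return(NA_real_)
    sum(cs$diffPairs[cols][cs$valid[cols]]) / (cs$nPairs * nValid)
  }, 0)
  data.frame(start = starts, end = starts + window - 1L,
             midpoint = starts + (window - 1L) / 2, pi = pis)
}

#' Per-gene nucleotide diversity
#'
#' @param alignments Named list of alignments, one per gene.
#' @param pairwiseDeletion Passed to [nucleotideDiversity()].
#' @return data.frame with columns `gene`, `length` (alignment columns) and
#'   `pi`.
#' @export
perGeneDiversity <- function(alignments, pairwiseDeletion = FALSE) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  rows <- lapply(names(alignments), function(g) {
    m <- alignmentMatrix(alignments[[g]])
    data.frame(gene = g, length = ncol(m),
               pi = nucleotideDiversity(m, pairwiseDeletion),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concatenate per-gene alignments
#'
#' Joins equal-taxa alignments column-wise (genes in the given order, e.g.
#' annotation order of a reference genome) for a genome-scale sliding
#' window; also returns each gene's column span in the concatenation.
#'
#' @param alignments Named list of alignments sharing the same taxa.
#' @return List with `alignment` (character matrix) and `boundaries`
#'   (data.frame gene/start/end in concatenated columns).
#' @export
concatenateAlignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  mats <- lapply(alignments, alignmentMatrix)
  n <- nrow(mats[[1L]])
  if (!all(vapply(mats, nrow, 0L) == n)) {
    stop("alignments have differing taxon counts")
  }
  widths <- vapply(mats, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  list(
    alignment = do.call(cbind, mats),
    boundaries = data.frame(gene = names(alignments), start = starts,
                            end = ends, row.names = NULL,
                            stringsAsFactors = FALSE)
  )
}
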