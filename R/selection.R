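#' PR2-bias plot coordinates
#'
#' Parity Rule 2 coordinates of a codon set: AT bias = A3/(A3 + T3)
#' (abscissa) and GC bias = G3/(G3 + C3) (ordinate), from third-codon-
#' position composition. The plot center (0.5, 0.5) corresponds to A = T
#' and G = C at third positions, i.e. no strand asymmetry from mutation or
#' selection.
#'
#' @param pc One-row data.frame from [positionalComposition()] (or anything
#'   with `A3`, `T3`, `G3`, `C3`).
#' @param gene,species Labels carried into the output.
#' @return One-row data.frame with `gene`, `species`, `atBias`, `gcBias`
#'   (`NA` when a denominator is 0).
#' @export
pr2Point <- function(pc, gene = "", species = "") {
  at <- pc$A3 + pc$T3
  gc <- pc$G3 + pc$C3
  data.frame(
    gene = gene, species = species,
    atBias = if (at > 0) pc$A3 / at else NA_real_,
    gcBias = if (gc > 0) pc$G3 / gc else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' PR2 points for every (gene, species)
#'
#' @param records List of [Mitogenome-class] objects.
#' @return data.frame of per-gene, per-species PR2 coordinates.
#' @export
pr2Table <- function(records) {
  rows <- lapply(records, function(rec) {
    cdss <- codingSequences(rec)
    do.call(rbind, lapply(cdss, function(cds) {
      pr2Point(positionalComposition(cds), gene = cds@gene,
               species = speciesName(rec))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neutrality-plot regression
#'
#' Ordinary least squares of GC12 on GC3 with the Pearson correlation and
#' its two-sided p-value (t distribution, n - 2 df). A slope near 1 with a
#' significant correlation indicates mutation pressure dominating codon
#' usage; a slope near 0 indicates selection.
#'
#' @param points data.frame with columns `gc3` and `gc12` (one point per
#'   species or gene).
#' @param gene Label carried into the output.
#' @return One-row data.frame with `gene`, `slope`, `intercept`, `r`,
#'   `p`, `n` and `significance` (`**` for p < .01, `*` for p < .05,
#'   `ns` otherwise).
#' @export
neutralityRegression <- function(points, gene = "") {
  stopifnot(all(c("gc3", "gc12") %in% names(points)))
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points for a p-value")
  if (var(points$gc3) == 0) stop("degenerate regression: gc3 values all equal")
  fit <- lm(gc12 ~ gc3, data = points)
  ct <- cor.test(points$gc3, points$gc12, method = "pearson")
  p <- ct$p.value
  data.frame(
    gene = gene,
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r = unname(ct$estimate),
    p = p,
    n = n,
    significance = if (p < 0.01) "**" else if (p < 0.05) "*" else "ns",
    stringsAsFactors = FALSE
  )
}

#' Per-gene neutrality regressions across genomes
#'
#' @param records List of [Mitogenome-class] objects.
#' @return data.frame with one regression row per gene (GC12 on GC3 across
#'   species).
#' @export
neutralityTable <- function(records) {
  pts <- list()
  for (rec in records) {
    for (cds in codingSequences(rec)) {
      pc <- positionalComposition(cds)
      pts[[cds@gene]] <- rbind(pts[[cds@gene]],
                               data.frame(gc3 = pc$GC3, gc12 = pc$GC12))
    }
  }
  out <- do.call(rbind, lapply(names(pts), function(g) {
    neutralityRegression(pts[[g]], gene = g)
  }))
  rownames(out) <- NULL
  out
}

#' Classical correspondence analysis
#'
#' Chi-square-metric ordination of a nonnegative matrix. The correspondence
#' matrix `P = X / sum(X)` is centered and standardized,
#' `S = Dr^(-1/2) (P - r c') Dc^(-1/2)`, and decomposed by SVD; axis
#' inertias are the squared singular values and each axis's percentage is
#' its share of the total inertia (= chi-square statistic / sum(X)).
#' Principal coordinates are returned for rows and columns.
#'
#' For RSCU matrices set `dropStops = TRUE` to delete the stop-codon rows
#' (UAA/UAG or TAA/TAG rownames) before analysis; all-zero rows and columns
#' are always removed (and reported in `dropped`).
#'
#' Axis signs are arbitrary in CA; for reproducibility each axis is
#' oriented so its largest-magnitude row loading is positive.
#'
#' @param x Nonnegative numeric matrix (e.g. codons x species RSCU).
#' @param dropStops Delete stop-codon rows by rowname before analysis.
#' @return A [CAResult-class]. A matrix with no dependence structure (rank
#'   0 after centering) yields a zero-axis result, not an error.
#' @export
correspondenceAnalysis <- function(x, dropStops = FALSE) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(x < 0) || anyNA(x)) stop("matrix must be nonnegative and complete")
  dropped <- list(rows = character(), cols = character())
  if (dropStops && !is.null(rownames(x))) {
    stops <- c(stopCodons(), dnaToRna(stopCodons()))
    hit <- rownames(x) %in% stops
    dropped$rows <- c(dropped$rows, rownames(x)[hit])
    x <- x[!hit, , drop = FALSE]
  }
  zr <- rowSums(x) == 0
  zc <- colSums(x) == 0
  dropped$rows <- c(dropped$rows, rownames(x)[zr])
  dropped$cols <- c(dropped$cols, colnames(x)[zc])
  x <- x[!zr, !zc, drop = FALSE]
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need >= 2 rows and >= 2 columns after deletions")
  }
  P <- x / sum(x)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  dec <- svd(S)
  kmax <- min(nrow(x), ncol(x)) - 1L
  tol <- max(dim(S)) * max(dec$d, 0) * .Machine$double.eps * 100
  keep <- which(dec$d > max(tol, 1e-12))
  keep <- keep[keep <= kmax]
  if (!length(keep)) {
    return(new("CAResult",
               rowCoords = matrix(0, nrow(x), 0,
                                  dimnames = list(rownames(x), NULL)),
               colCoords = matrix(0, ncol(x), 0,
                                  dimnames = list(colnames(x), NULL)),
               inertia = numeric(), percent = numeric(), dropped = dropped))
  }
  d <- dec$d[keep]
  U <- dec$u[, keep, drop = FALSE]
  V <- dec$v[, keep, drop = FALSE]
  rowCo <- sweep(U, 1L, sqrt(r), "/") %*% diag(d, length(d))
  colCo <- sweep(V, 1L, sqrt(cc), "/") %*% diag(d, length(d))
  for (k in seq_along(d)) {
    if (rowCo[which.max(abs(rowCo[, k])), k] < 0) {
      rowCo[, k] <- -rowCo[, k]
      colCo[, k] <- -colCo[, k]
    }
  }
  dimnames(rowCo) <- list(rownames(x), paste0("Axis", seq_along(d)))
  dimnames(colCo) <- list(colnames(x), paste0("Axis", seq_along(d)))
  inert <- d^2
  new("CAResult", rowCoords = rowCo, colCoords = colCo, inertia = inert,
      percent = 100 * inert / sum(inert), dropped = dropped)
}

#' Per-gene correspondence analysis of RSCU across species
#'
#' Builds, for each protein-coding gene, the codons x species RSCU matrix
#' (or raw count matrix) and runs [correspondenceAnalysis()] with stop
#' codons removed.
#'
#' @param records List of [Mitogenome-class] objects.
#' @param source `"rscu"` (default) or `"counts"`.
#' @return Named list of [CAResult-class], one per gene occurring in every
#'   record.
#' @export
caByGene <- function(records, source = c("rscu", "counts")) {
  source <- match.arg(source)
  perSpecies <- lapply(records, function(rec) {
    lapply(codingSequences(rec), function(cds) {
      cc <- countCodons(cds, excludeStops = TRUE, scope = cds@gene,
                        species = speciesName(rec))
      if (source == "rscu") {
        tb <- rscu(cc)
        setNames(ifelse(is.na(tb$rscu), 0, tb$rscu), tb$codonDNA)
      } else {
        codonCounts(cc)
      }
    })
  })
  genes <- Reduce(intersect, lapply(perSpecies, names))
  out <- lapply(genes, function(g) {
    cols <- lapply(perSpecies, `[[`, g)
    mat <- do.call(cbind, cols)
    colnames(mat) <- vapply(records, function(r) {
      if (nzchar(speciesName(r))) speciesName(r) else accession(r)
    }, "")
    correspondenceAnalysis(mat, dropStops = TRUE)
  })
  names(out) <- genes
  out
}
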