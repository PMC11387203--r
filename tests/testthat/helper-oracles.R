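# Independent oracles used to validate the package implementations.
# These deliberately use the slowest, most literal formulation of each
# quantity and share no code with the package.

# Nucleotide diversity by explicit loops over pairs and columns
# (complete deletion: a column with any gap/N is excluded for all pairs).
oraclePi <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  stopifnot(ncol(m) > 0)
  total <- 0
  npairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      diffs <- 0
      for (k in seq_len(ncol(m))) if (m[i, k] != m[j, k]) diffs <- diffs + 1
      total <- total + diffs / ncol(m)
      npairs <- npairs + 1
    }
  }
  total / npairs
}

# CA inertia spectrum via eigen-decomposition of S'S (not SVD), plus the
# total chi-square statistic of the matrix for the conservation check.
oracleCAInertia <- function(x) {
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  P <- x / sum(x)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  ev <- eigen(t(S) %*% S, symmetric = TRUE)$values
  ev[ev < max(ev, 0) * 1e-10] <- 0
  sort(ev[ev > 1e-12], decreasing = TRUE)
}

oracleChisq <- function(x) {
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  expd <- outer(rowSums(x), colSums(x)) / sum(x)
  sum((x - expd)^2 / expd)
}

# Random test-case builders (callers control the RNG seed).
randomAlignment <- function(n, L, gapFrac = 0, nFrac = 0) {
  alpha <- c("A", "C", "G", "T")
  m <- matrix(sample(alpha, n * L, replace = TRUE), n, L)
  mut <- sample(length(m), round(length(m) * gapFrac))
  if (length(mut)) m[mut] <- "-"
  mut <- sample(length(m), round(length(m) * nFrac))
  if (length(mut)) m[mut] <- "N"
  apply(m, 1, paste, collapse = "")
}

randomCountMatrix <- function(nr, nc) {
  matrix(rpois(nr * nc, lambda = 5), nr, nc,
         dimnames = list(paste0("r", seq_len(nr)), paste0("c", seq_len(nc))))
}

# A tiny hand-made genome used across io/composition tests.
toyGenome <- function(seq = "ATGAAATAACCCGGGTTTACGTACGT",
                      features = data.frame(
                        gene = c("g1", "trnX"),
                        class = c("PCG", "tRNA"),
                        start = c(1L, 10L),
                        end = c(9L, 15L),
                        strand = c("+", "-"),
                        stringsAsFactors = FALSE),
                      circular = TRUE) {
  mitogenome("TOY1", seq, features, species = "Toy toyensis",
             circular = circular)
}
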