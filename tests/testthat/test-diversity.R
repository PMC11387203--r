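test_that("nucleotide diversity matches direct pairwise counting", {
  expect_equal(nucleotideDiversity(c("ACGTACGTAC", "ACGTACGTAC")), 0)
  expect_equal(nucleotideDiversity(c("AAAAAAAAAA", "AAAAAAAAAC")), 0.1)

  # 3 rows, 10 columns, pairwise differences 2, 4, 2
  rows <- c("AAAAAAAAAA", "CCAAAAAAAA", "CCGGAAAAAA")
  expect_equal(nucleotideDiversity(rows), (0.2 + 0.4 + 0.2) / 3,
               tolerance = 1e-12)

  expect_error(nucleotideDiversity("ACGT"), ">= 2 rows")
  expect_error(nucleotideDiversity(c("N-", "AN")), "zero analyzed sites")
})

test_that("Pi equals the brute-force oracle on random alignments", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    L <- sample(10:50, 1)
    rows <- randomAlignment(n, L, gapFrac = runif(1, 0, 0.05),
                            nFrac = runif(1, 0, 0.05))
    ok <- tryCatch({oraclePi(rows); TRUE}, error = function(e) FALSE)
    if (!ok) next  # all columns deleted; the package errors too
    expect_equal(nucleotideDiversity(rows), oraclePi(rows), tolerance = 1e-12)
  }
})

test_that("Pi is invariant to row and column permutation and equals the
           2-row p-distance", {
  set.seed(5)
  rows <- randomAlignment(5, 40)
  expect_equal(nucleotideDiversity(sample(rows)), nucleotideDiversity(rows))
  m <- do.call(rbind, strsplit(rows, ""))
  expect_equal(nucleotideDiversity(m[, sample(ncol(m))]),
               nucleotideDiversity(m))

  pair <- randomAlignment(2, 60)
  pdist <- mean(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]])
  expect_equal(nucleotideDiversity(pair), pdist)
})

test_that("duplicating every row k times changes Pi exactly as C(n,2) predicts", {
  set.seed(6)
  rows <- randomAlignment(4, 30)
  for (k in c(2, 3)) {
    dup <- rep(rows, each = k)
    expect_equal(nucleotideDiversity(dup), oraclePi(dup), tolerance = 1e-12)
    # closed form: nk(n-1)k pairs between distinct originals, none within
    n <- length(rows)
    expected <- oraclePi(rows) * (n * (n - 1) / 2 * k^2) /
      choose(n * k, 2)
    expect_equal(nucleotideDiversity(dup), expected, tolerance = 1e-12)
  }
})

test_that("Pi agrees with ape's raw pairwise distances (complete deletion)", {
  set.seed(9)
  rows <- randomAlignment(6, 80)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(rows), "")))
  apePi <- mean(ape::dist.dna(bin, model = "raw", pairwise.deletion = FALSE))
  expect_equal(nucleotideDiversity(rows), apePi, tolerance = 1e-12)
})

test_that("sliding windows advance by step, drop the partial tail, and
           reproduce whole-alignment Pi on homogeneous alignments", {
  set.seed(10)
  aln200 <- randomAlignment(4, 200)
  sw <- slidingWindowPi(aln200, window = 200, step = 20)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$pi, nucleotideDiversity(aln200))

  aln240 <- randomAlignment(4, 240)
  sw <- slidingWindowPi(aln240, window = 200, step = 20)
  expect_equal(sw$start, c(1L, 21L, 41L))
  expect_equal(sw$end, c(200L, 220L, 240L))
  expect_equal(sw$midpoint, sw$start + 99.5)
  # each window equals Pi computed directly on its columns
  m <- do.call(rbind, strsplit(aln240, ""))
  for (i in seq_len(nrow(sw))) {
    sub <- apply(m[, sw$start[i]:sw$end[i]], 1, paste, collapse = "")
    expect_equal(sw$pi[i], nucleotideDiversity(sub), tolerance = 1e-12)
  }

  # homogeneous alignment: every column has the same pattern
  col <- c("A", "A", "C", "T")
  hom <- apply(matrix(rep(col, 400), nrow = 4), 1, paste, collapse = "")
  sw <- slidingWindowPi(hom, window = 200, step = 40)
  expect_true(all(abs(sw$pi - nucleotideDiversity(hom)) < 1e-12))

  expect_error(slidingWindowPi(randomAlignment(3, 50), window = 200),
               "shorter than the window")
})

test_that("per-gene diversity maps genes to alignment length and Pi", {
  alns <- list(g1 = c("AAAA", "AAAA"), g2 = c("AAAA", "AAAC"))
  pg <- perGeneDiversity(alns)
  expect_equal(pg$pi, c(0, 0.25))
  expect_equal(pg$length, c(4L, 4L))

  cat_ <- concatenateAlignments(alns)
  expect_equal(dim(cat_$alignment), c(2L, 8L))
  expect_equal(cat_$boundaries$start, c(1L, 5L))
  expect_equal(cat_$boundaries$end, c(4L, 8L))
})

test_that("pairwise deletion keeps per-pair sites", {
  rows <- c("AANA", "AAAA", "CANA")
  # complete deletion removes column 3: pairs over 3 sites
  expect_equal(nucleotideDiversity(rows), (0 + 1 / 3 + 1 / 3) / 3)
  # pairwise deletion: every pair involves an N at column 3, same result
  expect_equal(nucleotideDiversity(rows, pairwiseDeletion = TRUE),
               (0 + 1 / 3 + 1 / 3) / 3)
  rows2 <- c("AAAA", "AAAC", "CANA")
  # (1,2): 1 diff / 4 sites; (1,3): 1/3; (2,3): 2/3
  expect_equal(nucleotideDiversity(rows2, pairwiseDeletion = TRUE),
               (1 / 4 + 1 / 3 + 2 / 3) / 3)
})
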