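test_that("PR2 coordinates follow the bias formulas", {
  pc <- data.frame(A3 = 0.25, T3 = 0.25, G3 = 0.25, C3 = 0.25)
  pt <- pr2Point(pc)
  expect_equal(c(pt$atBias, pt$gcBias), c(0.5, 0.5))

  # third-position counts A=30, T=60, G=20, C=10 -> (0.333, 0.667)
  cods <- c(rep("TTA", 30), rep("TTT", 60), rep("TTG", 20), rep("TTC", 10))
  pc <- positionalComposition(codingSequence(paste(cods, collapse = "")))
  pt <- pr2Point(pc)
  expect_equal(pt$atBias, 30 / 90, tolerance = 1e-9)
  expect_equal(pt$gcBias, 20 / 30, tolerance = 1e-9)

  # invariant to scaling all third-position counts
  cods3 <- rep(cods, 3)
  pt3 <- pr2Point(positionalComposition(codingSequence(paste(cods3, collapse = ""))))
  expect_equal(pt3$atBias, pt$atBias, tolerance = 1e-12)
  expect_equal(pt3$gcBias, pt$gcBias, tolerance = 1e-12)

  # zero denominator -> undefined marker
  pt <- pr2Point(data.frame(A3 = 0, T3 = 0, G3 = 0.5, C3 = 0.5))
  expect_true(is.na(pt$atBias))
})

test_that("neutrality regression reproduces closed-form OLS and Pearson r", {
  pts <- data.frame(gc3 = c(0, 0.5, 1), gc12 = c(0, 0.25, 0.5))
  fit <- neutralityRegression(pts)
  expect_equal(fit$slope, 0.5, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)

  ident <- data.frame(gc3 = c(0.1, 0.3, 0.7, 0.9))
  ident$gc12 <- ident$gc3
  fit <- neutralityRegression(ident)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)

  expect_error(neutralityRegression(data.frame(gc3 = c(1, 1, 1),
                                               gc12 = c(1, 2, 3))),
               "degenerate")
  expect_error(neutralityRegression(data.frame(gc3 = c(0, 1),
                                               gc12 = c(0, 1))),
               "3 points")
})

test_that("r^2 equals the explained variance ratio and duplicates don't
           change the fit", {
  set.seed(11)
  pts <- data.frame(gc3 = runif(20))
  pts$gc12 <- 0.3 * pts$gc3 + 0.2 + rnorm(20, sd = 0.02)
  fit <- neutralityRegression(pts)
  pred <- fit$intercept + fit$slope * pts$gc3
  ssRes <- sum((pts$gc12 - pred)^2)
  ssTot <- sum((pts$gc12 - mean(pts$gc12))^2)
  expect_equal(fit$r^2, 1 - ssRes / ssTot, tolerance = 1e-9)
  # closed-form slope: cov/var
  expect_equal(fit$slope, cov(pts$gc3, pts$gc12) / var(pts$gc3),
               tolerance = 1e-12)

  dup <- rbind(pts, pts[c(3, 3, 7), ])
  # exchanging the order of duplicated points changes nothing
  fit1 <- neutralityRegression(dup)
  fit2 <- neutralityRegression(dup[sample(nrow(dup)), ])
  expect_equal(fit1$slope, fit2$slope, tolerance = 1e-12)
  expect_equal(fit1$r, fit2$r, tolerance = 1e-12)
})

test_that("correspondence analysis handles the canonical small cases", {
  m <- matrix(c(10, 0, 0, 10), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  ca <- correspondenceAnalysis(m)
  expect_length(inertia(ca), 1L)
  expect_equal(axisPercent(ca), 100)

  # outer-product (independent) matrix: total inertia 0, no axes
  m <- matrix(c(1, 2, 2, 4), 2, 2)
  ca <- correspondenceAnalysis(m)
  expect_length(inertia(ca), 0L)

  expect_error(correspondenceAnalysis(matrix(-1, 2, 2)), "nonnegative")
  expect_error(correspondenceAnalysis(matrix(c(1, 0, 2, 0), 2, 2)),
               ">= 2 rows")
})

test_that("CA conserves inertia, centers coordinates and matches the
           eigen oracle", {
  set.seed(12)
  for (i in 1:40) {
    nr <- sample(3:8, 1)
    nc <- sample(2:6, 1)
    x <- randomCountMatrix(nr, nc)
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) next
    ca <- correspondenceAnalysis(x)
    # total inertia = chi-square / N
    expect_equal(sum(inertia(ca)), oracleChisq(x) / sum(x), tolerance = 1e-10)
    # spectrum equals the eigen-decomposition oracle
    ev <- oracleCAInertia(x)
    expect_equal(inertia(ca), ev[seq_along(inertia(ca))], tolerance = 1e-8)
    # transposing the matrix leaves the spectrum unchanged
    cat_ <- correspondenceAnalysis(t(x))
    expect_equal(inertia(cat_), inertia(ca), tolerance = 1e-8)
    # weighted means of principal coordinates are 0 on every axis
    r <- rowSums(x) / sum(x)
    cc <- colSums(x) / sum(x)
    for (k in seq_along(inertia(ca))) {
      expect_lt(abs(sum(r * rowCoords(ca)[, k])), 1e-10)
      expect_lt(abs(sum(cc * colCoords(ca)[, k])), 1e-10)
    }
    # sign convention: largest-magnitude row loading positive
    for (k in seq_along(inertia(ca))) {
      loading <- rowCoords(ca)[, k]
      expect_gt(loading[which.max(abs(loading))], 0)
    }
  }
})

test_that("CA percentages sum to 100 and stop-codon rows are dropped", {
  set.seed(13)
  x <- randomCountMatrix(6, 4)
  rownames(x)[1:2] <- c("UAA", "UAG")
  ca <- correspondenceAnalysis(x, dropStops = TRUE)
  expect_equal(sum(axisPercent(ca)), 100, tolerance = 1e-9)
  expect_false(any(c("UAA", "UAG") %in% rownames(rowCoords(ca))))
  expect_setequal(ca@dropped$rows, c("UAA", "UAG"))

  # all-zero rows and columns are removed, not fatal
  x2 <- randomCountMatrix(5, 4)
  x2[2, ] <- 0
  x2[, 3] <- 0
  ca2 <- correspondenceAnalysis(x2)
  expect_false("r2" %in% rownames(rowCoords(ca2)))
  expect_false("c3" %in% rownames(colCoords(ca2)))
})

test_that("CA agrees with MASS::corresp canonical correlations", {
  set.seed(14)
  x <- randomCountMatrix(7, 5)
  ca <- correspondenceAnalysis(x)
  k <- length(inertia(ca))
  mc <- MASS::corresp(x, nf = min(k, 4))
  expect_equal(sqrt(inertia(ca))[seq_along(mc$cor)], unname(mc$cor),
               tolerance = 1e-8)
})
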