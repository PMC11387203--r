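test_that("readFasta normalizes case and RNA alphabet and validates input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "acgt"), f)
  out <- readFasta(f)
  expect_equal(as.character(out), c(x = "ACGT"))

  writeLines(c(">u", "acgu"), f)
  expect_equal(unname(as.character(readFasta(f))), "ACGT")

  writeLines(c(">a", "ACG", ">a", "T"), f)
  expect_error(readFasta(f), "duplicate")

  writeLines(c(">a", "ACXGT"), f)
  expect_error(readFasta(f), "illegal")

  writeLines(c(">a", "AC-GT"), f)
  expect_error(readFasta(f), "illegal")
  expect_equal(unname(as.character(readFasta(f, allowGaps = TRUE))), "AC-GT")

  file.create(f2 <- withr::local_tempfile(fileext = ".fasta"))
  expect_error(readFasta(f2), "parse error")
})

test_that("FASTA round-trips byte-identically modulo line wrap", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(s1 = strrep("ACGTN", 33), s2 = "ATGCCC")
  writeFasta(seqs, f)
  back <- readFasta(f)
  expect_equal(as.character(back), seqs)
})

test_that("feature tables parse, validate and reject bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tclass\tstart\tend\tstrand",
               "ND2\tPCG\t1\t945\t+",
               "trnQ\ttRNA\t1000\t1065\t−"), f)
  ft <- readFeatureTable(f)
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$gene, c("ND2", "trnQ"))
  expect_equal(ft$start, c(1L, 1000L))
  expect_equal(ft$strand, c("+", "-"))  # Unicode minus accepted

  writeLines("ND2\tgene\t1\t945\t+", f)
  expect_error(readFeatureTable(f), "unknown class")
  writeLines("ND2\tPCG\tx\t945\t+", f)
  expect_error(readFeatureTable(f), "coordinate")
})

test_that("origin-wrapping features require a circular record", {
  feats <- data.frame(gene = "trnQ", class = "tRNA", start = 100L, end = 30L,
                      strand = "-", stringsAsFactors = FALSE)
  seq <- strrep("ACGT", 50)
  expect_error(mitogenome("X", seq, feats, circular = FALSE), "wrapping")
  expect_s4_class(mitogenome("X", seq, feats, circular = TRUE), "Mitogenome")
})

test_that("extractGene handles strands and the circular origin", {
  rec <- mitogenome("X", "ATGCCC", circular = FALSE)
  expect_equal(extractGene(rec, list(start = 1, end = 3)), "ATG")
  expect_equal(extractGene(rec, list(start = 1, end = 3, strand = "-")), "CAT")

  circ <- mitogenome("C", "AAAT", circular = TRUE)
  expect_equal(extractGene(circ, list(start = 4, end = 2)), "TAA")
  lin <- mitogenome("L", "AAAT", circular = FALSE)
  expect_error(extractGene(lin, list(start = 4, end = 2)), "wrapping")
  expect_error(extractGene(circ, list(start = 1, end = 9)), "outside")
})

test_that("extraction is consistent under reverse complement and rotation", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  rec <- mitogenome("X", seq, circular = FALSE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  recRc <- mitogenome("XR", rc, circular = FALSE)
  for (iv in list(c(5, 20), c(1, 60), c(33, 41))) {
    plus <- extractGene(rec, list(start = iv[1], end = iv[2]))
    mirrored <- extractGene(recRc, list(start = 61 - iv[2], end = 61 - iv[1],
                                        strand = "-"))
    expect_equal(mirrored, plus)
  }

  # total extracted length is invariant to rotating a circular genome
  rot <- function(s, k) paste0(substr(s, k + 1, nchar(s)), substr(s, 1, k))
  feats <- data.frame(gene = c("a", "b"), class = c("PCG", "tRNA"),
                      start = c(50L, 10L), end = c(9L, 30L),
                      strand = c("+", "+"), stringsAsFactors = FALSE)
  lens <- function(rec) {
    ft <- features(rec)
    sum(vapply(seq_len(nrow(ft)), function(i) {
      nchar(extractGene(rec, as.list(ft[i, , drop = FALSE])))
    }, 0))
  }
  base <- mitogenome("R0", seq, feats, circular = TRUE)
  for (k in c(7, 23)) {
    shift <- function(p) (p - 1 + k) %% 60 + 1  # same features after rotation
    featsK <- feats
    featsK$start <- as.integer(vapply(feats$start, shift, 0))
    featsK$end <- as.integer(vapply(feats$end, shift, 0))
    rotated <- mitogenome("Rk", rot(seq, 60 - k), featsK, circular = TRUE)
    expect_equal(lens(rotated), lens(base))
  }
})

test_that("codingSequence splits into triplets with trailing partial", {
  cs <- codingSequence("ATGAAATAA", "g")
  expect_equal(codons(cs), c("ATG", "AAA", "TAA"))
  expect_equal(trailingPartial(cs), 0L)

  cs <- codingSequence("ATGAAAT")
  expect_equal(codons(cs), c("ATG", "AAA"))
  expect_equal(trailingPartial(cs), 1L)

  cs <- codingSequence("ATGAATAATT")
  expect_equal(codons(cs), c("ATG", "AAT", "AAT"))
  expect_equal(trailingPartial(cs), 1L)

  cs <- codingSequence("AT")
  expect_length(codons(cs), 0L)
  expect_equal(trailingPartial(cs), 2L)
  expect_error(codingSequence(""), "empty")
})

test_that("the GenBank flat-file subset is parsed into a Mitogenome", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TEST0001                40 bp    DNA     circular INV 01-JAN-2024",
    "DEFINITION  Toy mitochondrion.",
    "ACCESSION   TEST0001",
    "SOURCE      Toy toyensis",
    "  ORGANISM  Toy toyensis",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..9",
    "                     /gene=\"ND9\"",
    "     tRNA            complement(10..15)",
    "                     /product=\"trnQ\"",
    "     rRNA            join(35..40,1..4)",
    "                     /gene=\"srRNA\"",
    "ORIGIN      ",
    "        1 atgaaataac ccgggtttac gtacgtaaaa ccccggggtt",
    "//"), gb)
  rec <- readGenBank(gb)
  expect_s4_class(rec, "Mitogenome")
  expect_equal(accession(rec), "TEST0001")
  expect_equal(speciesName(rec), "Toy toyensis")
  expect_true(isCircular(rec))
  expect_equal(length(rec), 40L)
  ft <- features(rec)
  expect_equal(ft$class, c("PCG", "tRNA", "rRNA"))
  expect_equal(ft$gene, c("ND9", "trnQ", "srRNA"))
  expect_equal(ft$strand, c("+", "-", "+"))
  expect_equal(extractGene(rec, "ND9"), "ATGAAATAA")
  # join() wraps the origin: tail then head
  expect_equal(ft$start[3], 35L)
  expect_equal(ft$end[3], 4L)
  expect_equal(extractGene(rec, "srRNA"), paste0("GGGGTT", "ATGA"))
})

test_that("a generated genome round-trips through the writers and readers", {
  rec <- generateMitogenome(synthesisParams(genomeLength = 15000L, seed = 11L))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeMitogenome(rec, fa, tsv)
  seqs <- readFasta(fa)
  ft <- readFeatureTable(tsv)
  expect_equal(unname(as.character(seqs)[1]),
               as.character(genomeSequence(rec)))
  expect_equal(as.data.frame(ft), as.data.frame(features(rec)))
})
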