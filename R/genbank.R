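# Minimal GenBank flat-file reader: enough of the format to consume
# mitogenome annotations (LOCUS, ACCESSION, ORGANISM, the CDS/tRNA/rRNA/
# D-loop features with complement() and two-interval join(), ORIGIN).
# Not a general GenBank parser.

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses the subset of the GenBank format needed for mitogenome work:
#' the LOCUS length and circular flag, ACCESSION, ORGANISM, the feature
#' table entries `CDS` (mapped to class PCG), `tRNA`, `rRNA` and `D-loop`
#' (mapped to control_region) with `complement()` and a two-interval
#' `join()` spanning the circular origin, and the ORIGIN sequence block.
#' Feature names come from the `/gene` qualifier, falling back to
#' `/product`.
#'
#' @param path Path to a GenBank flat file.
#' @return A [Mitogenome-class].
#' @export
readGenBank <- function(path) {
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1L])) {
    stop("GenBank parse error: missing LOCUS line")
  }
  circular <- grepl("\\bcircular\\b", lines[1L], ignore.case = TRUE)
  accession <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[1L])
  accLine <- grep("^ACCESSION", lines, value = TRUE)
  if (length(accLine)) accession <- sub("^ACCESSION\\s+(\\S+).*$", "\\1", accLine[1L])
  species <- ""
  orgLine <- grep("^\\s+ORGANISM", lines, value = TRUE)
  if (length(orgLine)) species <- sub("^\\s+ORGANISM\\s+", "", orgLine[1L])

  # sequence
  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop("GenBank parse error: missing ORIGIN block")
  seqLines <- lines[seq.int(oi[1L] + 1L, length(lines))]
  endi <- grep("^//", seqLines)
  if (length(endi)) seqLines <- seqLines[seq_len(endi[1L] - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nzchar(seq)) stop("GenBank parse error: empty sequence")

  # features
  fi <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fi)) {
    block <- lines[seq.int(fi[1L] + 1L, oi[1L] - 1L)]
    keyIdx <- grep("^ {5}\\S", block)
    for (j in seq_along(keyIdx)) {
      i0 <- keyIdx[j]
      i1 <- if (j < length(keyIdx)) keyIdx[j + 1L] - 1L else length(block)
      key <- sub("^ {5}(\\S+).*$", "\\1", block[i0])
      cls <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                    "D-loop" = "control_region", NULL)
      if (is.null(cls)) next
      body <- paste(trimws(block[i0:i1]), collapse = " ")
      loc <- sub(paste0("^", key, "\\s+"), "", trimws(block[i0]))
      parsed <- parseGenBankLocation(loc, nchar(seq))
      gene <- NA_character_
      m <- regmatches(body, regexpr("/gene=\"[^\"]+\"", body))
      if (length(m) && nzchar(m)) gene <- sub("/gene=\"([^\"]+)\"", "\\1", m)
      if (is.na(gene)) {
        m <- regmatches(body, regexpr("/product=\"[^\"]+\"", body))
        if (length(m) && nzchar(m)) gene <- sub("/product=\"([^\"]+)\"", "\\1", m)
      }
      if (is.na(gene)) gene <- paste0(key, "_", parsed$start)
      feats[[length(feats) + 1L]] <- list(gene = gene, class = cls,
                                          start = parsed$start,
                                          end = parsed$end,
                                          strand = parsed$strand)
    }
  }
  ftab <- if (length(feats)) {
    featureTable(
      gene   = vapply(feats, `[[`, "", "gene"),
      class  = vapply(feats, `[[`, "", "class"),
      start  = vapply(feats, function(f) f$start, 0L),
      end    = vapply(feats, function(f) f$end, 0L),
      strand = vapply(feats, `[[`, "", "strand")
    )
  } else {
    featureTable(character(), character(), integer(), integer(), character())
  }
  mitogenome(accession, seq, ftab, species = species, circular = circular)
}

# Location subset: "a..b", "complement(LOC)", "join(a..b,c..d)" where the
# two join intervals span the circular origin (tail + head).
parseGenBankLocation <- function(loc, genomeLength) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("GenBank parse error: only two-interval join() supported: ", loc)
    }
    iv <- lapply(parts, parseInterval)
    if (iv[[1L]]$end != genomeLength || iv[[2L]]$start != 1L) {
      stop("GenBank parse error: join() must span the circular origin: ", loc)
    }
    return(list(start = iv[[1L]]$start, end = iv[[2L]]$end, strand = strand))
  }
  iv <- parseInterval(loc)
  list(start = iv$start, end = iv$end, strand = strand)
}

parseInterval <- function(x) {
  if (!grepl("^\\d+\\.\\.\\d+$", x)) {
    stop("GenBank parse error: unsupported location: ", x)
  }
  parts <- as.integer(strsplit(x, "..", fixed = TRUE)[[1L]])
  list(start = parts[1L], end = parts[2L])
}
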