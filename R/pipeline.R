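#' Pipeline configuration
#'
#' Validates the options of the full analysis run before any computation.
#'
#' @param genomes List of [Mitogenome-class] objects, or `NULL` to read
#'   them from `inputDir`.
#' @param inputDir Directory holding paired `<name>.fasta` +
#'   `<name>.features.tsv` files (as written by [writeMitogenome()]).
#' @param alignments Named list of per-gene alignments for the diversity
#'   stage (optional; without it the diversity output has headers only).
#' @param outDir Output directory (created if needed).
#' @param hi,lo RSCU representation thresholds (default 1.6 / 0.6).
#' @param window,step Sliding-window width and step in alignment columns
#'   (default 200 / 20; `window >= step` required).
#' @param caSource Value matrix for correspondence analysis: `"rscu"` or
#'   `"counts"`.
#' @param seed Seed recorded in the manifest (the analyses themselves are
#'   deterministic).
#' @param format `"tsv"` or `"csv"`.
#' @return Validated configuration list for [runAll()].
#' @export
runConfig <- function(genomes = NULL, inputDir = NULL, alignments = NULL,
                      outDir = "mitocub-out", hi = 1.6, lo = 0.6,
                      window = 200L, step = 20L,
                      caSource = c("rscu", "counts"), seed = 1L,
                      format = c("tsv", "csv")) {
  caSource <- match.arg(caSource)
  format <- match.arg(format)
  if (!is.null(genomes)) stopifnot(all(vapply(genomes, is, TRUE, "Mitogenome")))
  if (is.null(genomes) && is.null(inputDir)) {
    stop("config error: provide genomes or inputDir")
  }
  if (hi <= lo) stop("config error: hi threshold must exceed lo")
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L) stop("config error: window and step must be >= 1")
  if (window < step) stop("config error: window must be >= step")
  list(genomes = genomes, inputDir = inputDir, alignments = alignments,
       outDir = outDir, hi = hi, lo = lo, window = window, step = step,
       caSource = caSource, seed = as.integer(seed), format = format)
}

#' Load genomes from a directory
#'
#' @param dir Directory with paired `<name>.fasta` and
#'   `<name>.features.tsv` files.
#' @return List of [Mitogenome-class] objects.
#' @export
loadGenomeDir <- function(dir) {
  fastas <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(fastas)) stop("no FASTA files in ", dir)
  lapply(fastas, function(fa) {
    ftp <- sub("\\.(fa|fasta)$", ".features.tsv", fa)
    if (!file.exists(ftp)) stop("missing feature table for ", fa)
    seqs <- readFasta(fa)
    id <- strsplit(names(seqs)[1L], " ", fixed = TRUE)[[1L]][1L]
    mitogenome(accession = id, sequence = as.character(seqs[[1L]]),
               features = as.data.frame(readFeatureTable(ftp)),
               species = sub("^\\S+\\s*", "", names(seqs)[1L]),
               circular = TRUE)
  })
}

# round to fixed decimals for display columns, keeping the raw value in a
# companion *_raw column
withFixed <- function(df, cols, digits) {
  for (col in intersect(cols, names(df))) {
    df[[paste0(col, "_raw")]] <- df[[col]]
    df[[col]] <- round(df[[col]], digits)
  }
  df
}

writeTable <- function(df, name, config) {
  sep <- if (config$format == "csv") "," else "\t"
  ext <- config$format
  path <- file.path(config$outDir, paste0(name, ".", ext))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

#' Run the full mitogenome codon-usage analysis
#'
#' Orchestrates every stage over a set of annotated genomes and writes one
#' table per figure-style output: `composition` (per region class),
#' `diversity` (sliding-window and per-gene Pi, when alignments are
#' supplied), `rscu_matrix` and `representation`, `start_stop`, `pr2`,
#' `neutrality`, `ca_axes` and `ca_coords`, `aa_usage`, `gravy`, plus a
#' `manifest.json` recording package version, configuration and seed. The
#' tables add no computation of their own: every number is regenerable by
#' calling the underlying function directly.
#'
#' Per-genome failures are isolated: a genome that cannot be analyzed is
#' dropped with a message, and the run only fails if all genomes fail.
#'
#' @param config From [runConfig()].
#' @return Invisibly, a named list of output file paths.
#' @export
runAll <- function(config) {
  genomes <- config$genomes
  if (is.null(genomes)) genomes <- loadGenomeDir(config$inputDir)
  ok <- logical(length(genomes))
  for (i in seq_along(genomes)) {
    ok[i] <- tryCatch({
      validObject(genomes[[i]])
      length(codingSequences(genomes[[i]])) > 0L
    }, error = function(e) FALSE)
    if (!ok[i]) message("dropping genome ", i, ": not analyzable")
  }
  genomes <- genomes[ok]
  if (!length(genomes)) stop("all genomes failed validation")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  comp <- withFixed(compositionTable(genomes),
                    c("atContent", "gcContent"), 4)
  comp <- withFixed(comp, c("atSkew", "gcSkew"), 3)
  paths$composition <- writeTable(comp, "composition", config)

  div <- if (!is.null(config$alignments)) {
    cat_ <- concatenateAlignments(config$alignments)
    sw <- slidingWindowPi(cat_$alignment, config$window, config$step)
    pg <- perGeneDiversity(config$alignments)
    rbind(
      data.frame(kind = "window", gene = NA_character_, start = sw$start,
                 end = sw$end, midpoint = sw$midpoint, length = NA_integer_,
                 pi = sw$pi, stringsAsFactors = FALSE),
      data.frame(kind = "gene", gene = pg$gene,
                 start = cat_$boundaries$start[match(pg$gene, cat_$boundaries$gene)],
                 end = cat_$boundaries$end[match(pg$gene, cat_$boundaries$gene)],
                 midpoint = NA_real_, length = pg$length, pi = pg$pi,
                 stringsAsFactors = FALSE)
    )
  } else {
    data.frame(kind = character(), gene = character(), start = integer(),
               end = integer(), midpoint = numeric(), length = integer(),
               pi = numeric(), stringsAsFactors = FALSE)
  }
  paths$diversity <- writeTable(withFixed(div, "pi", 3), "diversity", config)

  rscuTables <- lapply(genomes, function(g) {
    rscu(countCodons(codingSequences(g), species = speciesName(g)))
  })
  long <- do.call(rbind, lapply(seq_along(genomes), function(i) {
    cbind(species = speciesName(genomes[[i]]),
          accession = accession(genomes[[i]]),
          rscuTables[[i]], stringsAsFactors = FALSE)
  }))
  paths$rscu_matrix <- writeTable(withFixed(long, "rscu", 2),
                                  "rscu_matrix", config)

  consensus <- meanRscu(rscuTables)
  rep_ <- classifyRepresentation(consensus, hi = config$hi, lo = config$lo)
  consensus$class <- ifelse(consensus$codon %in% rep_$over, "over",
                            ifelse(consensus$codon %in% rep_$under, "under",
                                   "none"))
  paths$representation <- writeTable(withFixed(consensus, "rscu", 2),
                                     "representation", config)

  paths$start_stop <- writeTable(startStopTable(genomes), "start_stop", config)

  pr2 <- pr2Table(genomes)
  means <- do.call(rbind, lapply(split(pr2, pr2$gene), function(d) {
    data.frame(gene = d$gene[1L], species = "(mean)",
               atBias = mean(d$atBias, na.rm = TRUE),
               gcBias = mean(d$gcBias, na.rm = TRUE), stringsAsFactors = FALSE)
  }))
  paths$pr2 <- writeTable(withFixed(rbind(pr2, means), c("atBias", "gcBias"), 3),
                          "pr2", config)

  neut <- if (length(genomes) >= 3L) {
    withFixed(neutralityTable(genomes), c("slope", "intercept", "r"), 3)
  } else {
    message("neutrality regression needs >= 3 genomes; writing headers only")
    data.frame(gene = character(), slope = numeric(), intercept = numeric(),
               r = numeric(), p = numeric(), n = integer(),
               significance = character(), stringsAsFactors = FALSE)
  }
  paths$neutrality <- writeTable(neut, "neutrality", config)

  cas <- if (length(genomes) >= 2L) {
    caByGene(genomes, source = config$caSource)
  } else {
    message("correspondence analysis needs >= 2 genomes; writing headers only")
    list()
  }
  axes <- do.call(rbind, lapply(names(cas), function(g) {
    k <- length(inertia(cas[[g]]))
    if (!k) return(NULL)
    data.frame(gene = g, axis = seq_len(k), inertia = inertia(cas[[g]]),
               percent = axisPercent(cas[[g]]), stringsAsFactors = FALSE)
  }))
  if (is.null(axes)) {
    axes <- data.frame(gene = character(), axis = integer(),
                       inertia = numeric(), percent = numeric())
  }
  paths$ca_axes <- writeTable(withFixed(axes, "percent", 2), "ca_axes", config)

  coords <- do.call(rbind, lapply(names(cas), function(g) {
    ca <- cas[[g]]
    if (!length(inertia(ca))) return(NULL)
    ax <- function(m, j) if (ncol(m) >= j) m[, j] else rep(NA_real_, nrow(m))
    rbind(
      data.frame(gene = g, type = "codon", label = rownames(rowCoords(ca)),
                 axis1 = ax(rowCoords(ca), 1L), axis2 = ax(rowCoords(ca), 2L),
                 stringsAsFactors = FALSE),
      data.frame(gene = g, type = "species", label = rownames(colCoords(ca)),
                 axis1 = ax(colCoords(ca), 1L), axis2 = ax(colCoords(ca), 2L),
                 stringsAsFactors = FALSE)
    )
  }))
  if (is.null(coords)) {
    coords <- data.frame(gene = character(), type = character(),
                         label = character(), axis1 = numeric(),
                         axis2 = numeric())
  }
  paths$ca_coords <- writeTable(coords, "ca_coords", config)

  allCds <- unlist(lapply(genomes, codingSequences), use.names = FALSE)
  paths$aa_usage <- writeTable(withFixed(aminoAcidUsage(allCds), "freq", 4),
                               "aa_usage", config)

  gm <- gravyTable(genomes)
  gdf <- data.frame(species = rownames(gm), round(gm, 3),
                    check.names = FALSE, stringsAsFactors = FALSE)
  paths$gravy <- writeTable(gdf, "gravy", config)

  manifest <- list(
    package = "mitoCUB",
    version = as.character(packageVersion("mitoCUB")),
    nGenomes = length(genomes),
    accessions = vapply(genomes, accession, ""),
    config = config[c("hi", "lo", "window", "step", "caSource", "seed",
                      "format")]
  )
  manifestPath <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  paths$manifest <- manifestPath
  invisible(paths)
}
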