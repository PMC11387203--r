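#' Accessors for Mitogenome and related objects
#'
#' @param x A [Mitogenome-class], [CodingSequence-class], [CodonCounts-class]
#'   or [CAResult-class] object, as applicable.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))

#' @rdname accessors
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))

#' @rdname accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("codons", function(x) standardGeneric("codons"))

#' @rdname accessors
#' @export
setGeneric("trailingPartial", function(x) standardGeneric("trailingPartial"))

#' @rdname accessors
#' @export
setGeneric("codonCounts", function(x) standardGeneric("codonCounts"))

#' @rdname accessors
#' @export
setGeneric("stopCounts", function(x) standardGeneric("stopCounts"))

#' @rdname accessors
#' @export
setGeneric("rowCoords", function(x) standardGeneric("rowCoords"))

#' @rdname accessors
#' @export
setGeneric("colCoords", function(x) standardGeneric("colCoords"))

#' @rdname accessors
#' @export
setGeneric("inertia", function(x) standardGeneric("inertia"))

#' @rdname accessors
#' @export
setGeneric("axisPercent", function(x) standardGeneric("axisPercent"))

#' @rdname accessors
setMethod("accession", "Mitogenome", function(x) x@accession)

#' @rdname accessors
setMethod("speciesName", "Mitogenome", function(x) x@species)

#' @rdname accessors
setMethod("genomeSequence", "Mitogenome", function(x) x@sequence)

#' @rdname accessors
setMethod("isCircular", "Mitogenome", function(x) x@circular)

#' @rdname accessors
setMethod("features", "Mitogenome", function(x) x@features)

#' @rdname accessors
setMethod("length", "Mitogenome", function(x) length(x@sequence))

#' @rdname accessors
setMethod("codons", "CodingSequence", function(x) x@codons)

#' @rdname accessors
setMethod("trailingPartial", "CodingSequence", function(x) nchar(x@trailing))

#' @rdname accessors
setMethod("length", "CodingSequence", function(x) length(x@codons))

#' @rdname accessors
setMethod("codonCounts", "CodonCounts", function(x) x@counts)

#' @rdname accessors
setMethod("stopCounts", "CodonCounts", function(x) x@stopCounts)

#' @rdname accessors
setMethod("rowCoords", "CAResult", function(x) x@rowCoords)

#' @rdname accessors
setMethod("colCoords", "CAResult", function(x) x@colCoords)

#' @rdname accessors
setMethod("inertia", "CAResult", function(x) x@inertia)

#' @rdname accessors
setMethod("axisPercent", "CAResult", function(x) x@percent)

setMethod("show", "Mitogenome", function(object) {
  ft <- object@features
  cat("Mitogenome:", object@accession,
      if (nzchar(object@species)) paste0("(", object@species, ")") else "",
      "\n")
  cat(" ", length(object@sequence), "bp,",
      if (object@circular) "circular" else "linear", "\n")
  if (nrow(ft)) {
    tab <- table(factor(ft$class, levels = featureClasses()))
    cat("  features:", paste(paste0(tab, " ", names(tab)), collapse = ", "), "\n")
  } else {
    cat("  features: none\n")
  }
  invisible(object)
})

setMethod("show", "CodingSequence", function(object) {
  cat("CodingSequence:", object@gene,
      paste0("(", length(object@codons), " codons"),
      if (nchar(object@trailing))
        paste0("+ ", nchar(object@trailing), " nt incomplete stop)") else ")",
      "strand", object@strand, "\n")
  invisible(object)
})

setMethod("show", "CodonCounts", function(object) {
  cat("CodonCounts [", object@scope, "] ",
      if (nzchar(object@species)) paste0(object@species, " ") else "",
      sum(object@counts), " codons",
      if (length(object@stopCounts)) paste0(" (+", sum(object@stopCounts),
                                            " stops excluded)"),
      "\n", sep = "")
  invisible(object)
})

setMethod("show", "CAResult", function(object) {
  k <- length(object@inertia)
  cat("Correspondence analysis:", nrow(object@rowCoords), "rows x",
      nrow(object@colCoords), "cols,", k, "axes\n")
  if (k) {
    cat("  axis % inertia:",
        paste(sprintf("%.2f", object@percent[seq_len(min(k, 5L))]),
              collapse = ", "),
        if (k > 5L) "...", "\n")
  }
  invisible(object)
})
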