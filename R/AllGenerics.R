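#' @rdname CorrectionResult-class
#' @param object,x a `CorrectionResult`.
#' @export
setGeneric("correctedTranscripts",
           function(x) standardGeneric("correctedTranscripts"))

#' @rdname CorrectionResult-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname CorrectionResult-class
#' @export
setGeneric("selectedCds", function(x) standardGeneric("selectedCds"))

#' @rdname CorrectionResult-class
#' @export
setGeneric("skippedCds", function(x) standardGeneric("skippedCds"))

#' @rdname CorrectionResult-class
#' @export
setGeneric("unalignedIds", function(x) standardGeneric("unalignedIds"))

#' @rdname CorrectionResult-class
#' @export
setGeneric("correctionTable", function(x) standardGeneric("correctionTable"))

#' @rdname SyntheticTruth-class
#' @param object,x a `SyntheticTruth`.
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("cdsTable", function(x) standardGeneric("cdsTable"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("effectiveTpm", function(x) standardGeneric("effectiveTpm"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("artifactContigs", function(x) standardGeneric("artifactContigs"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("artifactLabels", function(x) standardGeneric("artifactLabels"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("truthPaf", function(x) standardGeneric("truthPaf"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("trueCdsSequences", function(x) standardGeneric("trueCdsSequences"))

#' @rdname AssemblyEvaluation-class
#' @param object,x an `AssemblyEvaluation`.
#' @export
setGeneric("capturedPct", function(x) standardGeneric("capturedPct"))

#' @rdname AssemblyEvaluation-class
#' @export
setGeneric("captureTable", function(x) standardGeneric("captureTable"))

#' @rdname AssemblyEvaluation-class
#' @export
setGeneric("misassemblies", function(x) standardGeneric("misassemblies"))

setMethod("correctedTranscripts", "CorrectionResult",
          function(x) x@transcripts)
setMethod("provenance", "CorrectionResult", function(x) x@provenance)
setMethod("selectedCds", "CorrectionResult", function(x) x@selectedCds)
setMethod("skippedCds", "CorrectionResult", function(x) x@skippedCds)
setMethod("unalignedIds", "CorrectionResult", function(x) x@unalignedIds)
setMethod("correctionTable", "CorrectionResult", function(x) x@table)

setMethod("show", "CorrectionResult", function(object) {
    cat("CorrectionResult\n")
    cat("  corrected transcripts :", length(object@transcripts), "\n")
    cat("  selected CDS          :", nrow(object@selectedCds), "\n")
    cat("  skipped CDS           :", nrow(object@skippedCds), "\n")
    cat("  unaligned transcripts :", length(object@unalignedIds), "\n")
    cat("  dropped insertions    :", object@droppedInsertions, "\n")
    if (length(object@transcripts)) {
        fr <- mean(vapply(strsplit(object@provenance, ""),
                          function(p) mean(p == "T"), numeric(1)))
        cat("  mean transcript-derived fraction:", round(fr, 3), "\n")
    }
})

setMethod("genomes", "SyntheticTruth", function(x) x@genomes)
setMethod("cdsTable", "SyntheticTruth", function(x) x@cds)
setMethod("abundances", "SyntheticTruth", function(x) x@abundance)
setMethod("effectiveTpm", "SyntheticTruth", function(x) x@effectiveTpm)
setMethod("artifactContigs", "SyntheticTruth", function(x) x@contigs)
setMethod("artifactLabels", "SyntheticTruth", function(x) x@artifactLabels)
setMethod("truthPaf", "SyntheticTruth", function(x) x@truthPaf)

#' Extract the true coding-sense CDS sequences of a simulated community
#' @rdname SyntheticTruth-class
#' @export
setMethod("trueCdsSequences", "SyntheticTruth", function(x) {
    seqs <- vapply(seq_len(nrow(x@cds)), function(i) {
        row <- x@cds[i, ]
        s <- substr(as.character(x@genomes[[row$contig_id]]),
                    row$start + 1L, row$end)
        if (row$strand == "-") revComp(s) else s
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- x@cds$feature_id
    out
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth (seed", object@seed, ")\n")
    cat("  genomes   :", length(object@genomes), "\n")
    cat("  CDS       :", nrow(object@cds),
        sprintf("(%d expressed)", sum(object@effectiveTpm > 0)), "\n")
    cat("  contigs   :", length(object@contigs), "\n")
    if (length(object@artifactLabels)) {
        tab <- table(object@artifactLabels)
        cat("  artifact classes:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
})

setMethod("capturedPct", "AssemblyEvaluation", function(x) x@capturedPct)
setMethod("captureTable", "AssemblyEvaluation", function(x) x@captureTable)
setMethod("misassemblies", "AssemblyEvaluation", function(x) x@misassemblies)

setMethod("show", "AssemblyEvaluation", function(object) {
    cat("AssemblyEvaluation\n")
    cat("  sequences assembled :", object@nSequences, "\n")
    cat("  unaligned sequences :", object@nUnaligned, "\n")
    cat("  captured (%)        :", round(object@capturedPct, 1), "\n")
    cat("  misassembly calls   :", nrow(object@misassemblies), "\n")
})
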