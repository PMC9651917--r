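#' Single-alignment capture fractions per reference
#'
#' A reference is captured when one single alignment covers at least
#' `minFraction` of its bases (default 0.95, inclusive). Unions of several
#' alignments never count: fragmented reconstructions must not score as
#' complete.
#'
#' @param refs named [Biostrings::DNAStringSet] of reference sequences, or a
#'   named integer vector of reference lengths.
#' @param paf PAF data.frame of assembly-to-reference alignments (reference
#'   as target).
#' @param minFraction capture threshold in `[0, 1]`.
#' @return data.frame with `ref_id`, `best_single_fraction`, `captured` and
#'   `best_aln` (row index into `paf`, NA when unaligned).
#' @export
captureFractions <- function(refs, paf, minFraction = 0.95) {
    if (methods::is(refs, "DNAStringSet")) {
        lens <- stats::setNames(Biostrings::width(refs), names(refs))
    } else {
        lens <- refs
    }
    if (is.null(names(lens)) || anyDuplicated(names(lens))) {
        argStop("references must have unique names")
    }
    frac <- rep(0, length(lens))
    bestAln <- rep(NA_integer_, length(lens))
    if (nrow(paf)) {
        alnFrac <- (paf$tend - paf$tstart) / paf$tlen
        for (i in seq_along(lens)) {
            hits <- which(paf$tname == names(lens)[i])
            if (length(hits)) {
                b <- hits[which.max(alnFrac[hits])]
                frac[i] <- alnFrac[b]
                bestAln[i] <- b
            }
        }
    }
    data.frame(ref_id = names(lens), best_single_fraction = frac,
               captured = frac >= minFraction, best_aln = bestAln,
               row.names = NULL, stringsAsFactors = FALSE)
}

# Reduce split parts of one query so they are mutually non-overlapping on the
# query: parts overlapping a better-matching kept part by more than
# `maxOverlap` of the shorter part are discarded.
.reduceParts <- function(parts, maxOverlap = 0.9) {
    ord <- order(-parts$matches, parts$qstart)
    keep <- integer(0)
    for (i in ord) {
        clash <- FALSE
        for (j in keep) {
            ov <- min(parts$qend[i], parts$qend[j]) -
                max(parts$qstart[i], parts$qstart[j])
            shorter <- min(parts$qend[i] - parts$qstart[i],
                           parts$qend[j] - parts$qstart[j])
            if (ov > maxOverlap * shorter) {
                clash <- TRUE
                break
            }
        }
        if (!clash) keep <- c(keep, i)
    }
    parts[sort(keep), , drop = FALSE]
}

#' Detect misassembled contigs from their genome alignments
#'
#' A contig is called misassembled when its split alignment parts either hit
#' different genomes (`inter_genome`) or map to the same genome at least
#' `gapBp` apart (`intra_gap`, inclusive at the boundary). Parts are first
#' reduced so that no two retained parts overlap by more than 90% on the
#' query (best-matching part wins); contiguous or single-part queries produce
#' no call.
#'
#' @param paf PAF data.frame of assembled transcripts aligned to reference
#'   genomes (one genome per target sequence).
#' @param gapBp minimum same-genome separation in bp (default 1000).
#' @return data.frame with `contig_id`, `kind` (`inter_genome` or
#'   `intra_gap`), `aln_i`, `aln_j` (row indices of the two evidence
#'   alignments) and `gap` (bp, NA for inter-genome calls).
#' @export
detectMisassemblies <- function(paf, gapBp = 1000L) {
    calls <- list()
    if (nrow(paf)) {
        paf$.row <- seq_len(nrow(paf))
        for (qn in unique(paf$qname)) {
            parts <- .reduceParts(paf[paf$qname == qn, , drop = FALSE])
            if (nrow(parts) < 2L) next
            parts <- parts[order(parts$qstart), , drop = FALSE]
            if (length(unique(parts$tname)) > 1L) {
                k <- which(parts$tname != parts$tname[1])[1]
                calls[[length(calls) + 1L]] <- data.frame(
                    contig_id = qn, kind = "inter_genome",
                    aln_i = parts$.row[1], aln_j = parts$.row[k],
                    gap = NA_integer_, stringsAsFactors = FALSE)
            } else {
                for (k in seq_len(nrow(parts) - 1L)) {
                    gap <- max(parts$tstart[k + 1L] - parts$tend[k],
                               parts$tstart[k] - parts$tend[k + 1L])
                    if (gap >= gapBp) {
                        calls[[length(calls) + 1L]] <- data.frame(
                            contig_id = qn, kind = "intra_gap",
                            aln_i = parts$.row[k], aln_j = parts$.row[k + 1L],
                            gap = as.integer(gap), stringsAsFactors = FALSE)
                    }
                }
            }
        }
    }
    if (!length(calls)) {
        return(data.frame(contig_id = character(0), kind = character(0),
                          aln_i = integer(0), aln_j = integer(0),
                          gap = integer(0), stringsAsFactors = FALSE))
    }
    do.call(rbind, calls)
}

#' Build the expressed-truth reference set
#'
#' For simulated data only genes that are actually expressed should count as
#' ground truth; the filter keeps references with TPM at least `minTpm`
#' (default 1, inclusive).
#'
#' @param expressionTable data.frame with columns `ref_id` (or `feature_id`
#'   or `transcript_id`) and `tpm`.
#' @param minTpm inclusive TPM cutoff.
#' @return Character vector of retained reference ids.
#' @export
buildTruthSet <- function(expressionTable, minTpm = 1.0) {
    idCol <- intersect(c("ref_id", "feature_id", "transcript_id"),
                       names(expressionTable))[1]
    if (is.na(idCol) || !"tpm" %in% names(expressionTable)) {
        argStop("expression table needs an id column and a 'tpm' column")
    }
    if (any(expressionTable$tpm < 0)) {
        argStop("negative TPM in expression table")
    }
    expressionTable[[idCol]][expressionTable$tpm >= minTpm]
}

#' Histogram of CDS completeness fractions
#'
#' Bins capture fractions over `[0, 1]` into `nBins` equal-width bins;
#' the last bin is right-inclusive so a fraction of exactly 1 is counted.
#'
#' @param fractions numeric vector in `[0, 1]`.
#' @param nBins number of bins (default 20).
#' @return data.frame with `bin_lo`, `bin_hi`, `count`; counts sum to
#'   `length(fractions)`.
#' @export
completenessHistogram <- function(fractions, nBins = 20L) {
    if (length(fractions) && (any(is.na(fractions)) ||
                              any(fractions < 0 | fractions > 1))) {
        argStop("fractions must lie in [0, 1]")
    }
    edges <- seq(0, 1, length.out = nBins + 1L)
    idx <- pmin(floor(fractions * nBins) + 1L, nBins)
    data.frame(bin_lo = edges[-(nBins + 1L)], bin_hi = edges[-1L],
               count = tabulate(idx, nbins = nBins))
}

#' Evaluate an assembly against a truth reference set
#'
#' Computes the summary statistics used to compare assemblies: number of
#' sequences, number with no alignment to the truth references, percentage of
#' truth references captured by a single alignment (after the TPM filter when
#' an expression table is given), and misassembly calls when genome
#' alignments are supplied.
#'
#' @param assembly named [Biostrings::DNAStringSet] of assembled sequences.
#' @param truthRefs named [Biostrings::DNAStringSet] of reference transcript
#'   sequences.
#' @param paf PAF of `assembly` aligned to `truthRefs`.
#' @param expression optional expression table for [buildTruthSet()].
#' @param genomePaf optional PAF of `assembly` aligned to reference genomes,
#'   used for misassembly detection.
#' @param minFraction capture threshold (default 0.95).
#' @param minTpm truth-set TPM cutoff (default 1).
#' @param gapBp same-genome misassembly gap (default 1000).
#' @return An [AssemblyEvaluation-class] object.
#' @export
evaluateAssembly <- function(assembly, truthRefs, paf, expression = NULL,
                             genomePaf = NULL, minFraction = 0.95,
                             minTpm = 1.0, gapBp = 1000L) {
    truthIds <- names(truthRefs)
    if (!is.null(expression)) {
        truthIds <- intersect(truthIds, buildTruthSet(expression, minTpm))
    }
    cap <- captureFractions(truthRefs[truthIds], paf,
                            minFraction = minFraction)
    mis <- if (is.null(genomePaf)) {
        detectMisassemblies(emptyPaf(), gapBp = gapBp)
    } else {
        detectMisassemblies(genomePaf, gapBp = gapBp)
    }
    methods::new("AssemblyEvaluation",
        nSequences = length(assembly),
        nUnaligned = sum(!names(assembly) %in% unique(paf$qname)),
        capturedPct = if (nrow(cap)) 100 * mean(cap$captured) else
            NA_real_,
        captureTable = cap,
        misassemblies = mis,
        truthIds = truthIds)
}

#' Exact-substring alignments of queries against references
#'
#' Builds PAF records for every query that occurs as an exact substring of a
#' reference, in either orientation. This is the evaluation route for
#' truth-known, error-free data, where reconstructed sequences are expected
#' to match their references exactly; it makes the desk-scale evaluation
#' loop independent of an external aligner.
#'
#' @param queries,refs named [Biostrings::DNAStringSet].
#' @return A PAF data.frame (first occurrence per query/reference/strand).
#' @export
exactMatchAlignments <- function(queries, refs) {
    qChr <- as.character(queries)
    rChr <- as.character(refs)
    rows <- list()
    for (i in seq_along(qChr)) {
        qlen <- nchar(qChr[i])
        for (strand in c("+", "-")) {
            probe <- if (strand == "+") qChr[i] else revComp(qChr[i])
            for (j in seq_along(rChr)) {
                if (qlen > nchar(rChr[j])) next
                at <- regexpr(probe, rChr[j], fixed = TRUE)
                if (at > 0) {
                    rows[[length(rows) + 1L]] <- data.frame(
                        qname = names(queries)[i], qlen = qlen,
                        qstart = 0L, qend = qlen, strand = strand,
                        tname = names(refs)[j], tlen = nchar(rChr[j]),
                        tstart = as.integer(at) - 1L,
                        tend = as.integer(at) - 1L + qlen,
                        matches = qlen, block_len = qlen, mapq = 60L,
                        tp = "P", cg = paste0(qlen, "M"),
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    if (!length(rows)) return(emptyPaf())
    out <- do.call(rbind, rows)
    out$tags <- rep(list(character(0)), nrow(out))
    out
}

#' Write an evaluation report to TSV and JSON
#'
#' @param eval an [AssemblyEvaluation-class].
#' @param tsvPath,jsonPath,histPath output paths (`NULL` to skip);
#'   `histPath` receives the completeness histogram.
#' @param nBins histogram bins.
#' @return Invisibly, `eval`.
#' @export
writeEvaluation <- function(eval, tsvPath = NULL, jsonPath = NULL,
                            histPath = NULL, nBins = 20L) {
    stopifnot(methods::is(eval, "AssemblyEvaluation"))
    summary <- data.frame(
        n_sequences = eval@nSequences,
        n_unaligned = eval@nUnaligned,
        captured_pct = eval@capturedPct,
        n_misassemblies = nrow(eval@misassemblies),
        n_misassembled_contigs = length(unique(eval@misassemblies$contig_id)))
    if (!is.null(tsvPath)) {
        utils::write.table(summary, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    if (!is.null(jsonPath)) {
        jsonlite::write_json(c(as.list(summary),
                               list(capture = eval@captureTable)),
                             jsonPath, auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(histPath)) {
        hist <- completenessHistogram(eval@captureTable$best_single_fraction,
                                      nBins = nBins)
        utils::write.table(hist, histPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(eval)
}
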