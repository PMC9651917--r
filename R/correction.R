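#' Build the consensus sequence for one selected CDS
#'
#' Walks the CDS interval in genome-forward coordinates. At every position
#' covered by at least one alignment segment, the base of the winning
#' segment's transcript is emitted (label `T`), so that variants observed in
#' the RNA evidence are preserved over the genomic base; uncovered positions
#' are filled from the genome (label `G`). The winner at a position is the
#' segment whose source alignment has the most matches, ties broken by higher
#' mapping quality, then by lexicographically smallest transcript id —
#' deterministic regardless of input order. Transcript insertions relative to
#' the genome are dropped (counted, not emitted) so the output length always
#' equals the CDS length; a position where the winning transcript carries a
#' deletion falls back to the next-best transcript base, or to the genome.
#' For a minus-strand CDS the result is reverse complemented into coding
#' sense and the provenance labels reversed with it.
#'
#' @param cds one CDS feature (list or one-row data.frame).
#' @param genomeSeq character scalar, the full sequence of the CDS's contig.
#' @param segments segment data.frame for this CDS ([computeCdsCoverage()]).
#' @param paf the PAF data.frame the segments' `aln_ref` indices point into.
#' @param transcriptSeqs named character vector (or coercible
#'   [Biostrings::DNAStringSet]) of transcript contig sequences.
#' @return A list with `id`, `seq`, `provenance` (string over `{T,G}`),
#'   `cds_ref`, `status`, `source_contigs` and `dropped_insertions`.
#' @export
buildConsensus <- function(cds, genomeSeq, segments, paf, transcriptSeqs) {
    if (methods::is(transcriptSeqs, "DNAStringSet")) {
        transcriptSeqs <- stats::setNames(as.character(transcriptSeqs),
                                          names(transcriptSeqs))
    }
    len <- cds$end - cds$start
    cons <- strsplit(substr(genomeSeq, cds$start + 1L, cds$end), "")[[1]]
    if (length(cons) != len) {
        integrityStop("CDS ", cds$feature_id, " exceeds contig bounds")
    }
    prov <- rep("G", len)
    dropped <- 0L
    if (nrow(segments)) {
        m <- paf$matches[segments$aln_ref]
        mq <- paf$mapq[segments$aln_ref]
        qn <- paf$qname[segments$aln_ref]
        # locale-independent rank so the tie-break is fully deterministic
        qr <- match(qn, sort(unique(qn), method = "radix"))
        # apply from worst to best so the winner's bases land last
        for (i in order(m, mq, -qr)) {
            aln <- paf[segments$aln_ref[i], , drop = FALSE]
            tseq <- transcriptSeqs[[aln$qname]]
            if (is.null(tseq) || nchar(tseq) != aln$qlen) {
                integrityStop("alignment of ", aln$qname,
                              " inconsistent with transcript length")
            }
            if (segments$q_hi[i] > aln$qlen) {
                integrityStop("segment query interval exceeds transcript ",
                              aln$qname)
            }
            qmap <- queryMapForTarget(aln)
            tpos <- segments$t_lo[i]:(segments$t_hi[i] - 1L)
            qpos <- qmap[tpos - aln$tstart + 1L]
            ok <- !is.na(qpos)
            if (any(ok)) {
                bases <- strsplit(tseq, "")[[1]][qpos[ok] + 1L]
                if (aln$strand == "-") bases <- complementBases(bases)
                rel <- tpos[ok] - cds$start + 1L
                cons[rel] <- bases
                prov[rel] <- "T"
            }
            dropped <- dropped + countInsertions(aln, segments$t_lo[i],
                                                 segments$t_hi[i])
        }
    }
    if (cds$strand == "-") {
        cons <- rev(complementBases(cons))
        prov <- rev(prov)
    }
    list(id = paste0(cds$feature_id, "|corrected"),
         seq = paste(cons, collapse = ""),
         provenance = paste(prov, collapse = ""),
         cds_ref = cds$feature_id,
         status = "aligned",
         source_contigs = sort(unique(paf$qname[segments$aln_ref])),
         dropped_insertions = dropped)
}

# Count transcript insertion events anchored inside [tLo, tHi) of an
# alignment's target span. Insertions do not consume target bases, so they
# are anchored at the target coordinate where they occur.
countInsertions <- function(aln, tLo, tHi) {
    if (is.na(aln$cg)) return(0L)
    ops <- parseCigar(aln$cg)
    tcur <- aln$tstart
    n <- 0L
    for (k in seq_along(ops$op)) {
        op <- ops$op[k]
        if (op == "I" && tcur >= tLo && tcur < tHi) n <- n + 1L
        if (op %in% c("M", "=", "X", "D", "N")) tcur <- tcur + ops$len[k]
    }
    n
}

# Summarise a list of coverage objects into a data.frame.
coverageSummary <- function(coverages) {
    if (!length(coverages)) {
        return(data.frame(cds_ref = character(0), covered_bases = integer(0),
                          fraction = numeric(0), stringsAsFactors = FALSE))
    }
    data.frame(
        cds_ref = vapply(coverages, `[[`, character(1), "cds_ref"),
        covered_bases = vapply(coverages, `[[`, integer(1), "covered_bases"),
        fraction = vapply(coverages, `[[`, numeric(1), "fraction"),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Correct a metatranscriptome assembly against an annotated metagenome
#'
#' The central procedure: transcript-to-genome alignments are filtered,
#' projected onto every annotated coding region, coding regions with at least
#' `threshold` of their bases covered by transcript evidence are selected,
#' and one full-length transcript is built per selected CDS by concatenating
#' fragment-derived bases and filling gaps from the genome. Operon splitting
#' and intergenic trimming are emergent: a contig overlapping k coding
#' regions contributes segments to all k (k outputs), and bases mapping
#' outside every CDS never appear in any output because output length is
#' fixed to CDS length.
#'
#' @param transcripts named [Biostrings::DNAStringSet] of assembled
#'   transcript contigs.
#' @param genomeSeqs named [Biostrings::DNAStringSet] of metagenomic contigs.
#' @param cdsTable CDS annotation ([readGffCds()]).
#' @param alignments PAF data.frame of transcript-to-genome alignments.
#' @param threshold minimum covered fraction for a CDS to be corrected
#'   (default 0.5, inclusive).
#' @param minBlock,primaryOnly,minIdentity see [filterAlignments()].
#' @return A [CorrectionResult-class] object.
#' @export
correctAssembly <- function(transcripts, genomeSeqs, cdsTable, alignments,
                            threshold = 0.5, minBlock = 100L,
                            primaryOnly = TRUE, minIdentity = 0) {
    validatePaf(alignments)
    badQ <- setdiff(unique(alignments$qname), names(transcripts))
    if (length(badQ)) {
        integrityStop("alignments reference unknown transcript id(s): ",
                      paste(badQ, collapse = ", "))
    }
    badT <- setdiff(unique(alignments$tname), names(genomeSeqs))
    if (length(badT)) {
        integrityStop("alignments reference unknown genomic contig(s): ",
                      paste(badT, collapse = ", "))
    }
    badC <- setdiff(unique(cdsTable$contig_id), names(genomeSeqs))
    if (length(badC)) {
        integrityStop("annotation references unknown genomic contig(s): ",
                      paste(badC, collapse = ", "))
    }
    filtered <- filterAlignments(alignments, minBlock = minBlock,
                                 primaryOnly = primaryOnly,
                                 minIdentity = minIdentity)
    covs <- computeAllCoverages(filtered, cdsTable)
    sel <- selectCoveredCds(covs, threshold)
    skipped <- covs[setdiff(names(covs), names(sel))]
    genomeChr <- stats::setNames(as.character(genomeSeqs), names(genomeSeqs))
    txChr <- stats::setNames(as.character(transcripts), names(transcripts))
    built <- lapply(names(sel), function(fid) {
        cds <- cdsTable[match(fid, cdsTable$feature_id), , drop = FALSE]
        buildConsensus(cds, genomeChr[[cds$contig_id]], sel[[fid]]$segments,
                       filtered, txChr)
    })
    ids <- vapply(built, `[[`, character(1), "id")
    seqs <- Biostrings::DNAStringSet(vapply(built, `[[`, character(1),
                                            "seq"))
    names(seqs) <- ids
    selRows <- match(names(sel), cdsTable$feature_id)
    tab <- if (!length(sel)) {
        data.frame(id = character(0), cds_ref = character(0),
                   contig = character(0), start = integer(0),
                   end = integer(0), strand = character(0),
                   fraction = numeric(0), status = character(0),
                   source_contigs = character(0), stringsAsFactors = FALSE)
    } else data.frame(
        id = ids,
        cds_ref = vapply(built, `[[`, character(1), "cds_ref"),
        contig = cdsTable$contig_id[selRows],
        start = cdsTable$start[selRows],
        end = cdsTable$end[selRows],
        strand = cdsTable$strand[selRows],
        fraction = vapply(sel, `[[`, numeric(1), "fraction"),
        status = "aligned",
        source_contigs = vapply(built, function(b)
            paste(b$source_contigs, collapse = ","), character(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    part <- partitionTranscripts(filtered, names(transcripts))
    methods::new("CorrectionResult",
        transcripts = seqs,
        provenance = vapply(built, `[[`, character(1), "provenance"),
        table = tab,
        selectedCds = coverageSummary(sel),
        skippedCds = coverageSummary(skipped),
        unalignedIds = part$unaligned,
        droppedInsertions = sum(vapply(built, `[[`, integer(1),
                                       "dropped_insertions")))
}

#' Write corrected transcripts to FASTA and a companion TSV
#'
#' FASTA headers carry `cds=<feature_id> status=aligned
#' provenance_T=<fraction>`; the TSV has one row per corrected transcript
#' with its CDS placement, coverage fraction and supporting contigs.
#'
#' @param result a [CorrectionResult-class].
#' @param fastaPath,tsvPath output paths (either may be `NULL` to skip).
#' @return Invisibly, `result`.
#' @export
writeCorrected <- function(result, fastaPath = NULL, tsvPath = NULL) {
    stopifnot(methods::is(result, "CorrectionResult"))
    if (!is.null(fastaPath)) {
        fracT <- vapply(strsplit(result@provenance, ""),
                        function(p) mean(p == "T"), numeric(1))
        out <- result@transcripts
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(
            description = sprintf("cds=%s status=%s provenance_T=%.4f",
                                  result@table$cds_ref, result@table$status,
                                  fracT))
        writeFasta(out, fastaPath)
    }
    if (!is.null(tsvPath)) {
        utils::write.table(result@table, tsvPath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(result)
}
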