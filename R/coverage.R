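#' Filter transcript-to-genome alignments
#'
#' Drops short alignment blocks, secondary alignments and low-identity hits
#' before coverage computation. Order is preserved; row names keep the
#' original row indices so segments can reference their source alignment.
#'
#' @param paf a PAF data.frame ([readPaf()]).
#' @param minBlock minimum alignment block length in bp (default 100; blocks
#'   shorter than a typical read add little evidence and much noise).
#' @param primaryOnly drop records tagged `tp:A:S` (secondary)? Default TRUE
#'   so that one transcript copy supports each locus; set FALSE for
#'   paralog-rich communities.
#' @param minIdentity minimum `matches / block_len` (default 0).
#' @return The filtered PAF data.frame.
#' @export
filterAlignments <- function(paf, minBlock = 100L, primaryOnly = TRUE,
                             minIdentity = 0) {
    validatePaf(paf)
    if (nrow(paf) == 0L) return(paf)
    keep <- paf$block_len >= minBlock &
        paf$matches / paf$block_len >= minIdentity
    if (primaryOnly) {
        keep <- keep & (is.na(paf$tp) | paf$tp != "S")
    }
    paf[keep, , drop = FALSE]
}

#' Map aligned target positions to query positions
#'
#' For one alignment, returns the 0-based query coordinate (on the original
#' query strand) aligned to each target position `tstart .. tend-1`. With a
#' `cg` CIGAR the mapping is base-accurate and positions inside deletions are
#' `NA`; without one, coordinates are interpolated linearly across the block
#' assuming a collinear gapless mapping.
#'
#' @param aln a single-row PAF data.frame (or a list with the PAF fields).
#' @return Integer vector of length `tend - tstart`.
#' @keywords internal
queryMapForTarget <- function(aln) {
    span <- aln$tend - aln$tstart
    if (is.na(aln$cg)) {
        scale <- (aln$qend - aln$qstart) / span
        off <- seq_len(span) - 1L
        q <- if (aln$strand == "+") {
            aln$qstart + floor(off * scale)
        } else {
            r <- (aln$qlen - aln$qend) + floor(off * scale)
            aln$qlen - 1L - r
        }
        return(as.integer(q))
    }
    ops <- parseCigar(aln$cg)
    qpos <- rep(NA_integer_, span)
    tcur <- 0L
    # CIGAR coordinates run in alignment orientation: for '-' the query is
    # reverse complemented, so walk in rc coordinates and convert at the end.
    qcur <- if (aln$strand == "+") aln$qstart else aln$qlen - aln$qend
    for (k in seq_along(ops$op)) {
        len <- ops$len[k]
        op <- ops$op[k]
        if (op %in% c("M", "=", "X")) {
            qpos[tcur + seq_len(len)] <- qcur + seq_len(len) - 1L
            tcur <- tcur + len
            qcur <- qcur + len
        } else if (op %in% c("I", "S")) {
            qcur <- qcur + len
        } else if (op %in% c("D", "N")) {
            tcur <- tcur + len
        } else {
            parseStop("unsupported CIGAR op '", op, "'")
        }
    }
    if (aln$strand == "-") qpos <- aln$qlen - 1L - qpos
    as.integer(qpos)
}

#' Project one alignment onto one CDS
#'
#' Intersects the alignment's target interval with the CDS interval and maps
#' the intersection back to query coordinates (base-accurate when a CIGAR is
#' present). Returns `NULL` when the alignment does not touch the CDS.
#'
#' @param aln single-row PAF data.frame; `aln$tname` must equal
#'   `cds$contig_id`.
#' @param cds a single CDS feature (one row of [readGffCds()] output, as a
#'   list or data.frame).
#' @param alnRef integer index identifying the source alignment.
#' @return A one-row data.frame with columns `cds_ref`, `aln_ref`, `t_lo`,
#'   `t_hi`, `q_lo`, `q_hi`, or `NULL`.
#' @export
projectToCds <- function(aln, cds, alnRef = 1L) {
    if (aln$tname != cds$contig_id) {
        argStop("alignment target ", aln$tname,
                " does not match CDS contig ", cds$contig_id)
    }
    tLo <- max(aln$tstart, cds$start)
    tHi <- min(aln$tend, cds$end)
    if (tLo >= tHi) return(NULL)
    qmap <- queryMapForTarget(aln)
    qSeg <- qmap[(tLo - aln$tstart + 1L):(tHi - aln$tstart)]
    qSeg <- qSeg[!is.na(qSeg)]
    if (length(qSeg)) {
        qLo <- min(qSeg)
        qHi <- max(qSeg) + 1L
    } else {
        # whole intersection falls in a transcript deletion: zero-length span
        qLo <- qHi <- if (aln$strand == "+") aln$qstart else aln$qend
    }
    data.frame(cds_ref = cds$feature_id, aln_ref = as.integer(alnRef),
               t_lo = tLo, t_hi = tHi, q_lo = qLo, q_hi = qHi,
               stringsAsFactors = FALSE)
}

#' Compute union coverage of one CDS by transcript alignments
#'
#' Projects every alignment on the CDS's contig onto the CDS interval and
#' reports the size of the union of the projected target intervals, as an
#' absolute base count and as a fraction of CDS length.
#'
#' @param paf filtered PAF data.frame.
#' @param cds one CDS feature (list/one-row data.frame).
#' @return A list with `cds_ref`, `covered_bases`, `fraction` and a
#'   `segments` data.frame (see [projectToCds()]).
#' @export
computeCdsCoverage <- function(paf, cds) {
    segs <- list()
    if (nrow(paf) > 0L) {
        onContig <- which(paf$tname == cds$contig_id &
                          paf$tstart < cds$end & paf$tend > cds$start)
        segs <- lapply(onContig, function(i)
            projectToCds(paf[i, , drop = FALSE], cds, alnRef = i))
        segs <- segs[!vapply(segs, is.null, logical(1))]
    }
    segments <- if (length(segs)) do.call(rbind, segs) else
        data.frame(cds_ref = character(0), aln_ref = integer(0),
                   t_lo = integer(0), t_hi = integer(0),
                   q_lo = integer(0), q_hi = integer(0),
                   stringsAsFactors = FALSE)
    covered <- 0L
    if (nrow(segments)) {
        ir <- IRanges::reduce(IRanges::IRanges(start = segments$t_lo + 1L,
                                               end = segments$t_hi))
        covered <- sum(IRanges::width(ir))
    }
    list(cds_ref = cds$feature_id,
         covered_bases = as.integer(covered),
         fraction = covered / (cds$end - cds$start),
         segments = segments)
}

#' Compute coverage for every CDS in an annotation table
#'
#' @param paf filtered PAF data.frame.
#' @param cdsTable CDS table from [readGffCds()].
#' @return Named list of per-CDS coverage objects ([computeCdsCoverage()]).
#' @export
computeAllCoverages <- function(paf, cdsTable) {
    out <- lapply(seq_len(nrow(cdsTable)), function(i)
        computeCdsCoverage(paf, cdsTable[i, , drop = FALSE]))
    names(out) <- cdsTable$feature_id
    out
}

#' Select coding regions with sufficient transcript coverage
#'
#' Keeps CDS whose covered fraction is at least `threshold` (inclusive: a CDS
#' at exactly the threshold is selected).
#'
#' @param coverages list of coverage objects ([computeAllCoverages()]).
#' @param threshold required covered fraction in `[0, 1]` (default 0.5).
#' @return The selected subset of `coverages`.
#' @export
selectCoveredCds <- function(coverages, threshold = 0.5) {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        is.na(threshold) || threshold < 0 || threshold > 1) {
        argStop("threshold must be a number in [0, 1]")
    }
    coverages[vapply(coverages, function(x) x$fraction >= threshold,
                     logical(1))]
}

#' Partition transcript ids into aligned and unaligned sets
#'
#' Transcripts absent from the surviving alignments (for example mRNA of
#' dietary origin in gut samples, which has no source genome in the
#' metagenome) are routed to the orphan path.
#'
#' @param paf filtered PAF data.frame.
#' @param transcriptIds character vector of all transcript ids.
#' @return List with character vectors `aligned` and `unaligned`; the two
#'   partition `transcriptIds`.
#' @export
partitionTranscripts <- function(paf, transcriptIds) {
    aligned <- intersect(transcriptIds, unique(paf$qname))
    list(aligned = aligned,
         unaligned = setdiff(transcriptIds, aligned))
}
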