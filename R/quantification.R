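#' Count reads per transcript from read-to-transcript alignments
#'
#' Each read contributes total weight 1, assigned to its best-scoring
#' targets (maximal `matches`). Under the default `fractional` policy the
#' weight is split equally among tied best targets — homologous genes are the
#' central difficulty of diverse communities, and zeroing multi-mappers would
#' bias whole homolog families; under `unique`, multi-mapped reads contribute
#' nothing.
#'
#' @param paf PAF data.frame of reads aligned to the transcript set.
#' @param mapqMin minimum mapping quality (default 0).
#' @param multimap `"fractional"` or `"unique"`.
#' @param transcriptIds optional character vector fixing the output universe;
#'   transcripts without reads get count 0.
#' @return Named numeric vector of (possibly fractional) counts.
#' @export
countFromAlignments <- function(paf, mapqMin = 0L,
                                multimap = c("fractional", "unique"),
                                transcriptIds = NULL) {
    multimap <- match.arg(multimap)
    ids <- unique(c(transcriptIds, paf$tname))
    counts <- stats::setNames(numeric(length(ids)), ids)
    keep <- paf$mapq >= mapqMin
    paf <- paf[keep, , drop = FALSE]
    if (nrow(paf)) {
        best <- stats::aggregate(matches ~ qname, data = paf, FUN = max)
        bestOf <- stats::setNames(best$matches, best$qname)
        isBest <- paf$matches == bestOf[paf$qname]
        paf <- paf[isBest, , drop = FALSE]
        # one vote per (read, transcript) even if several best hits coincide
        paf <- paf[!duplicated(paf[, c("qname", "tname")]), , drop = FALSE]
        nTargets <- table(paf$qname)
        w <- if (multimap == "fractional") {
            1 / as.numeric(nTargets[paf$qname])
        } else {
            as.numeric(nTargets[paf$qname] == 1L)
        }
        agg <- tapply(w, paf$tname, sum)
        counts[names(agg)] <- as.numeric(agg)
    }
    counts
}

#' Transcripts-per-million from counts and lengths
#'
#' `rate_i = count_i / length_i`; `tpm_i = 1e6 * rate_i / sum(rate)`. TPM
#' sums to one million whenever any read was counted; an all-zero count
#' vector yields all-zero TPM.
#'
#' @param counts named numeric vector of per-transcript counts.
#' @param lengths named numeric vector of transcript lengths (bp), aligned
#'   with `counts` by name.
#' @return data.frame with `transcript_id`, `length`, `count`, `tpm`.
#' @export
tpmFromCounts <- function(counts, lengths) {
    if (!is.null(names(lengths)) && !is.null(names(counts))) {
        if (!all(names(counts) %in% names(lengths))) {
            argStop("missing lengths for: ",
                    paste(setdiff(names(counts), names(lengths)),
                          collapse = ", "))
        }
        lengths <- lengths[names(counts)]
    }
    if (length(lengths) != length(counts)) {
        argStop("counts and lengths must align")
    }
    if (any(lengths <= 0)) {
        argStop("transcript lengths must be positive")
    }
    rate <- counts / lengths
    tot <- sum(rate)
    tpm <- if (tot > 0) 1e6 * rate / tot else rate * 0
    data.frame(transcript_id = names(counts), length = unname(lengths),
               count = unname(counts), tpm = unname(tpm),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Map fixed-length reads to transcripts by exact matching
#'
#' Finds every exact occurrence of each read in the transcript set (forward
#' orientation) and reports them as PAF records — the desk-scale mapping
#' route for error-free simulated reads, where exact matching recovers the
#' full multi-mapping structure across homologous transcripts.
#'
#' @param reads [Biostrings::DNAStringSet] of equal-width reads.
#' @param transcripts named [Biostrings::DNAStringSet].
#' @return A PAF data.frame with one record per (read, transcript) hit.
#' @export
mapReadsExact <- function(reads, transcripts) {
    if (length(unique(Biostrings::width(reads))) > 1L) {
        argStop("reads must have equal width for dictionary matching")
    }
    if (length(reads) == 0L) return(emptyPaf())
    pd <- Biostrings::PDict(reads)
    readLen <- Biostrings::width(reads)[1]
    rows <- vector("list", length(transcripts))
    for (j in seq_along(transcripts)) {
        m <- Biostrings::matchPDict(pd, transcripts[[j]])
        cnt <- S4Vectors::elementNROWS(m)
        hit <- which(cnt > 0L)
        if (!length(hit)) next
        firstStart <- vapply(hit, function(i)
            BiocGenerics::start(m[[i]])[1], integer(1))
        rows[[j]] <- data.frame(
            qname = names(reads)[hit], qlen = readLen, qstart = 0L,
            qend = readLen, strand = "+",
            tname = names(transcripts)[j],
            tlen = Biostrings::width(transcripts)[j],
            tstart = firstStart - 1L, tend = firstStart - 1L + readLen,
            matches = readLen, block_len = readLen, mapq = 60L,
            tp = "P", cg = paste0(readLen, "M"), stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(emptyPaf())
    out <- do.call(rbind, rows)
    out$tags <- rep(list(character(0)), nrow(out))
    rownames(out) <- NULL
    out
}
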