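.stopCodons <- c("TAA", "TAG", "TGA")  # genetic code table 11

#' Find open reading frames in all six frames
#'
#' Scans the three forward and three reverse frames for maximal ORFs: runs
#' from the first accepted start codon after the previous stop to the next
#' in-frame stop codon, or to the end of the sequence (3'-partial ORFs are
#' allowed). Uses the bacterial genetic code (table 11), whose canonical
#' start codons are ATG, GTG and TTG.
#'
#' @param seq DNA sequence (character scalar or [Biostrings::DNAString]).
#' @param minAa minimum ORF length in amino acids, counting the start codon
#'   and excluding the stop (default 100, the conventional long-ORF cutoff).
#' @param starts accepted start codons.
#' @param transcriptId optional id recorded with each call.
#' @return data.frame with columns `transcript_id`, `frame` (0-2 forward,
#'   3-5 reverse), `start`, `end` (0-based half-open on the coding-sense
#'   strand after frame resolution; `end` excludes the stop codon) and
#'   `aa_len`, sorted by `aa_len` descending.
#' @export
findOrfs <- function(seq, minAa = 100L, starts = c("ATG", "GTG", "TTG"),
                     transcriptId = NA_character_) {
    seq <- toupper(as.character(seq))
    n <- nchar(seq)
    res <- list()
    for (frame in 0:5) {
        s <- if (frame < 3) seq else revComp(seq)
        off <- frame %% 3
        k <- (n - off) %/% 3
        if (k < 1L) next
        pos <- off + 3L * (seq_len(k) - 1L)
        codons <- substring(s, pos + 1L, pos + 3L)
        startIdx <- NA_integer_
        for (j in seq_len(k)) {
            if (codons[j] %in% .stopCodons) {
                if (!is.na(startIdx) && j - startIdx >= minAa) {
                    res[[length(res) + 1L]] <- c(frame, pos[startIdx],
                                                 pos[startIdx] + 3L *
                                                     (j - startIdx),
                                                 j - startIdx)
                }
                startIdx <- NA_integer_
            } else if (is.na(startIdx) && codons[j] %in% starts) {
                startIdx <- j
            }
        }
        if (!is.na(startIdx) && k + 1L - startIdx >= minAa) {
            # 3'-partial ORF running off the end of the transcript
            res[[length(res) + 1L]] <- c(frame, pos[startIdx],
                                         pos[startIdx] +
                                             3L * (k + 1L - startIdx),
                                         k + 1L - startIdx)
        }
    }
    if (!length(res)) {
        return(data.frame(transcript_id = character(0), frame = integer(0),
                          start = integer(0), end = integer(0),
                          aa_len = integer(0), stringsAsFactors = FALSE))
    }
    m <- do.call(rbind, res)
    out <- data.frame(transcript_id = transcriptId, frame = m[, 1],
                      start = m[, 2], end = m[, 3], aa_len = m[, 4],
                      stringsAsFactors = FALSE)
    out[order(-out$aa_len, out$frame, out$start), , drop = FALSE]
}

#' Select coding candidates among unaligned transcripts
#'
#' Keeps unaligned transcript contigs that contain at least one ORF of
#' `minAa` amino acids or more — the candidates worth rescuing even though
#' they have no source genome in the metagenome (for example dietary mRNA in
#' gut samples). Kept records are labelled `status = "unaligned"`.
#'
#' @param records [Biostrings::DNAStringSet] of unaligned transcripts.
#' @param minAa minimum ORF length in amino acids.
#' @return The kept subset, with a `status` metadata column.
#' @export
selectCoding <- function(records, minAa = 100L) {
    keep <- vapply(seq_along(records), function(i)
        nrow(findOrfs(records[[i]], minAa = minAa)) > 0L, logical(1))
    out <- records[keep]
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        status = rep("unaligned", length(out)))
    out
}

# Cheap k-mer prefilter: fraction of the shorter sequence's distinct k-mers
# present in the other sequence. Only used to skip hopeless alignments.
.kmerShare <- function(a, b, k = 8L) {
    ka <- unique(substring(a, seq_len(nchar(a) - k + 1L),
                           seq_len(nchar(a) - k + 1L) + k - 1L))
    mean(vapply(ka, function(x) grepl(x, b, fixed = TRUE), logical(1)))
}

# Identity and shorter-sequence coverage of the best local alignment of a
# against b (both character scalars), trying both orientations.
.pairIdentity <- function(a, b) {
    if (nchar(a) > nchar(b)) {
        tmp <- a; a <- b; b <- tmp
    }
    best <- c(identity = 0, cov = 0)
    for (q in c(a, revComp(a))) {
        if (.kmerShare(q, b) < 0.2) next
        al <- Biostrings::pairwiseAlignment(q, b, type = "local")
        idn <- Biostrings::pid(al, type = "PID1") / 100
        cov <- (Biostrings::nchar(al)) / nchar(a)
        if (idn * cov > best["identity"] * best["cov"]) {
            best <- c(identity = idn, cov = min(cov, 1))
        }
    }
    best
}

#' Greedy identity clustering of orphan candidates against corrected output
#'
#' Deduplicates the final transcript set: corrected (aligned) transcripts are
#' seeded as cluster centroids first, then orphan candidates are considered
#' in order of decreasing length. A candidate joins the first centroid it
#' matches with at least `minIdentity` over at least `minCov` of the shorter
#' sequence (exact-duplicate shortcut, then k-mer prefilter plus pairwise
#' alignment, both orientations); otherwise it becomes a new centroid. An
#' orphan duplicating a corrected transcript is therefore always absorbed.
#'
#' @param corrected [Biostrings::DNAStringSet] of corrected transcripts.
#' @param orphanCandidates [Biostrings::DNAStringSet] of unaligned coding
#'   candidates; id spaces must not overlap.
#' @param minIdentity minimum pairwise identity (default 0.95).
#' @param minCov minimum aligned coverage of the shorter sequence (0.9).
#' @return [Biostrings::DNAStringSet] of centroids with a `status` metadata
#'   column (`aligned` or `unaligned`); contains every corrected transcript
#'   exactly once and never two exact duplicates.
#' @export
clusterDedup <- function(corrected, orphanCandidates, minIdentity = 0.95,
                         minCov = 0.9) {
    if (length(intersect(names(corrected), names(orphanCandidates)))) {
        argStop("corrected and orphan id spaces overlap")
    }
    cent <- as.character(corrected)
    status <- rep("aligned", length(cent))
    names(status) <- names(corrected)
    cand <- orphanCandidates[order(-Biostrings::width(orphanCandidates))]
    for (i in seq_along(cand)) {
        s <- as.character(cand[[i]])
        if (s %in% cent || revComp(s) %in% cent) next
        absorbed <- FALSE
        for (j in seq_along(cent)) {
            hit <- .pairIdentity(s, cent[j])
            if (hit["identity"] >= minIdentity && hit["cov"] >= minCov) {
                absorbed <- TRUE
                break
            }
        }
        if (!absorbed) {
            cent <- c(cent, stats::setNames(s, names(cand)[i]))
            status <- c(status, stats::setNames("unaligned",
                                                names(cand)[i]))
        }
    }
    out <- Biostrings::DNAStringSet(cent)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(status = unname(status))
    out
}
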