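.codons61 <- {
    b <- c("A", "C", "G", "T")
    all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
    setdiff(all, c("TAA", "TAG", "TGA"))
}

# A random framed CDS: start codon, stop-free body, stop codon.
.randomCdsSeq <- function(len) {
    stopifnot(len %% 3 == 0, len >= 9)
    body <- sample(.codons61, len / 3 - 2L, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""),
           sample(.stopCodons, 1L))
}

# Copy-plus-mutate a framed CDS to a target identity, preserving the start
# and stop codons and never introducing an internal stop.
.mutateCds <- function(seq, identity) {
    codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
    nBody <- length(codons) - 2L
    pMut <- 1 - identity
    for (i in seq_len(nBody) + 1L) {
        muts <- which(stats::runif(3) < pMut)
        if (!length(muts)) next
        repeat {
            cd <- strsplit(codons[i], "")[[1]]
            for (p in muts) {
                cd[p] <- sample(setdiff(c("A", "C", "G", "T"), cd[p]), 1L)
            }
            cd <- paste(cd, collapse = "")
            if (!cd %in% .stopCodons) {
                codons[i] <- cd
                break
            }
        }
    }
    paste(codons, collapse = "")
}

#' Generate a random multi-genome community with framed CDS annotations
#'
#' Each genome is i.i.d. random DNA carrying `nCds` non-overlapping coding
#' regions, each a proper frame (start codon, stop-free body, in-frame stop),
#' with random strand and a length divisible by 3 drawn from `cdsLenRange`.
#' Optionally, `homologPairs` CDS are duplicated between genome pairs by
#' copy-plus-mutate at `homologIdentity`, emulating closely related strains
#' whose shared genes cause multi-mapping.
#'
#' @param nGenomes number of genomes.
#' @param genomeLen genome length in bp.
#' @param nCds coding regions per genome.
#' @param cdsLenRange CDS length range in bp (rounded down to codons).
#' @param seed integer seed; the same seed always reproduces the same
#'   community byte for byte.
#' @param minGap minimum intergenic distance in bp (default 120, leaving room
#'   for intergenic-extension artifacts and operon spans).
#' @param homologPairs number of cross-genome homologous CDS pairs.
#' @param homologIdentity nucleotide identity of homolog copies.
#' @return List with `genomes` ([Biostrings::DNAStringSet]) and `cds`
#'   (annotation data.frame, 0-based half-open).
#' @export
generateCommunity <- function(nGenomes = 5L, genomeLen = 50000L, nCds = 20L,
                              cdsLenRange = c(300L, 1500L), seed = 1L,
                              minGap = 120L, homologPairs = 0L,
                              homologIdentity = 0.97) {
    if (nGenomes < 1L || genomeLen < 1L || nCds < 1L) {
        argStop("community parameters must be positive")
    }
    withSeed(opSeed(seed, "generate_community"), {
        lo <- max(9L, 3L * (cdsLenRange[1] %/% 3L))
        hi <- 3L * (cdsLenRange[2] %/% 3L)
        if (hi < lo) argStop("invalid cdsLenRange")
        # shared length draw so cross-genome homolog slots line up
        lens <- 3L * sample((lo %/% 3L):(hi %/% 3L), nCds, replace = TRUE)
        if (sum(lens) + (nCds + 1L) * minGap > genomeLen) {
            argStop("cannot pack ", nCds, " CDS of total ", sum(lens),
                    " bp plus gaps into a ", genomeLen, " bp genome")
        }
        genomeIds <- sprintf("genome%02d", seq_len(nGenomes))
        cdsSeqs <- matrix(NA_character_, nrow = nGenomes, ncol = nCds)
        for (g in seq_len(nGenomes)) {
            for (j in seq_len(nCds)) {
                cdsSeqs[g, j] <- .randomCdsSeq(lens[j])
            }
        }
        if (homologPairs > 0L && nGenomes >= 2L) {
            picks <- sample(nCds, min(homologPairs, nCds))
            for (j in picks) {
                pair <- sample(nGenomes, 2L)
                cdsSeqs[pair[2], j] <- .mutateCds(cdsSeqs[pair[1], j],
                                                  homologIdentity)
            }
        }
        genomes <- character(nGenomes)
        cdsRows <- list()
        for (g in seq_len(nGenomes)) {
            chars <- sample(c("A", "C", "G", "T"), genomeLen, replace = TRUE)
            slack <- genomeLen - sum(lens) - (nCds + 1L) * minGap
            cutsU <- sort(stats::runif(nCds))
            extra <- diff(c(0, floor(cutsU * slack), slack))
            extra <- extra[seq_len(nCds + 1L)]
            starts <- integer(nCds)
            pos <- 0L
            for (j in seq_len(nCds)) {
                pos <- pos + minGap + extra[j]
                starts[j] <- pos
                pos <- pos + lens[j]
            }
            strands <- sample(c("+", "-"), nCds, replace = TRUE)
            for (j in seq_len(nCds)) {
                placed <- if (strands[j] == "+") cdsSeqs[g, j] else
                    revComp(cdsSeqs[g, j])
                chars[(starts[j] + 1L):(starts[j] + lens[j])] <-
                    strsplit(placed, "")[[1]]
                cdsRows[[length(cdsRows) + 1L]] <- data.frame(
                    contig_id = genomeIds[g], start = starts[j],
                    end = starts[j] + lens[j], strand = strands[j],
                    feature_id = sprintf("%s_cds%02d", genomeIds[g], j),
                    product = NA_character_, stringsAsFactors = FALSE)
            }
            genomes[g] <- paste(chars, collapse = "")
        }
        gset <- Biostrings::DNAStringSet(genomes)
        names(gset) <- genomeIds
        list(genomes = gset, cds = do.call(rbind, cdsRows))
    })
}

#' Assign random relative abundances to genomes
#'
#' Draws log-normal(0, sigma) values and normalises them to sum to 1 — a
#' skewed distribution resembling the uneven species abundances of real
#' communities.
#'
#' @param genomeIds character vector of genome ids.
#' @param sigma log-scale standard deviation (> 0).
#' @param seed integer seed.
#' @return Named numeric vector summing to 1.
#' @export
assignAbundances <- function(genomeIds, sigma = 1.0, seed = 1L) {
    if (sigma <= 0) argStop("sigma must be positive")
    withSeed(opSeed(seed, "assign_abundances"), {
        x <- stats::rlnorm(length(genomeIds), 0, sigma)
        stats::setNames(x / sum(x), genomeIds)
    })
}

#' Assign per-gene expression and effective TPM
#'
#' Per-gene expression is log-normal with a `zeroFraction` of silent genes;
#' the effective transcript abundance of a gene in the community is its
#' expression level multiplied by its species' relative abundance, normalised
#' to one million (TPM).
#'
#' @param cds CDS annotation table (needs `feature_id`, `contig_id`).
#' @param abundance named per-genome abundance ([assignAbundances()]).
#' @param sigma log-scale standard deviation of expression.
#' @param zeroFraction fraction of genes that are silent.
#' @param seed integer seed.
#' @return List with named numeric vectors `expression` and `effectiveTpm`
#'   (the latter sums to 1e6 unless everything is silent).
#' @export
assignExpression <- function(cds, abundance, sigma = 1.0,
                             zeroFraction = 0.1, seed = 1L) {
    if (abs(sum(abundance) - 1) > 1e-6) {
        argStop("abundances must be normalised")
    }
    withSeed(opSeed(seed, "assign_expression"), {
        n <- nrow(cds)
        expr <- stats::rlnorm(n, 0, sigma)
        silent <- stats::runif(n) < zeroFraction
        expr[silent] <- 0
        names(expr) <- cds$feature_id
        w <- expr * abundance[cds$contig_id]
        tpm <- if (sum(w) > 0) 1e6 * w / sum(w) else w
        names(tpm) <- cds$feature_id
        list(expression = expr, effectiveTpm = tpm)
    })
}

# One truth PAF row for a contig piece placed at genome[a, b).
.piecePaf <- function(qname, qlen, qstart, qend, strand, tname, tlen, a, b) {
    data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
               strand = strand, tname = tname, tlen = tlen,
               tstart = a, tend = b, matches = qend - qstart,
               block_len = qend - qstart, mapq = 60L, tp = "P",
               cg = paste0(qend - qstart, "M"), stringsAsFactors = FALSE)
}

#' Generate artifact transcript contigs with ground-truth alignments
#'
#' For every expressed CDS, emits one set of transcript contigs following a
#' drawn artifact class that emulates what de novo metatranscriptome
#' assemblers actually produce: `fragmented` (several overlapping pieces
#' jointly covering the CDS), `partial` (one piece covering a fraction drawn
#' from `partialRange`), `fragmented_partial` (two pieces with an internal
#' gap), `intergenic_extended` (full CDS plus genomic flanks), `operon_span`
#' (one contig covering two adjacent same-strand CDS), `chimeric` (splice of
#' pieces from two genomes, for misassembly testing) and `clean` (an exact
#' copy). Every piece's exact genome placement is recorded as a truth PAF
#' record with a CIGAR tag.
#'
#' @param genomes named [Biostrings::DNAStringSet].
#' @param cds CDS annotation table.
#' @param effectiveTpm named per-gene TPM; only genes with TPM > 0 get
#'   contigs.
#' @param mix named numeric of class proportions (must sum to 1).
#' @param errorRate per-base substitution rate injected into contigs.
#' @param seed integer seed.
#' @param partialRange covered-fraction range for partial classes.
#' @param flank intergenic flank length in bp.
#' @return List with `contigs` ([Biostrings::DNAStringSet]), `labels` (named
#'   character, contig to class) and `truthPaf` (PAF data.frame).
#' @export
makeArtifactContigs <- function(genomes, cds, effectiveTpm,
                                mix = c(fragmented = 0.25, partial = 0.25,
                                        fragmented_partial = 0.25,
                                        intergenic_extended = 0.25),
                                errorRate = 0, seed = 1L,
                                partialRange = c(0.5, 0.95), flank = 50L) {
    known <- c("fragmented", "partial", "fragmented_partial",
               "intergenic_extended", "operon_span", "chimeric", "clean")
    if (!all(names(mix) %in% known)) {
        argStop("unknown artifact class: ",
                paste(setdiff(names(mix), known), collapse = ", "))
    }
    if (abs(sum(mix) - 1) > 1e-6) argStop("mix proportions must sum to 1")
    genomeChr <- stats::setNames(as.character(genomes), names(genomes))
    glen <- stats::setNames(nchar(genomeChr), names(genomeChr))
    withSeed(opSeed(seed, "make_artifact_contigs"), {
        expressed <- cds[effectiveTpm[cds$feature_id] > 0, , drop = FALSE]
        classes <- sample(names(mix), nrow(expressed), replace = TRUE,
                          prob = mix)
        seqs <- character(0)
        labels <- character(0)
        pafRows <- list()
        piece <- function(qname, gname, a, b, strand) {
            s <- substr(genomeChr[[gname]], a + 1L, b)
            if (strand == "-") s <- revComp(s)
            seqs[[qname]] <<- s
            pafRows[[length(pafRows) + 1L]] <<- .piecePaf(
                qname, b - a, 0L, b - a, strand, gname, glen[[gname]], a, b)
        }
        for (i in seq_len(nrow(expressed))) {
            row <- expressed[i, ]
            fid <- row$feature_id
            L <- row$end - row$start
            cls <- classes[i]
            if (cls == "operon_span") {
                sameContig <- cds[cds$contig_id == row$contig_id, ,
                                  drop = FALSE]
                sameContig <- sameContig[order(sameContig$start), ,
                                         drop = FALSE]
                at <- match(fid, sameContig$feature_id)
                nxt <- if (at < nrow(sameContig) &&
                           sameContig$strand[at + 1L] == row$strand) {
                    sameContig[at + 1L, ]
                } else if (at > 1L &&
                           sameContig$strand[at - 1L] == row$strand) {
                    sameContig[at - 1L, ]
                } else NULL
                if (is.null(nxt)) {
                    warning("no adjacent same-strand CDS for ", fid,
                            "; falling back to a clean contig")
                    cls <- "clean"
                } else {
                    piece(paste0("tx_", fid, "_operon"), row$contig_id,
                          min(row$start, nxt$start), max(row$end, nxt$end),
                          row$strand)
                    labels[paste0("tx_", fid, "_operon")] <- "operon_span"
                    next
                }
            }
            if (cls == "chimeric") {
                others <- cds[cds$contig_id != row$contig_id, , drop = FALSE]
                if (!nrow(others)) {
                    warning("no second genome for chimeric contig of ", fid,
                            "; falling back to a clean contig")
                    cls <- "clean"
                } else {
                    oth <- others[sample(nrow(others), 1L), ]
                    l1 <- max(100L, round(0.6 * L))
                    l2 <- max(100L, round(0.4 * (oth$end - oth$start)))
                    qn <- paste0("tx_", fid, "_chimera")
                    s1 <- substr(genomeChr[[row$contig_id]],
                                 row$start + 1L, row$start + l1)
                    if (row$strand == "-") s1 <- revComp(s1)
                    s2 <- substr(genomeChr[[oth$contig_id]],
                                 oth$start + 1L, oth$start + l2)
                    if (oth$strand == "-") s2 <- revComp(s2)
                    seqs[[qn]] <- paste0(s1, s2)
                    qlen <- l1 + l2
                    # for '-' pieces the rc-aware PAF convention requires the
                    # query interval on the original strand
                    pafRows[[length(pafRows) + 1L]] <- .piecePaf(
                        qn, qlen, 0L, l1, row$strand, row$contig_id,
                        glen[[row$contig_id]], row$start, row$start + l1)
                    pafRows[[length(pafRows) + 1L]] <- .piecePaf(
                        qn, qlen, l1, qlen, oth$strand, oth$contig_id,
                        glen[[oth$contig_id]], oth$start, oth$start + l2)
                    labels[qn] <- "chimeric"
                    next
                }
            }
            if (cls == "clean") {
                qn <- paste0("tx_", fid, "_clean")
                piece(qn, row$contig_id, row$start, row$end, row$strand)
                labels[qn] <- "clean"
            } else if (cls == "fragmented") {
                n <- if (L >= 450L) sample(2:3, 1L) else 2L
                jit <- round(stats::runif(n - 1L, -L / (6 * n), L / (6 * n)))
                cuts <- sort(row$start + round(L / n * seq_len(n - 1L)) + jit)
                bounds <- c(row$start, cuts, row$end)
                for (k in seq_len(n)) {
                    qn <- paste0("tx_", fid, "_frag", k)
                    piece(qn, row$contig_id, bounds[k],
                          min(row$end, bounds[k + 1L] + 20L), row$strand)
                    labels[qn] <- "fragmented"
                }
            } else if (cls == "partial") {
                fr <- stats::runif(1, partialRange[1], partialRange[2])
                len <- max(100L, round(fr * L))
                off <- sample(0:(L - len), 1L)
                qn <- paste0("tx_", fid, "_part")
                piece(qn, row$contig_id, row$start + off,
                      row$start + off + len, row$strand)
                labels[qn] <- "partial"
            } else if (cls == "fragmented_partial") {
                fr <- stats::runif(1, partialRange[1], partialRange[2])
                tot <- min(L, max(210L, round(fr * L)))
                l1 <- max(100L, round(tot * stats::runif(1, 0.35, 0.65)))
                l2 <- max(100L, tot - l1)
                qn1 <- paste0("tx_", fid, "_fp1")
                qn2 <- paste0("tx_", fid, "_fp2")
                piece(qn1, row$contig_id, row$start, row$start + l1,
                      row$strand)
                piece(qn2, row$contig_id, row$end - l2, row$end, row$strand)
                labels[qn1] <- "fragmented_partial"
                labels[qn2] <- "fragmented_partial"
            } else if (cls == "intergenic_extended") {
                qn <- paste0("tx_", fid, "_ext")
                piece(qn, row$contig_id, max(0L, row$start - flank),
                      min(glen[[row$contig_id]], row$end + flank),
                      row$strand)
                labels[qn] <- "intergenic_extended"
            }
        }
        paf <- if (length(pafRows)) do.call(rbind, pafRows) else emptyPaf()
        if (nrow(paf)) {
            paf$tags <- rep(list(character(0)), nrow(paf))
            rownames(paf) <- NULL
        }
        if (errorRate > 0 && length(seqs)) {
            for (qn in names(seqs)) {
                ch <- strsplit(seqs[[qn]], "")[[1]]
                hit <- which(stats::runif(length(ch)) < errorRate)
                for (p in hit) {
                    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
                }
                seqs[[qn]] <- paste(ch, collapse = "")
                if (length(hit)) {
                    for (r in which(paf$qname == qn)) {
                        nIn <- sum(hit > paf$qstart[r] & hit <= paf$qend[r])
                        paf$matches[r] <- paf$matches[r] - nIn
                    }
                }
            }
        }
        contigs <- Biostrings::DNAStringSet(unlist(seqs))
        list(contigs = contigs, labels = labels, truthPaf = paf)
    })
}

#' Simulate error-free reads from a transcript set
#'
#' Reads are drawn from transcripts with probability proportional to
#' effective TPM times the number of possible start positions (fragment
#' sampling weights longer transcripts up), with uniform start positions.
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param effectiveTpm named numeric abundance, aligned by name.
#' @param nReads number of reads.
#' @param readLen read length (must not exceed the shortest expressed
#'   transcript).
#' @param seed integer seed.
#' @return List with `reads` ([Biostrings::DNAStringSet]) and `truth`
#'   (data.frame `read_id`, `transcript_id`, `start`).
#' @export
simulateReads <- function(transcripts, effectiveTpm, nReads = 10000L,
                          readLen = 100L, seed = 1L) {
    tpm <- effectiveTpm[names(transcripts)]
    tpm[is.na(tpm)] <- 0
    w <- tpm * pmax(0L, Biostrings::width(transcripts) - readLen + 1L)
    if (all(w == 0)) argStop("no transcript is both expressed and longer ",
                             "than the read length")
    withSeed(opSeed(seed, "simulate_reads"), {
        src <- sample(seq_along(transcripts), nReads, replace = TRUE,
                      prob = w / sum(w))
        nStarts <- Biostrings::width(transcripts) - readLen + 1L
        starts <- vapply(src, function(i) sample.int(nStarts[i], 1L),
                         integer(1))
        chr <- as.character(transcripts)
        readSeq <- substr(chr[src], starts, starts + readLen - 1L)
        ids <- sprintf("read%06d", seq_len(nReads))
        reads <- Biostrings::DNAStringSet(readSeq)
        names(reads) <- ids
        list(reads = reads,
             truth = data.frame(read_id = ids,
                                transcript_id = names(transcripts)[src],
                                start = starts - 1L,
                                stringsAsFactors = FALSE))
    })
}

#' Generate a complete synthetic community with ground truth
#'
#' One-call wrapper tying together [generateCommunity()],
#' [assignAbundances()], [assignExpression()] and [makeArtifactContigs()].
#' The single seed fans out to per-operation seeds, so each component is also
#' reproducible in isolation.
#'
#' @inheritParams generateCommunity
#' @inheritParams makeArtifactContigs
#' @param abundanceSigma,expressionSigma log-normal scale parameters.
#' @param zeroFraction fraction of silent genes.
#' @return A [SyntheticTruth-class] object.
#' @export
generateSyntheticTruth <- function(nGenomes = 5L, genomeLen = 50000L,
                                   nCds = 20L, cdsLenRange = c(300L, 1500L),
                                   abundanceSigma = 1.0,
                                   expressionSigma = 1.0,
                                   zeroFraction = 0.1,
                                   mix = c(fragmented = 0.25, partial = 0.25,
                                           fragmented_partial = 0.25,
                                           intergenic_extended = 0.25),
                                   errorRate = 0, seed = 1L,
                                   homologPairs = 0L,
                                   partialRange = c(0.5, 0.95),
                                   flank = 50L) {
    comm <- generateCommunity(nGenomes = nGenomes, genomeLen = genomeLen,
                              nCds = nCds, cdsLenRange = cdsLenRange,
                              seed = seed, homologPairs = homologPairs)
    ab <- assignAbundances(names(comm$genomes), sigma = abundanceSigma,
                           seed = seed)
    ex <- assignExpression(comm$cds, ab, sigma = expressionSigma,
                           zeroFraction = zeroFraction, seed = seed)
    art <- makeArtifactContigs(comm$genomes, comm$cds, ex$effectiveTpm,
                               mix = mix, errorRate = errorRate, seed = seed,
                               partialRange = partialRange, flank = flank)
    methods::new("SyntheticTruth",
        genomes = comm$genomes, cds = comm$cds, abundance = ab,
        expression = ex$expression, effectiveTpm = ex$effectiveTpm,
        contigs = art$contigs, artifactLabels = art$labels,
        truthPaf = art$truthPaf, seed = as.integer(seed))
}

#' Derive contig-to-CDS-transcript alignments from ground truth
#'
#' Projects every truth contig placement onto the coding regions it overlaps
#' and re-expresses the overlap in the coordinates of the coding-sense CDS
#' transcript. This gives exactly the alignments an aligner would report for
#' the raw artifact contigs against the true transcript set, derived
#' analytically instead of by running one.
#'
#' @param truth a [SyntheticTruth-class].
#' @return A PAF data.frame (targets are CDS feature ids).
#' @export
truthCdsAlignments <- function(truth) {
    cds <- truth@cds
    contigs <- stats::setNames(as.character(truth@contigs),
                               names(truth@contigs))
    cdsSeq <- stats::setNames(as.character(trueCdsSequences(truth)),
                              cds$feature_id)
    paf <- truth@truthPaf
    rows <- list()
    for (i in seq_len(nrow(paf))) {
        onContig <- cds[cds$contig_id == paf$tname[i] &
                        cds$start < paf$tend[i] &
                        cds$end > paf$tstart[i], , drop = FALSE]
        for (k in seq_len(nrow(onContig))) {
            cr <- onContig[k, ]
            lo <- max(paf$tstart[i], cr$start)
            hi <- min(paf$tend[i], cr$end)
            if (hi <= lo) next
            if (paf$strand[i] == "+") {
                qLo <- paf$qstart[i] + (lo - paf$tstart[i])
                qHi <- paf$qstart[i] + (hi - paf$tstart[i])
            } else {
                qLo <- paf$qstart[i] + (paf$tend[i] - hi)
                qHi <- paf$qstart[i] + (paf$tend[i] - lo)
            }
            if (cr$strand == "+") {
                cLo <- lo - cr$start
                cHi <- hi - cr$start
            } else {
                cLo <- cr$end - hi
                cHi <- cr$end - lo
            }
            strand <- if (paf$strand[i] == cr$strand) "+" else "-"
            qSub <- substr(contigs[[paf$qname[i]]], qLo + 1L, qHi)
            if (strand == "-") qSub <- revComp(qSub)
            tSub <- substr(cdsSeq[[cr$feature_id]], cLo + 1L, cHi)
            matches <- sum(strsplit(qSub, "")[[1]] ==
                           strsplit(tSub, "")[[1]])
            rows[[length(rows) + 1L]] <- data.frame(
                qname = paf$qname[i], qlen = paf$qlen[i],
                qstart = qLo, qend = qHi, strand = strand,
                tname = cr$feature_id, tlen = cr$end - cr$start,
                tstart = cLo, tend = cHi, matches = matches,
                block_len = hi - lo, mapq = 60L, tp = "P",
                cg = paste0(hi - lo, "M"), stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(emptyPaf())
    out <- do.call(rbind, rows)
    out$tags <- rep(list(character(0)), nrow(out))
    rownames(out) <- NULL
    out
}
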