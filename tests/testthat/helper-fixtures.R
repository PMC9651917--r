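# Shared fixtures and independent oracles for the test suite.

# Convenience PAF row constructor with sane defaults.
pafRow <- function(qname = "t1", qlen = 100L, qstart = 0L, qend = 100L,
                   strand = "+", tname = "c1", tlen = 1000L, tstart = 0L,
                   tend = 100L, matches = qend - qstart,
                   block_len = qend - qstart, mapq = 60L,
                   tp = NA_character_, cg = NA_character_) {
    df <- data.frame(qname = qname, qlen = qlen, qstart = qstart,
                     qend = qend, strand = strand, tname = tname,
                     tlen = tlen, tstart = tstart, tend = tend,
                     matches = matches, block_len = block_len, mapq = mapq,
                     tp = tp, cg = cg, stringsAsFactors = FALSE)
    df$tags <- rep(list(character(0)), nrow(df))
    df
}

pafBind <- function(...) {
    do.call(rbind, list(...))
}

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-base boolean-array coverage oracle: counts CDS positions covered by at
# least one alignment target interval, independent of interval arithmetic.
bruteCoverage <- function(cdsStart, cdsEnd, tstarts, tends) {
    covered <- rep(FALSE, cdsEnd - cdsStart)
    for (k in seq_along(tstarts)) {
        for (p in seq(cdsStart, cdsEnd - 1L)) {
            if (p >= tstarts[k] && p < tends[k]) {
                covered[p - cdsStart + 1L] <- TRUE
            }
        }
    }
    sum(covered)
}

# Independent six-frame maximal-ORF oracle. Enumerates every start codon,
# checks it is the first start of its stop-bounded region, and pairs it with
# the next in-frame stop (or the sequence end, 3'-partial).
bruteOrfs <- function(seq, minAa = 100L, starts = c("ATG", "GTG", "TTG")) {
    stops <- c("TAA", "TAG", "TGA")
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    out <- list()
    n <- nchar(seq)
    for (frame in 0:5) {
        s <- if (frame < 3) seq else rc(seq)
        off <- frame %% 3
        k <- (n - off) %/% 3
        if (k < 1) next
        pos <- off + 3L * (seq_len(k) - 1L)
        codons <- substring(s, pos + 1L, pos + 3L)
        stopIdx <- which(codons %in% stops)
        startIdx <- which(codons %in% starts)
        for (p in startIdx) {
            prevStop <- c(0L, stopIdx[stopIdx < p])
            prevStop <- max(prevStop)
            if (any(startIdx > prevStop & startIdx < p)) next
            after <- stopIdx[stopIdx > p]
            aaLen <- if (length(after)) min(after) - p else k + 1L - p
            if (aaLen >= minAa) {
                out[[length(out) + 1L]] <- data.frame(
                    frame = frame, start = pos[p],
                    end = pos[p] + 3L * aaLen, aa_len = aaLen)
            }
        }
    }
    if (!length(out)) {
        return(data.frame(frame = integer(0), start = integer(0),
                          end = integer(0), aa_len = integer(0)))
    }
    do.call(rbind, out)
}

# Small two-CDS single-genome fixture used by the correction tests. Returns
# genome (character), cds table and true coding-sense CDS sequences.
makeTinyGenome <- function(seed = 1) {
    set.seed(seed)
    g <- strsplit(randomDna(1200), "")[[1]]
    cds1 <- strsplit(paste0(
        "ATG", paste(rep("GCT", 98), collapse = ""), "TAA"), "")[[1]]
    cds2seq <- paste0("ATG", paste(rep("CAT", 58), collapse = ""), "TGA")
    cds2 <- strsplit(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds2seq))), "")[[1]]
    g[101:400] <- cds1           # plus strand at [100, 400)
    g[501:680] <- cds2           # minus strand at [500, 680)
    genome <- paste(g, collapse = "")
    cds <- data.frame(
        contig_id = "c1", start = c(100L, 500L), end = c(400L, 680L),
        strand = c("+", "-"), feature_id = c("g1", "g2"),
        product = NA_character_, stringsAsFactors = FALSE)
    list(genome = genome,
         genomes = setNames(Biostrings::DNAStringSet(genome), "c1"),
         cds = cds,
         trueCds = c(g1 = paste(g[101:400], collapse = ""), g2 = cds2seq))
}

# Extract a coding-sense transcript contig from a genome span, returning the
# sequence and its truth PAF row.
contigFromGenome <- function(genome, a, b, strand, qname,
                             tname = "c1") {
    s <- substr(genome, a + 1L, b)
    if (strand == "-") {
        s <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
    }
    list(seq = s,
         paf = pafRow(qname = qname, qlen = b - a, qstart = 0L,
                      qend = b - a, strand = strand, tname = tname,
                      tlen = nchar(genome), tstart = a, tend = b,
                      cg = paste0(b - a, "M")))
}
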