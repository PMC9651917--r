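test_that("consensus gap-fills uncovered interior from the genome", {
    fx <- makeTinyGenome()
    cds <- fx$cds[1, ]                           # [100, 400), '+'
    # two fragments leaving CDS positions 120..179 (relative 20..79) bare
    f1 <- contigFromGenome(fx$genome, 100L, 120L, "+", "f1")
    f2 <- contigFromGenome(fx$genome, 180L, 400L, "+", "f2")
    paf <- pafBind(f1$paf, f2$paf)
    cov <- computeCdsCoverage(paf, cds)
    out <- buildConsensus(cds, fx$genome, cov$segments, paf,
                          c(f1 = f1$seq, f2 = f2$seq))
    expect_equal(out$seq, fx$trueCds[["g1"]])
    expect_equal(out$provenance,
                 paste0(strrep("T", 20), strrep("G", 60), strrep("T", 220)))
    expect_equal(out$id, "g1|corrected")
    expect_equal(out$status, "aligned")
})

test_that("transcript variants override the genome base", {
    fx <- makeTinyGenome()
    cds <- fx$cds[1, ]
    full <- contigFromGenome(fx$genome, 100L, 300L, "+", "v1")
    mut <- full$seq
    orig <- substr(mut, 51, 51)
    sub <- setdiff(c("A", "C", "G", "T"), orig)[1]
    substr(mut, 51, 51) <- sub
    paf <- full$paf
    paf$matches <- paf$matches - 1L
    cov <- computeCdsCoverage(paf, cds)
    out <- buildConsensus(cds, fx$genome, cov$segments, paf, c(v1 = mut))
    # the substitution sits at CDS position 51 (1-based), inside the covered
    # span, so the RNA base wins; the uncovered tail is genome-filled
    expect_equal(substr(out$seq, 51, 51), sub)
    expect_equal(substr(out$provenance, 51, 51), "T")
    expect_equal(substr(out$seq, 201, 300),
                 substr(fx$trueCds[["g1"]], 201, 300))
    expect_equal(substr(out$provenance, 201, 300), strrep("G", 100))
})

test_that("per-position winner is by matches, mapq, then qname", {
    fx <- makeTinyGenome()
    cds <- fx$cds[1, ]
    mkMut <- function(base) {
        s <- contigFromGenome(fx$genome, 100L, 400L, "+", "x")$seq
        substr(s, 10, 10) <- base
        s
    }
    orig <- substr(fx$trueCds[["g1"]], 10, 10)
    alts <- setdiff(c("A", "C", "G", "T"), orig)
    tA <- mkMut(alts[1])
    tB <- mkMut(alts[2])
    base <- contigFromGenome(fx$genome, 100L, 400L, "+", "x")$paf

    run <- function(paf, seqs) {
        cov <- computeCdsCoverage(paf, cds)
        buildConsensus(cds, fx$genome, cov$segments, paf, seqs)
    }
    p1 <- base; p1$qname <- "a"; p1$matches <- 290L
    p2 <- base; p2$qname <- "b"; p2$matches <- 280L
    out <- run(pafBind(p1, p2), c(a = tA, b = tB))
    expect_equal(substr(out$seq, 10, 10), alts[1])
    # full tie on matches and mapq: lexicographically smaller qname wins,
    # independent of input order
    p2$matches <- 290L
    outAB <- run(pafBind(p1, p2), c(a = tA, b = tB))
    outBA <- run(pafBind(p2, p1), c(a = tA, b = tB))
    expect_equal(substr(outAB$seq, 10, 10), alts[1])
    expect_equal(outAB$seq, outBA$seq)
})

test_that("minus-strand CDS is emitted in coding sense", {
    fx <- makeTinyGenome()
    cds <- fx$cds[2, ]                           # [500, 680), '-'
    ctg <- contigFromGenome(fx$genome, 500L, 680L, "-", "m1")
    cov <- computeCdsCoverage(ctg$paf, cds)
    out <- buildConsensus(cds, fx$genome, cov$segments, ctg$paf,
                          c(m1 = ctg$seq))
    expect_equal(out$seq, fx$trueCds[["g2"]])
    expect_true(startsWith(out$seq, "ATG"))
    # and equals the reverse complement of the forward-strand consensus
    cdsPlus <- cds
    cdsPlus$strand <- "+"
    outPlus <- buildConsensus(cdsPlus, fx$genome, cov$segments, ctg$paf,
                              c(m1 = ctg$seq))
    expect_equal(out$seq,
                 as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(outPlus$seq))))
    expect_equal(out$provenance, paste(rev(strsplit(outPlus$provenance,
                                                    "")[[1]]),
                                       collapse = ""))
})

test_that("operon-spanning contigs are split into one output per CDS", {
    fx <- makeTinyGenome(seed = 4)
    # make both CDS plus-strand and adjacent via one spanning contig
    fx$cds$strand[2] <- "+"
    g <- strsplit(fx$genome, "")[[1]]
    cds2 <- strsplit(fx$trueCds[["g2"]], "")[[1]]
    g[501:680] <- cds2
    genome <- paste(g, collapse = "")
    genomes <- setNames(Biostrings::DNAStringSet(genome), "c1")
    op <- contigFromGenome(genome, 100L, 680L, "+", "operon1")
    contigs <- setNames(Biostrings::DNAStringSet(op$seq), "operon1")
    res <- correctAssembly(contigs, genomes, fx$cds, op$paf)
    expect_length(correctedTranscripts(res), 2)
    expect_equal(as.character(correctedTranscripts(res)[["g1|corrected"]]),
                 substr(genome, 101, 400))
    expect_equal(as.character(correctedTranscripts(res)[["g2|corrected"]]),
                 substr(genome, 501, 680))
    expect_equal(correctionTable(res)$source_contigs, rep("operon1", 2))
})

test_that("intergenic extensions contribute no flank bases", {
    fx <- makeTinyGenome(seed = 5)
    cds <- fx$cds[1, ]
    ext <- contigFromGenome(fx$genome, 50L, 450L, "+", "ext1")
    contigs <- setNames(Biostrings::DNAStringSet(ext$seq), "ext1")
    res <- correctAssembly(contigs, fx$genomes, fx$cds, ext$paf)
    out <- correctedTranscripts(res)[["g1|corrected"]]
    expect_equal(nchar(as.character(out)), cds$end - cds$start)
    expect_equal(as.character(out), fx$trueCds[["g1"]])
    expect_equal(provenance(res)[1], strrep("T", 300))
})

test_that("transcript insertions are dropped and counted", {
    fx <- makeTinyGenome(seed = 6)
    cds <- fx$cds[1, ]
    base <- contigFromGenome(fx$genome, 100L, 400L, "+", "ins1")
    withIns <- paste0(substr(base$seq, 1, 150), "GGGGG",
                      substr(base$seq, 151, 300))
    paf <- pafRow(qname = "ins1", qlen = 305L, qstart = 0L, qend = 305L,
                  strand = "+", tname = "c1", tlen = nchar(fx$genome),
                  tstart = 100L, tend = 400L, matches = 300L,
                  block_len = 305L, cg = "150M5I150M")
    contigs <- setNames(Biostrings::DNAStringSet(withIns), "ins1")
    res <- correctAssembly(contigs, fx$genomes, fx$cds, paf)
    out <- correctedTranscripts(res)[["g1|corrected"]]
    expect_equal(nchar(as.character(out)), 300L)
    expect_equal(as.character(out), fx$trueCds[["g1"]])
    expect_equal(res@droppedInsertions, 1L)
})

test_that("correction reports skipped CDS and validates input ids", {
    fx <- makeTinyGenome(seed = 7)
    half <- contigFromGenome(fx$genome, 100L, 240L, "+", "h1")
    contigs <- setNames(Biostrings::DNAStringSet(half$seq), "h1")
    res <- correctAssembly(contigs, fx$genomes, fx$cds, half$paf,
                           threshold = 0.5)
    # g1 covered 140/300 < 0.5 and g2 untouched: nothing selected
    expect_length(correctedTranscripts(res), 0)
    expect_equal(sort(skippedCds(res)$cds_ref), c("g1", "g2"))
    expect_equal(skippedCds(res)$fraction[match("g2",
                                                skippedCds(res)$cds_ref)],
                 0)
    # lowering the threshold only adds CDS
    res2 <- correctAssembly(contigs, fx$genomes, fx$cds, half$paf,
                            threshold = 0.4)
    expect_true(all(selectedCds(res)$cds_ref %in%
                    selectedCds(res2)$cds_ref))

    badPaf <- half$paf
    badPaf$qname <- "ghost"
    expect_error(correctAssembly(contigs, fx$genomes, fx$cds, badPaf),
                 "ghost")
    badPaf <- half$paf
    badPaf$tname <- "nope"
    badPaf$tlen <- 1200L
    expect_error(correctAssembly(contigs, fx$genomes, fx$cds, badPaf),
                 "nope")
})

test_that("overlapping fragments reconstruct the exact CDS", {
    fx <- makeTinyGenome(seed = 8)
    f1 <- contigFromGenome(fx$genome, 100L, 260L, "+", "f1")
    f2 <- contigFromGenome(fx$genome, 250L, 400L, "+", "f2")
    contigs <- Biostrings::DNAStringSet(c(f1 = f1$seq, f2 = f2$seq))
    res <- correctAssembly(contigs, fx$genomes, fx$cds,
                           pafBind(f1$paf, f2$paf))
    out <- correctedTranscripts(res)[["g1|corrected"]]
    expect_equal(as.character(out), fx$trueCds[["g1"]])
    expect_equal(provenance(res)[1], strrep("T", 300))
    expect_equal(correctionTable(res)$source_contigs[1], "f1,f2")
})
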