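test_that("community generation is deterministic and well formed", {
    a <- generateCommunity(nGenomes = 3, genomeLen = 20000, nCds = 8,
                           seed = 17)
    b <- generateCommunity(nGenomes = 3, genomeLen = 20000, nCds = 8,
                           seed = 17)
    expect_identical(as.character(a$genomes), as.character(b$genomes))
    expect_identical(a$cds, b$cds)

    for (g in names(a$genomes)) {
        rows <- a$cds[a$cds$contig_id == g, ]
        expect_equal(nrow(rows), 8)
        rows <- rows[order(rows$start), ]
        expect_true(all(rows$start[-1] >= rows$end[-nrow(rows)]))
        expect_true(all(rows$end <= Biostrings::width(a$genomes[g])))
    }
    expect_false(anyDuplicated(a$cds$feature_id) > 0)
})

test_that("generated CDS are proper frames with no internal stops", {
    comm <- generateCommunity(nGenomes = 2, genomeLen = 30000, nCds = 12,
                              seed = 19)
    truth <- methods::new("SyntheticTruth", genomes = comm$genomes,
                          cds = comm$cds,
                          abundance = setNames(c(0.5, 0.5),
                                               names(comm$genomes)),
                          expression = numeric(0),
                          effectiveTpm = numeric(0),
                          contigs = Biostrings::DNAStringSet(),
                          artifactLabels = character(0),
                          truthPaf = emptyPaf(), seed = 19L)
    cdsSeqs <- trueCdsSequences(truth)
    for (i in seq_along(cdsSeqs)) {
        s <- as.character(cdsSeqs[[i]])
        expect_equal(nchar(s) %% 3, 0)
        expect_equal(substr(s, 1, 3), "ATG")
        aa <- as.character(Biostrings::translate(
            Biostrings::DNAString(s), genetic.code =
                Biostrings::getGeneticCode("11")))
        # exactly one stop, at the end (translate-and-scan oracle)
        expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
        expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    }
})

test_that("infeasible CDS packing is rejected", {
    expect_error(generateCommunity(nGenomes = 1, genomeLen = 3000,
                                   nCds = 10, cdsLenRange = c(600, 600),
                                   seed = 1),
                 "pack")
})

test_that("abundances normalise and spread with sigma", {
    one <- assignAbundances("g1", seed = 21)
    expect_equal(unname(one), 1.0)

    ab <- assignAbundances(sprintf("g%02d", 1:32), sigma = 1.5, seed = 21)
    expect_equal(sum(ab), 1)
    expect_true(all(ab > 0))

    cv <- function(sigma) {
        vals <- vapply(1:30, function(s) {
            x <- assignAbundances(sprintf("g%02d", 1:32), sigma = sigma,
                                  seed = s)
            stats::sd(x) / mean(x)
        }, numeric(1))
        mean(vals)
    }
    expect_gt(cv(1.5), cv(0.3))
    expect_error(assignAbundances("g1", sigma = 0), "positive")
})

test_that("effective TPM is expression times abundance, normalised", {
    cds <- data.frame(contig_id = c("gA", "gA", "gB"),
                      start = 0, end = 300, strand = "+",
                      feature_id = c("x1", "x2", "y1"),
                      product = NA, stringsAsFactors = FALSE)
    ab <- c(gA = 0.75, gB = 0.25)
    ex <- assignExpression(cds, ab, zeroFraction = 0, seed = 23)
    expect_equal(sum(ex$effectiveTpm), 1e6)
    w <- ex$expression * ab[cds$contig_id]
    expect_equal(unname(ex$effectiveTpm), unname(1e6 * w / sum(w)))

    silent <- assignExpression(cds, ab, zeroFraction = 1, seed = 23)
    expect_true(all(silent$effectiveTpm == 0))
})

test_that("truth alignments replay the contig sequences exactly", {
    truth <- suppressWarnings(
        generateSyntheticTruth(nGenomes = 3, genomeLen = 20000,
                               nCds = 8, seed = 25,
                               mix = c(fragmented = 0.3, partial = 0.2,
                                       fragmented_partial = 0.2,
                                       intergenic_extended = 0.1,
                                       operon_span = 0.1,
                                       chimeric = 0.1)))
    paf <- truthPaf(truth)
    genomesChr <- as.character(genomes(truth))
    contigsChr <- as.character(artifactContigs(truth))
    expect_gt(nrow(paf), 0)
    for (i in seq_len(nrow(paf))) {
        tSub <- substr(genomesChr[[paf$tname[i]]], paf$tstart[i] + 1L,
                       paf$tend[i])
        qSub <- substr(contigsChr[[paf$qname[i]]], paf$qstart[i] + 1L,
                       paf$qend[i])
        if (paf$strand[i] == "-") {
            tSub <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(tSub)))
        }
        expect_equal(qSub, tSub)
    }
    validatePaf(paf)
})

test_that("artifact classes honour their coverage contracts", {
    clean <- generateSyntheticTruth(nGenomes = 2, genomeLen = 15000,
                                    nCds = 6, seed = 27,
                                    mix = c(clean = 1), zeroFraction = 0)
    trueTx <- as.character(trueCdsSequences(clean))
    for (qn in names(artifactContigs(clean))) {
        fid <- sub("^tx_(.*)_clean$", "\\1", qn)
        expect_equal(as.character(artifactContigs(clean)[[qn]]),
                     trueTx[[fid]])
    }

    part <- generateSyntheticTruth(nGenomes = 2, genomeLen = 15000,
                                   nCds = 6, seed = 27,
                                   mix = c(partial = 1), zeroFraction = 0)
    covs <- computeAllCoverages(truthPaf(part), cdsTable(part))
    fr <- vapply(covs, `[[`, numeric(1), "fraction")
    expect_true(all(fr >= 0.49 & fr <= 0.96))

    chim <- generateSyntheticTruth(nGenomes = 2, genomeLen = 15000,
                                   nCds = 6, seed = 27,
                                   mix = c(chimeric = 1), zeroFraction = 0)
    calls <- detectMisassemblies(truthPaf(chim))
    expect_setequal(unique(calls$contig_id),
                    names(artifactLabels(chim)))
})

test_that("operon spans fall back cleanly when no neighbour exists", {
    expect_warning(
        truth <- generateSyntheticTruth(nGenomes = 1, genomeLen = 5000,
                                        nCds = 1, seed = 29,
                                        mix = c(operon_span = 1),
                                        zeroFraction = 0),
        "falling back")
    expect_equal(unname(artifactLabels(truth)), "clean")
})

test_that("whole-truth generation is reproducible byte for byte", {
    a <- generateSyntheticTruth(nGenomes = 2, genomeLen = 15000, nCds = 5,
                                seed = 31)
    b <- generateSyntheticTruth(nGenomes = 2, genomeLen = 15000, nCds = 5,
                                seed = 31)
    expect_identical(as.character(genomes(a)), as.character(genomes(b)))
    expect_identical(as.character(artifactContigs(a)),
                     as.character(artifactContigs(b)))
    expect_identical(effectiveTpm(a), effectiveTpm(b))
    expect_identical(truthPaf(a)[, 1:14], truthPaf(b)[, 1:14])
})
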