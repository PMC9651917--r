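test_that("alignment filtering applies block, secondary and identity rules", {
    expect_equal(nrow(filterAlignments(emptyPaf())), 0)
    short <- pafRow(qlen = 50, qend = 50, tend = 50)
    expect_equal(nrow(filterAlignments(short, minBlock = 100)), 0)

    mixed <- pafBind(pafRow(qname = "p1", tp = "P"),
                     pafRow(qname = "s1", tp = "S"),
                     pafRow(qname = "n1"),
                     pafRow(qname = "s2", tp = "S"))
    kept <- filterAlignments(mixed)
    expect_equal(kept$qname, c("p1", "n1"))
    expect_equal(nrow(filterAlignments(mixed, primaryOnly = FALSE)), 4)

    lowId <- pafRow(matches = 50, block_len = 100, qend = 100, tend = 100)
    expect_equal(nrow(filterAlignments(lowId, minIdentity = 0.9)), 0)
    expect_equal(nrow(filterAlignments(lowId, minIdentity = 0.5)), 1)
})

test_that("projection intersects alignment and CDS intervals", {
    cds <- list(contig_id = "c1", start = 0L, end = 40L, strand = "+",
                feature_id = "g1")
    aln <- pafRow(tstart = 50, tend = 150)
    expect_null(projectToCds(aln, cds))

    cds2 <- list(contig_id = "c1", start = 100L, end = 200L, strand = "+",
                 feature_id = "g2")
    seg <- projectToCds(aln, cds2)
    expect_equal(seg$t_lo, 100)
    expect_equal(seg$t_hi, 150)
    # last 50 query bases of the gapless block, plus strand
    expect_equal(seg$q_lo, 50)
    expect_equal(seg$q_hi, 100)

    alnMinus <- pafRow(strand = "-", tstart = 50, tend = 150)
    segM <- projectToCds(alnMinus, cds2)
    # minus strand: the target tail maps to the query head
    expect_equal(segM$q_lo, 0)
    expect_equal(segM$q_hi, 50)

    expect_error(projectToCds(aln, list(contig_id = "cX", start = 0,
                                        end = 10, feature_id = "g")),
                 "does not match")
})

test_that("CIGAR projection agrees with an explicit per-base walk", {
    aln <- pafRow(qlen = 100, qstart = 0, qend = 100, tstart = 100,
                  tend = 210, block_len = 110, matches = 100,
                  cg = "50M10D50M")
    # independent expansion of the CIGAR into (target, query) pairs
    pairs <- cbind(t = c(100:149, 160:209), q = c(0:49, 50:99))
    for (cdsIv in list(c(130, 190), c(100, 155), c(150, 160),
                       c(145, 165))) {
        cds <- list(contig_id = "c1", start = cdsIv[1], end = cdsIv[2],
                    strand = "+", feature_id = "g")
        seg <- projectToCds(aln, cds)
        inSpan <- pairs[pairs[, "t"] >= cdsIv[1] &
                        pairs[, "t"] < cdsIv[2], , drop = FALSE]
        if (nrow(inSpan)) {
            expect_equal(seg$q_lo, min(inSpan[, "q"]))
            expect_equal(seg$q_hi, max(inSpan[, "q"]) + 1L)
        } else {
            # interval fully inside the deletion: zero-length query span
            expect_equal(seg$q_lo, seg$q_hi)
        }
        expect_equal(seg$t_lo, max(100, cdsIv[1]))
        expect_equal(seg$t_hi, min(210, cdsIv[2]))
    }
})

test_that("projection is monotone under CDS enlargement", {
    set.seed(21)
    for (i in 1:20) {
        ts <- sample(0:400, 1)
        te <- ts + sample(50:300, 1)
        aln <- pafRow(qlen = te - ts, qend = te - ts, tstart = ts,
                      tend = te, tlen = 1000)
        a <- sort(sample(0:999, 2))
        cdsSmall <- list(contig_id = "c1", start = a[1], end = a[2],
                         strand = "+", feature_id = "g")
        cdsBig <- list(contig_id = "c1", start = max(0, a[1] - 50),
                       end = min(1000, a[2] + 50), strand = "+",
                       feature_id = "g")
        sSmall <- projectToCds(aln, cdsSmall)
        sBig <- projectToCds(aln, cdsBig)
        if (!is.null(sSmall)) {
            expect_true(!is.null(sBig))
            expect_lte(sBig$t_lo, sSmall$t_lo)
            expect_gte(sBig$t_hi, sSmall$t_hi)
        }
    }
})

test_that("union coverage matches the per-base boolean oracle", {
    cds <- list(contig_id = "c1", start = 100L, end = 200L, strand = "+",
                feature_id = "g1")
    expect_equal(computeCdsCoverage(emptyPaf(), cds)$fraction, 0)

    # disjoint segments [0,30) and [50,90) of a length-100 CDS
    paf <- pafBind(pafRow(qname = "a", qlen = 30, qend = 30, tstart = 100,
                          tend = 130),
                   pafRow(qname = "b", qlen = 40, qend = 40, tstart = 150,
                          tend = 190))
    cov <- computeCdsCoverage(paf, cds)
    expect_equal(cov$covered_bases, 70)
    expect_equal(cov$fraction, 0.7)

    set.seed(7)
    for (i in 1:30) {
        n <- sample(1:50, 1)
        ts <- sample(0:1990, n, replace = TRUE)
        te <- pmin(2000L, ts + sample(20:400, n, replace = TRUE))
        paf <- do.call(rbind, lapply(seq_len(n), function(k)
            pafRow(qname = sprintf("t%02d", k), qlen = te[k] - ts[k],
                   qend = te[k] - ts[k], tlen = 2000L, tstart = ts[k],
                   tend = te[k])))
        cds <- list(contig_id = "c1", start = 500L, end = 1500L,
                    strand = "+", feature_id = "g")
        cov <- computeCdsCoverage(paf, cds)
        expect_equal(cov$covered_bases,
                     bruteCoverage(500L, 1500L, ts, te))
    }
})

test_that("coverage fraction is invariant under segment order", {
    set.seed(9)
    ts <- sample(0:900, 10)
    te <- ts + 80L
    mk <- function(ord) do.call(rbind, lapply(ord, function(k)
        pafRow(qname = sprintf("t%d", k), qlen = 80, qend = 80,
               tstart = ts[k], tend = te[k])))
    cds <- list(contig_id = "c1", start = 0L, end = 1000L, strand = "+",
                feature_id = "g")
    f1 <- computeCdsCoverage(mk(1:10), cds)$fraction
    f2 <- computeCdsCoverage(mk(sample(10)), cds)$fraction
    expect_equal(f1, f2)
})

test_that("coverage selection keeps the inclusive boundary", {
    mkCov <- function(id, fr) list(cds_ref = id, covered_bases = 0L,
                                   fraction = fr, segments = NULL)
    covs <- list(a = mkCov("a", 0.49), b = mkCov("b", 0.50),
                 c = mkCov("c", 0.51))
    sel <- selectCoveredCds(covs, 0.5)
    expect_equal(names(sel), c("b", "c"))
    expect_equal(names(selectCoveredCds(covs, 0)), c("a", "b", "c"))
    expect_error(selectCoveredCds(covs, 1.01), "threshold")
    expect_error(selectCoveredCds(covs, -0.1), "threshold")

    set.seed(5)
    frs <- runif(100)
    covs <- lapply(seq_along(frs), function(i) mkCov(paste0("x", i),
                                                     frs[i]))
    names(covs) <- paste0("x", seq_along(frs))
    thr <- 0.37
    expect_equal(names(selectCoveredCds(covs, thr)),
                 names(covs)[frs >= thr])
})

test_that("transcript partition is a true partition", {
    ids <- sprintf("t%02d", 1:20)
    p <- partitionTranscripts(emptyPaf(), ids)
    expect_equal(p$unaligned, ids)
    expect_length(p$aligned, 0)

    paf <- do.call(rbind, lapply(ids, function(q) pafRow(qname = q)))
    p <- partitionTranscripts(paf, ids)
    expect_length(p$unaligned, 0)

    set.seed(13)
    some <- sample(ids, 8)
    paf <- do.call(rbind, lapply(some, function(q) pafRow(qname = q)))
    p <- partitionTranscripts(paf, ids)
    expect_setequal(c(p$aligned, p$unaligned), ids)
    expect_length(intersect(p$aligned, p$unaligned), 0)
    expect_setequal(p$aligned, some)
})
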