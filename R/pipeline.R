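#' Write a CDS annotation table as GFF3
#'
#' Inverse of [readGffCds()]: internal 0-based half-open coordinates are
#' converted back to GFF's 1-based inclusive convention at this boundary.
#'
#' @param cds CDS table ([readGffCds()] layout).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGffCds <- function(cds, path) {
    attr <- sprintf("ID=%s", cds$feature_id)
    hasProd <- !is.na(cds$product) & nzchar(cds$product)
    attr[hasProd] <- paste0(attr[hasProd], ";product=",
                            cds$product[hasProd])
    lines <- sprintf("%s\t.\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                     cds$contig_id, cds$start + 1L, cds$end, cds$strand,
                     attr)
    writeLines(c("##gff-version 3", lines), path)
    invisible(path)
}

.checkInputs <- function(paths) {
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing)) {
        argStop("input file(s) not found: ",
                paste(missing, collapse = ", "))
    }
}

.writeRunSummary <- function(outputDir, summary) {
    jsonlite::write_json(summary, file.path(outputDir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full correction pipeline on files
#'
#' Reads transcript contigs, genomic contigs, CDS annotation and
#' transcript-to-genome alignments, runs [correctAssembly()], optionally
#' rescues unaligned transcripts through the orphan path ([selectCoding()]
#' then [clusterDedup()]), and writes the combined transcript FASTA, a
#' companion TSV and a machine-readable run summary into `outputDir`.
#'
#' @param transcriptsFasta,genomesFasta,gffPath,pafPath input file paths.
#' @param outputDir output directory (created if needed).
#' @param threshold CDS coverage selection threshold (default 0.5).
#' @param minBlock minimum alignment block length (default 100).
#' @param orphanEnabled run the orphan path? Default TRUE.
#' @param minAa minimum orphan ORF length in amino acids (default 100).
#' @param minIdentity,minCov [clusterDedup()] parameters.
#' @return Invisibly, a list with the [CorrectionResult-class] and the final
#'   combined [Biostrings::DNAStringSet].
#' @export
runCorrect <- function(transcriptsFasta, genomesFasta, gffPath, pafPath,
                       outputDir, threshold = 0.5, minBlock = 100L,
                       orphanEnabled = TRUE, minAa = 100L,
                       minIdentity = 0.95, minCov = 0.9) {
    .checkInputs(c(transcriptsFasta, genomesFasta, gffPath, pafPath))
    if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
        argStop("threshold must lie in [0, 1]")
    }
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    transcripts <- readFasta(transcriptsFasta)
    genomes <- readFasta(genomesFasta)
    cds <- readGffCds(gffPath)
    paf <- readPaf(pafPath)
    result <- correctAssembly(transcripts, genomes, cds, paf,
                              threshold = threshold, minBlock = minBlock)
    combined <- correctedTranscripts(result)
    S4Vectors::mcols(combined) <- S4Vectors::DataFrame(
        status = rep("aligned", length(combined)))
    nOrphans <- 0L
    if (orphanEnabled && length(unalignedIds(result))) {
        candidates <- selectCoding(transcripts[unalignedIds(result)],
                                   minAa = minAa)
        combined <- clusterDedup(correctedTranscripts(result), candidates,
                                 minIdentity = minIdentity, minCov = minCov)
        nOrphans <- sum(S4Vectors::mcols(combined)$status == "unaligned")
    }
    hdr <- combined
    tab <- correctionTable(result)
    at <- match(names(combined), tab$id)
    fracT <- vapply(strsplit(provenance(result), ""),
                    function(p) mean(p == "T"), numeric(1))
    S4Vectors::mcols(hdr)$description <- ifelse(
        is.na(at),
        sprintf("status=%s", S4Vectors::mcols(combined)$status),
        sprintf("cds=%s status=aligned provenance_T=%.4f",
                tab$cds_ref[at], fracT[at]))
    writeFasta(hdr, file.path(outputDir, "transcripts.fasta"))
    writeCorrected(result, tsvPath = file.path(outputDir,
                                               "corrected_transcripts.tsv"))
    .writeRunSummary(outputDir, list(
        command = "correct", threshold = threshold, minBlock = minBlock,
        orphan_enabled = orphanEnabled,
        n_input_transcripts = length(transcripts),
        n_cds = nrow(cds),
        n_selected_cds = nrow(selectedCds(result)),
        n_skipped_cds = nrow(skippedCds(result)),
        n_corrected = length(correctedTranscripts(result)),
        n_unaligned_input = length(unalignedIds(result)),
        n_orphans_kept = nOrphans,
        dropped_insertions = result@droppedInsertions))
    invisible(list(result = result, combined = combined))
}

#' Run reference-based evaluation on files
#'
#' @param assemblyFasta assembled transcript FASTA.
#' @param truthFasta reference transcript FASTA.
#' @param pafPath assembly-to-reference PAF.
#' @param outputDir output directory.
#' @param expressionTsv optional TSV with columns `feature_id`, `tpm`; when
#'   given, the truth set is filtered at `minTpm` before scoring.
#' @param genomePafPath optional assembly-to-genome PAF for misassembly
#'   detection.
#' @param minFraction,minTpm,gapBp see [evaluateAssembly()].
#' @return Invisibly, the [AssemblyEvaluation-class].
#' @export
runEvaluate <- function(assemblyFasta, truthFasta, pafPath, outputDir,
                        expressionTsv = NULL, genomePafPath = NULL,
                        minFraction = 0.95, minTpm = 1.0, gapBp = 1000L) {
    .checkInputs(c(assemblyFasta, truthFasta, pafPath, expressionTsv,
                   genomePafPath))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    assembly <- readFasta(assemblyFasta)
    truthRefs <- readFasta(truthFasta)
    paf <- readPaf(pafPath)
    expression <- if (!is.null(expressionTsv)) {
        utils::read.delim(expressionTsv, stringsAsFactors = FALSE)
    }
    genomePaf <- if (!is.null(genomePafPath)) readPaf(genomePafPath)
    ev <- evaluateAssembly(assembly, truthRefs, paf,
                           expression = expression, genomePaf = genomePaf,
                           minFraction = minFraction, minTpm = minTpm,
                           gapBp = gapBp)
    writeEvaluation(ev,
                    tsvPath = file.path(outputDir, "evaluation.tsv"),
                    jsonPath = file.path(outputDir, "evaluation.json"),
                    histPath = file.path(outputDir,
                                         "completeness_histogram.tsv"))
    invisible(ev)
}

#' Quantify transcripts from read alignments on files
#'
#' @param transcriptsFasta transcript FASTA.
#' @param readsPafPath PAF of reads aligned to the transcripts.
#' @param outputDir output directory; writes `abundance.tsv` with columns
#'   `transcript_id`, `length`, `count`, `tpm`.
#' @param mapqMin,multimap see [countFromAlignments()].
#' @return Invisibly, the abundance data.frame.
#' @export
runQuantify <- function(transcriptsFasta, readsPafPath, outputDir,
                        mapqMin = 0L, multimap = "fractional") {
    .checkInputs(c(transcriptsFasta, readsPafPath))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    transcripts <- readFasta(transcriptsFasta)
    paf <- readPaf(readsPafPath)
    counts <- countFromAlignments(paf, mapqMin = mapqMin,
                                  multimap = multimap,
                                  transcriptIds = names(transcripts))
    lens <- stats::setNames(Biostrings::width(transcripts),
                            names(transcripts))
    extra <- setdiff(names(counts), names(lens))
    if (length(extra)) {
        integrityStop("alignments reference unknown transcript id(s): ",
                      paste(extra, collapse = ", "))
    }
    ab <- tpmFromCounts(counts, lens)
    utils::write.table(ab, file.path(outputDir, "abundance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .writeRunSummary(outputDir, list(
        command = "quantify", mapq_min = mapqMin, multimap = multimap,
        n_transcripts = length(transcripts), n_alignments = nrow(paf),
        total_count = sum(ab$count), tpm_sum = sum(ab$tpm)))
    invisible(ab)
}

#' Simulate a synthetic community to files
#'
#' Writes everything the rest of the pipeline consumes: genome FASTA, CDS
#' GFF3, artifact contig FASTA, truth PAF, expression TSV (`feature_id`,
#' `tpm`), true transcript FASTA, simulated reads FASTA and their
#' read-to-transcript truth PAF. Byte-identical outputs for the same seed.
#'
#' @inheritParams generateSyntheticTruth
#' @param outputDir output directory.
#' @param nReads,readLen read simulation parameters ([simulateReads()]);
#'   `nReads = 0` skips read simulation.
#' @return Invisibly, the [SyntheticTruth-class].
#' @export
runSimulate <- function(outputDir, nGenomes = 5L, genomeLen = 50000L,
                        nCds = 20L, cdsLenRange = c(300L, 1500L),
                        abundanceSigma = 1.0, expressionSigma = 1.0,
                        zeroFraction = 0.1,
                        mix = c(fragmented = 0.25, partial = 0.25,
                                fragmented_partial = 0.25,
                                intergenic_extended = 0.25),
                        errorRate = 0, seed = 1L, nReads = 10000L,
                        readLen = 100L) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    truth <- generateSyntheticTruth(
        nGenomes = nGenomes, genomeLen = genomeLen, nCds = nCds,
        cdsLenRange = cdsLenRange, abundanceSigma = abundanceSigma,
        expressionSigma = expressionSigma, zeroFraction = zeroFraction,
        mix = mix, errorRate = errorRate, seed = seed)
    writeFasta(genomes(truth), file.path(outputDir, "genomes.fasta"))
    writeGffCds(cdsTable(truth), file.path(outputDir, "annotation.gff3"))
    writeFasta(artifactContigs(truth), file.path(outputDir,
                                                 "contigs.fasta"))
    writePaf(truthPaf(truth), file.path(outputDir, "truth.paf"))
    utils::write.table(
        data.frame(feature_id = names(effectiveTpm(truth)),
                   tpm = unname(effectiveTpm(truth))),
        file.path(outputDir, "expression.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    trueTx <- trueCdsSequences(truth)
    writeFasta(trueTx, file.path(outputDir, "true_transcripts.fasta"))
    if (nReads > 0L) {
        sim <- simulateReads(trueTx, effectiveTpm(truth), nReads = nReads,
                             readLen = readLen, seed = seed)
        writeFasta(sim$reads, file.path(outputDir, "reads.fasta"))
        readPafTable <- mapReadsExact(sim$reads, trueTx)
        writePaf(readPafTable, file.path(outputDir, "reads_vs_truth.paf"))
        utils::write.table(sim$truth,
                           file.path(outputDir, "read_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .writeRunSummary(outputDir, list(
        command = "simulate", seed = seed, n_genomes = nGenomes,
        genome_len = genomeLen, n_cds_per_genome = nCds,
        n_expressed = sum(effectiveTpm(truth) > 0),
        n_contigs = length(artifactContigs(truth)),
        error_rate = errorRate, n_reads = nReads))
    invisible(truth)
}
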