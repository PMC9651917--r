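#' @import methods
NULL

#' Result of correcting a metatranscriptome assembly
#'
#' Container for the output of [correctAssembly()]: one reconstructed
#' transcript per selected coding region, in coding-sense orientation, with
#' per-base provenance recording whether each base came from assembled RNA
#' evidence (`T`) or was filled from the genome (`G`).
#'
#' @slot transcripts [Biostrings::DNAStringSet] of corrected transcripts,
#'   named `<feature_id>|corrected`.
#' @slot provenance character vector of per-base label strings over `{T,G}`,
#'   parallel to `transcripts`.
#' @slot table data.frame with one row per corrected transcript: `id`,
#'   `cds_ref`, `contig`, `start`, `end`, `strand`, `fraction`, `status`,
#'   `source_contigs` (comma-separated supporting transcript ids).
#' @slot selectedCds data.frame of coverage summaries (`cds_ref`,
#'   `covered_bases`, `fraction`) for the coding regions that passed the
#'   coverage threshold.
#' @slot skippedCds same summary for coding regions below threshold
#'   (uncovered CDS appear here with fraction 0).
#' @slot unalignedIds character vector of transcript contigs with no
#'   surviving alignment to the metagenome.
#' @slot droppedInsertions integer count of transcript insertion events
#'   (relative to the genome) that were dropped to keep output length equal
#'   to CDS length.
#' @exportClass CorrectionResult
setClass("CorrectionResult",
    representation(transcripts = "DNAStringSet",
                   provenance = "character",
                   table = "data.frame",
                   selectedCds = "data.frame",
                   skippedCds = "data.frame",
                   unalignedIds = "character",
                   droppedInsertions = "integer"),
    validity = function(object) {
        msg <- character(0)
        n <- length(object@transcripts)
        if (length(object@provenance) != n) {
            msg <- c(msg, "provenance must parallel transcripts")
        } else if (n > 0 &&
                   !all(nchar(object@provenance) ==
                        Biostrings::width(object@transcripts))) {
            msg <- c(msg, "provenance length must equal sequence length")
        }
        if (n > 0 && any(grepl("[^TG]", object@provenance))) {
            msg <- c(msg, "provenance labels must be 'T' or 'G'")
        }
        if (nrow(object@table) != n) {
            msg <- c(msg, "table must have one row per transcript")
        }
        if (anyDuplicated(names(object@transcripts))) {
            msg <- c(msg, "corrected transcript ids must be unique")
        }
        if (length(msg)) msg else TRUE
    })

#' Ground truth for a simulated microbial community
#'
#' Holds everything the synthetic-data generator knows about a simulated
#' community: genome sequences, CDS annotation, per-genome relative
#' abundances, per-gene expression, effective TPM (expression times species
#' abundance, normalised to one million), artifact transcript contigs with
#' class labels, and base-accurate truth alignments of every contig to its
#' source genome.
#'
#' @slot genomes [Biostrings::DNAStringSet] of genome sequences.
#' @slot cds CDS table (0-based half-open, see [readGffCds()]).
#' @slot abundance named numeric, per-genome relative abundance, sums to 1.
#' @slot expression named numeric, per-gene relative expression level.
#' @slot effectiveTpm named numeric, per-gene TPM; sums to 1e6 over expressed
#'   genes (all zero when nothing is expressed).
#' @slot contigs [Biostrings::DNAStringSet] of artifact transcript contigs.
#' @slot artifactLabels named character, contig id to artifact class in
#'   `{fragmented, partial, fragmented_partial, intergenic_extended,
#'   operon_span, chimeric, clean}`.
#' @slot truthPaf PAF data.frame of exact contig-to-genome placements with
#'   `cg` CIGAR tags.
#' @slot seed integer seed the community was generated from.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(genomes = "DNAStringSet",
                   cds = "data.frame",
                   abundance = "numeric",
                   expression = "numeric",
                   effectiveTpm = "numeric",
                   contigs = "DNAStringSet",
                   artifactLabels = "character",
                   truthPaf = "data.frame",
                   seed = "integer"),
    validity = function(object) {
        msg <- character(0)
        glen <- stats::setNames(Biostrings::width(object@genomes),
                                names(object@genomes))
        cds <- object@cds
        if (nrow(cds)) {
            if (!all(cds$contig_id %in% names(object@genomes))) {
                msg <- c(msg, "CDS reference unknown genomes")
            } else if (any(cds$start < 0 | cds$end > glen[cds$contig_id])) {
                msg <- c(msg, "CDS outside genome bounds")
            }
        }
        if (length(object@abundance) &&
            abs(sum(object@abundance) - 1) > 1e-6) {
            msg <- c(msg, "abundances must sum to 1")
        }
        s <- sum(object@effectiveTpm)
        if (length(object@effectiveTpm) && s > 0 && abs(s - 1e6) > 1) {
            msg <- c(msg, "effective TPM must sum to 1e6")
        }
        if (length(msg)) msg else TRUE
    })

#' Reference-based evaluation of an assembly
#'
#' Report produced by [evaluateAssembly()]: sequence counts, single-alignment
#' capture statistics over the (optionally TPM-filtered) truth set, and
#' misassembly calls.
#'
#' @slot nSequences number of assembled sequences.
#' @slot nUnaligned number of assembled sequences with no alignment to the
#'   truth references.
#' @slot capturedPct percentage of truth references captured (best single
#'   alignment covering at least the capture threshold of the reference).
#' @slot captureTable data.frame with per-reference `ref_id`,
#'   `best_single_fraction`, `captured`.
#' @slot misassemblies data.frame of misassembly calls
#'   ([detectMisassemblies()]); zero rows when no genome alignments were
#'   provided.
#' @slot truthIds character vector of reference ids scored.
#' @exportClass AssemblyEvaluation
setClass("AssemblyEvaluation",
    representation(nSequences = "integer",
                   nUnaligned = "integer",
                   capturedPct = "numeric",
                   captureTable = "data.frame",
                   misassemblies = "data.frame",
                   truthIds = "character"),
    validity = function(object) {
        msg <- character(0)
        if (object@nUnaligned > object@nSequences) {
            msg <- c(msg, "unaligned count exceeds sequence count")
        }
        if (!is.na(object@capturedPct) &&
            (object@capturedPct < 0 || object@capturedPct > 100)) {
            msg <- c(msg, "capturedPct must lie in [0, 100]")
        }
        if (length(msg)) msg else TRUE
    })
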