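#' Read a FASTA file into a DNAStringSet
#'
#' Sequence ids are the first whitespace-delimited token of each header; the
#' remainder of the header is kept in `mcols(x)$description`. Sequences are
#' uppercased on read. Only the characters A, C, G, T and N are accepted:
#' downstream consensus logic is deterministic over this alphabet.
#'
#' @param path path to a FASTA text file.
#' @return A [Biostrings::DNAStringSet] with unique names and a
#'   `description` metadata column.
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) {
        argStop("FASTA file not found: ", path)
    }
    lines <- readLines(path, warn = FALSE)
    firstContent <- which(nzchar(trimws(lines)))[1]
    if (!is.na(firstContent) && !startsWith(lines[firstContent], ">")) {
        parseStop("malformed FASTA: sequence before first '>' at line ",
                  firstContent)
    }
    if (is.na(firstContent)) {
        x <- Biostrings::DNAStringSet()
        S4Vectors::mcols(x) <- S4Vectors::DataFrame(
            description = character(0))
        return(x)
    }
    x <- Biostrings::readDNAStringSet(path)
    headers <- names(x)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    if (anyDuplicated(ids)) {
        parseStop("duplicated FASTA ids: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    if (any(Biostrings::width(x) == 0L)) {
        parseStop("zero-length sequence for id: ",
                  paste(ids[Biostrings::width(x) == 0L], collapse = ", "))
    }
    chr <- toupper(as.character(x))
    bad <- grepl("[^ACGTN]", chr)
    if (any(bad)) {
        parseStop("non-ACGTN characters in sequence(s): ",
                  paste(ids[bad], collapse = ", "))
    }
    x <- Biostrings::DNAStringSet(chr)
    names(x) <- ids
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(description = desc)
    x
}

#' Write sequences to a FASTA file
#'
#' @param records a named [Biostrings::DNAStringSet]; an optional
#'   `description` metadata column is appended to each header.
#' @param path output path.
#' @param lineWidth sequence line width (default 60).
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(records, path, lineWidth = 60L) {
    stopifnot(methods::is(records, "DNAStringSet"))
    out <- records
    desc <- S4Vectors::mcols(records)$description
    if (!is.null(desc)) {
        hdr <- ifelse(nzchar(desc), paste(names(records), desc),
                      names(records))
        names(out) <- hdr
    }
    Biostrings::writeXStringSet(out, filepath = path, width = lineWidth)
    invisible(path)
}

#' Read CDS features from a GFF3 annotation
#'
#' Reads a GFF3 file in the dialect produced by prokaryotic annotation
#' pipelines such as Prokka: an optional `##FASTA` trailer carrying contig
#' sequences is tolerated (everything after it is ignored). Only rows of type
#' `CDS` are returned. GFF's 1-based inclusive coordinates are converted to
#' the package-wide 0-based half-open convention at this boundary; no other
#' code performs coordinate conversion.
#'
#' @param path path to a GFF3 file.
#' @return A data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `feature_id` and `product`. `feature_id` is the
#'   `ID` attribute, falling back to `locus_tag`, falling back to
#'   `contig:start-end`.
#' @export
readGffCds <- function(path) {
    if (!file.exists(path)) {
        argStop("GFF file not found: ", path)
    }
    lines <- readLines(path, warn = FALSE)
    fastaAt <- which(grepl("^##FASTA\\s*$", lines))[1]
    if (!is.na(fastaAt)) {
        lines <- lines[seq_len(fastaAt - 1L)]
    }
    body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    cdsRows <- body[vapply(strsplit(body, "\t", fixed = TRUE),
                           function(f) length(f) >= 8 && f[3] == "CDS",
                           logical(1))]
    for (row in cdsRows) {
        f <- strsplit(row, "\t", fixed = TRUE)[[1]]
        s <- suppressWarnings(as.integer(f[4]))
        e <- suppressWarnings(as.integer(f[5]))
        if (is.na(s) || is.na(e) || e < s) {
            parseStop("CDS row with end < start or non-integer coordinates: ",
                      f[1], ":", f[4], "-", f[5])
        }
        if (!f[7] %in% c("+", "-")) {
            parseStop("CDS row with unknown strand '", f[7], "' on ", f[1])
        }
    }
    if (length(cdsRows) == 0L) {
        return(data.frame(contig_id = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          feature_id = character(0), product = character(0),
                          stringsAsFactors = FALSE))
    }
    tmp <- tempfile(fileext = ".gff3")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c("##gff-version 3", cdsRows), tmp)
    gr <- rtracklayer::import(tmp, format = "gff3")
    m <- S4Vectors::mcols(gr)
    fid <- if ("ID" %in% colnames(m)) as.character(m$ID) else
        rep(NA_character_, length(gr))
    lt <- if ("locus_tag" %in% colnames(m)) as.character(m$locus_tag) else
        rep(NA_character_, length(gr))
    start0 <- BiocGenerics::start(gr) - 1L
    end0 <- BiocGenerics::end(gr)
    contig <- as.character(GenomicRanges::seqnames(gr))
    fid <- ifelse(!is.na(fid) & nzchar(fid), fid,
           ifelse(!is.na(lt) & nzchar(lt), lt,
                  paste0(contig, ":", start0, "-", end0)))
    if (anyDuplicated(fid)) {
        parseStop("duplicated CDS feature ids: ",
                  paste(unique(fid[duplicated(fid)]), collapse = ", "))
    }
    prod <- if ("product" %in% colnames(m)) as.character(m$product) else
        rep(NA_character_, length(gr))
    data.frame(contig_id = contig, start = start0, end = end0,
               strand = as.character(BiocGenerics::strand(gr)),
               feature_id = fid, product = prod, stringsAsFactors = FALSE)
}

# The 12 mandatory PAF columns, in file order.
.pafCols <- c("qname", "qlen", "qstart", "qend", "strand",
              "tname", "tlen", "tstart", "tend",
              "matches", "block_len", "mapq")
.pafInt <- c("qlen", "qstart", "qend", "tlen", "tstart", "tend",
             "matches", "block_len", "mapq")

#' Construct an empty PAF table
#' @return A zero-row PAF data.frame (see [readPaf()] for columns).
#' @export
emptyPaf <- function() {
    df <- data.frame(qname = character(0), qlen = integer(0),
                     qstart = integer(0), qend = integer(0),
                     strand = character(0), tname = character(0),
                     tlen = integer(0), tstart = integer(0),
                     tend = integer(0), matches = integer(0),
                     block_len = integer(0), mapq = integer(0),
                     tp = character(0), cg = character(0),
                     stringsAsFactors = FALSE)
    df$tags <- vector("list", 0L)
    df
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory columns of minimap2's Pairwise mApping Format plus
#' the `tp:A:` (primary/secondary) and `cg:Z:` (CIGAR) tags when present. All
#' coordinates are 0-based half-open as in the format itself. Remaining tags
#' are retained verbatim in the `tags` list-column.
#'
#' @param path path to a PAF text file.
#' @return A data.frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `matches`, `block_len`,
#'   `mapq`, `tp`, `cg` and a `tags` list-column.
#' @export
readPaf <- function(path) {
    if (!file.exists(path)) {
        argStop("PAF file not found: ", path)
    }
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
        return(emptyPaf())
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 12L)) {
        parseStop("PAF line ", which(nf < 12L)[1],
                  " has fewer than 12 columns")
    }
    core <- t(vapply(fields, function(f) f[1:12], character(12)))
    colnames(core) <- .pafCols
    df <- as.data.frame(core, stringsAsFactors = FALSE)
    for (col in .pafInt) {
        v <- suppressWarnings(as.integer(df[[col]]))
        if (anyNA(v)) {
            parseStop("non-integer ", col, " at PAF line ",
                      which(is.na(v))[1])
        }
        df[[col]] <- v
    }
    if (!all(df$strand %in% c("+", "-"))) {
        parseStop("invalid strand at PAF line ",
                  which(!df$strand %in% c("+", "-"))[1])
    }
    extra <- lapply(fields, function(f) if (length(f) > 12L) f[-(1:12)]
                    else character(0))
    getTag <- function(tags, prefix) {
        hit <- tags[startsWith(tags, prefix)]
        if (length(hit)) substring(hit[1], nchar(prefix) + 1L)
        else NA_character_
    }
    df$tp <- vapply(extra, getTag, character(1), prefix = "tp:A:")
    df$cg <- vapply(extra, getTag, character(1), prefix = "cg:Z:")
    df$tags <- lapply(extra, function(tags)
        tags[!startsWith(tags, "tp:A:") & !startsWith(tags, "cg:Z:")])
    validatePaf(df)
    df
}

#' Write a PAF table back to disk
#'
#' Inverse of [readPaf()]: `readPaf(writePaf(x, f))` reproduces every field.
#'
#' @param paf a PAF data.frame as returned by [readPaf()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePaf <- function(paf, path) {
    validatePaf(paf)
    lines <- vapply(seq_len(nrow(paf)), function(i) {
        core <- vapply(.pafCols, function(col) as.character(paf[[col]][i]),
                       character(1))
        tags <- character(0)
        if (!is.na(paf$tp[i])) tags <- c(tags, paste0("tp:A:", paf$tp[i]))
        if (!is.na(paf$cg[i])) tags <- c(tags, paste0("cg:Z:", paf$cg[i]))
        tags <- c(tags, paf$tags[[i]])
        paste(c(core, tags), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Validate the structural invariants of a PAF table
#'
#' Checks the coordinate invariants of the format (half-open intervals within
#' sequence bounds, `matches <= block_len`) and, when a CIGAR is present,
#' that its consumed query and target lengths equal the alignment spans.
#'
#' @param paf a PAF data.frame.
#' @return Invisibly, `paf`.
#' @export
validatePaf <- function(paf) {
    need <- c(.pafCols, "tp", "cg")
    miss <- setdiff(need, names(paf))
    if (length(miss)) {
        argStop("PAF table missing columns: ", paste(miss, collapse = ", "))
    }
    if (nrow(paf) == 0L) return(invisible(paf))
    with(paf, {
        if (any(qstart < 0 | qstart >= qend | qend > qlen)) {
            integrityStop("PAF query interval out of bounds")
        }
        if (any(tstart < 0 | tstart >= tend | tend > tlen)) {
            integrityStop("PAF target interval out of bounds")
        }
        if (any(matches > block_len)) {
            integrityStop("PAF matches exceed block length")
        }
    })
    hasCg <- which(!is.na(paf$cg))
    for (i in hasCg) {
        ops <- parseCigar(paf$cg[i])
        qc <- sum(ops$len[ops$op %in% c("M", "=", "X", "I")])
        tc <- sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
        if (qc != paf$qend[i] - paf$qstart[i] ||
            tc != paf$tend[i] - paf$tstart[i]) {
            integrityStop("CIGAR length inconsistent with alignment spans ",
                          "for query ", paf$qname[i])
        }
    }
    invisible(paf)
}

#' Parse a CIGAR string into operation/length pairs
#' @param cg CIGAR string, e.g. `"50M10D50M"`.
#' @return A list with integer vector `len` and character vector `op`.
#' @keywords internal
parseCigar <- function(cg) {
    m <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, list(m))[[1]]
    if (length(toks) == 0L || sum(nchar(toks)) != nchar(cg)) {
        parseStop("malformed CIGAR string: ", cg)
    }
    list(len = as.integer(sub("[A-Z=]$", "", toks)),
         op = sub("^[0-9]+", "", toks))
}
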