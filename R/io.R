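#' Read a reference transcript set from FASTA
#'
#' Reads transcript sequences, keeping the first whitespace-delimited
#' token of each header as the transcript id. Sequences are uppercased
#' and restricted to the A/C/G/T/N alphabet.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by transcript id, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 description", "acgt"), fa)
#' readTranscripts(fa)
#' @export
readTranscripts <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    if (length(x) == 0L)
        stop("no FASTA records in ", path)
    ids <- sub("\\s.*$", "", names(x))
    if (any(!nzchar(ids)))
        stop("empty transcript id in ", path)
    if (anyDuplicated(ids))
        stop("duplicate transcript id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(x) <- ids
    bad <- setdiff(Biostrings::uniqueLetters(x), c("A", "C", "G", "T", "N"))
    if (length(bad))
        stop("disallowed characters in sequences: ", paste(bad, collapse = ""))
    if (any(Biostrings::width(x) == 0L))
        stop("empty sequence in ", path)
    x
}

#' Write a transcript set to FASTA
#'
#' @param transcripts a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTranscripts <- function(transcripts, path) {
    Biostrings::writeXStringSet(transcripts, path)
    invisible(path)
}

#' Read sequencing reads from 4-line FASTQ (Phred+33)
#'
#' @param path path to an uncompressed FASTQ file.
#' @return a [Biostrings::QualityScaledDNAStringSet]; decoded integer
#'   qualities are available via [readQualities()].
#' @export
readReads <- function(path) {
    ## validate record shape up front: the parser pads short quality
    ## strings silently, so length mismatches must be caught here
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) %% 4L != 0L)
        stop("FASTQ line count not a multiple of 4 in ", path)
    seqLen <- nchar(lines[seq(2L, length(lines), by = 4L)])
    qualLen <- nchar(lines[seq(4L, length(lines), by = 4L)])
    if (any(seqLen != qualLen)) {
        id <- sub("^@", "", lines[4L * (which(seqLen != qualLen)[1L] - 1L) + 1L])
        stop("sequence/quality length mismatch for read: ", id)
    }
    x <- tryCatch(
        withCallingHandlers(
            Biostrings::readQualityScaledDNAStringSet(path,
                                                      quality.scoring = "phred"),
            warning = function(w) {
                if (grepl("metadata columns", conditionMessage(w)))
                    invokeRestart("muffleWarning")
            }),
        error = function(e) stop("failed to parse FASTQ ", path, ": ",
                                 conditionMessage(e), call. = FALSE))
    x
}

#' Decode per-base Phred qualities
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @return a list of integer vectors, one per read.
#' @export
readQualities <- function(reads) {
    lapply(as.character(Biostrings::quality(reads)), function(s)
        as.integer(charToRaw(s)) - 33L)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReads <- function(reads, path) {
    Biostrings::writeQualityScaledXStringSet(reads, path)
    invisible(path)
}

#' Read alignments from a text SAM file
#'
#' Parses SAM body lines into a data frame of alignment records. Only
#' flag bit 0x4 (unmapped) and CIGAR operations M, =, X, I, D, S are
#' interpreted downstream; records whose CIGAR contains N, H or P are
#' skipped with a warning and counted in the `skipped` attribute.
#'
#' @param path path to a SAM file (with or without header lines).
#' @return a data.frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `cigar`, `seq`, `qual` and logical `unmapped`; attribute `skipped`
#'   carries the number of records dropped for unsupported CIGARs.
#' @export
readSAM <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (length(lines) == 0L) {
        out <- data.frame(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          cigar = character(), seq = character(),
                          qual = character(), unmapped = logical(),
                          stringsAsFactors = FALSE)
        attr(out, "skipped") <- 0L
        return(out)
    }
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 11L))
        stop("SAM record with fewer than 11 fields at line ", which(nf < 11L)[1L])
    get <- function(i) vapply(f, `[[`, "", i)
    out <- data.frame(
        qname = get(1L),
        flag = as.integer(get(2L)),
        rname = get(3L),
        pos = as.integer(get(4L)),
        cigar = get(6L),
        seq = get(10L),
        qual = get(11L),
        stringsAsFactors = FALSE)
    out$unmapped <- bitwAnd(out$flag, 4L) > 0L
    bad <- !out$unmapped & grepl("[NHP]", out$cigar)
    if (any(bad)) {
        warning(sum(bad), " SAM record(s) with unsupported CIGAR ops skipped")
        out <- out[!bad, , drop = FALSE]
    }
    chk <- !out$unmapped & out$cigar != "*" & out$seq != "*"
    if (any(chk)) {
        qlen <- vapply(out$cigar[chk],
                       function(cg) .cigarQueryLen(.parseCigar(cg)), 0L)
        mism <- qlen != nchar(out$seq[chk])
        if (any(mism))
            stop("CIGAR/sequence length mismatch for read ",
                 out$qname[chk][which(mism)[1L]])
    }
    rownames(out) <- NULL
    attr(out, "skipped") <- sum(bad)
    out
}

#' Write alignments to a text SAM file
#'
#' @param alignments a data.frame as returned by [readSAM()].
#' @param reference a named [Biostrings::DNAStringSet] used for the
#'   `@SQ` header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSAM <- function(alignments, reference, path) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                     Biostrings::width(reference)))
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                    alignments$qname, alignments$flag, alignments$rname,
                    alignments$pos, alignments$cigar, alignments$seq,
                    alignments$qual)
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Write / read tab-separated result tables
#'
#' Plain TSV with a header line, stable column order and no quoting;
#' the standard interchange format for the pipeline's outputs.
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `writeTsv` returns `path` invisibly; `readTsv` returns a
#'   data.frame.
#' @export
writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write SNP sites as a minimal VCF sidecar
#'
#' Emits a fixed minimal VCFv4.2 header and one record per SNP site,
#' with per-variety allelic depths in an `AD`-style sample field.
#'
#' @param sites a SNP site table from [callSnps()].
#' @param varieties character vector of variety labels (sample columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSnpVcf <- function(sites, varieties, path) {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=triohet",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", varieties), collapse = "\t"))
    if (nrow(sites)) {
        ad <- vapply(seq_len(nrow(sites)), function(i) {
            paste(vapply(varieties, function(v)
                sprintf("%d,%d", sites[[paste0(v, "_refDepth")]][i],
                        sites[[paste0(v, "_altDepth")]][i]), ""),
                collapse = "\t")
        }, "")
        body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d\tAD\t%s",
                        sites$transcript_id, sites$pos, sites$ref, sites$alt,
                        sites$total_depth, ad)
        writeLines(c(hdr, body), path)
    } else {
        writeLines(hdr, path)
    }
    invisible(path)
}
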