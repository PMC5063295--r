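## Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

## reverse complement of plain character vectors (short motifs/primers)
.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Phred+33 decode/encode
.qualToInt <- function(q) {
    lapply(q, function(s) as.integer(charToRaw(s)) - 33L)
}

.intToQual <- function(q) {
    vapply(q, function(v) rawToChar(as.raw(v + 33L)), "")
}

## base characters -> codes 1..4 (A,C,G,T), NA otherwise (e.g. N)
.baseCodes <- function(s) {
    r <- as.integer(charToRaw(s))
    code <- rep(NA_integer_, 256L)
    code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
    code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
    code[r]
}

## parse a CIGAR string into (lengths, ops); no validation beyond syntax
.parseCigar <- function(cigar) {
    m <- gregexpr("\\d+|[A-Z=]", cigar)[[1]]
    tok <- regmatches(cigar, list(m))[[1]]
    if (length(tok) < 2L || length(tok) %% 2L != 0L)
        stop("malformed CIGAR: ", cigar)
    lens <- suppressWarnings(as.integer(tok[c(TRUE, FALSE)]))
    ops <- tok[c(FALSE, TRUE)]
    if (anyNA(lens) || any(ops %in% as.character(0:9)))
        stop("malformed CIGAR: ", cigar)
    list(lengths = lens, ops = ops)
}

.QUERY_OPS <- c("M", "=", "X", "I", "S")
.REF_OPS <- c("M", "=", "X", "D")

.cigarQueryLen <- function(parsed) {
    sum(parsed$lengths[parsed$ops %in% .QUERY_OPS])
}

## a simple counting logger: stage-level drop counts surfaced to manifests
.newCounter <- function() {
    env <- new.env(parent = emptyenv())
    env$counts <- integer()
    env
}

.count <- function(counter, what, n = 1L) {
    if (is.null(counter)) return(invisible(NULL))
    cur <- counter$counts[what]
    counter$counts[what] <- if (is.na(cur)) n else cur + n
    invisible(NULL)
}
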