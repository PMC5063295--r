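#' GC content of a primer sequence
#'
#' @param seq character vector of non-empty A/C/G/T strings.
#' @return numeric vector, percent G+C.
#' @export
gcContent <- function(seq) {
    if (any(!grepl("^[ACGT]+$", seq)))
        stop("gcContent: sequences must be non-empty A/C/G/T strings")
    100 * (nchar(gsub("[AT]", "", seq))) / nchar(seq)
}

#' Melting temperature (long-oligo approximation)
#'
#' `Tm = 81.5 + 0.41 * GC% - 675 / length`, the standard approximation
#' for oligos of 14 bases and longer; depends only on length and GC
#' content.
#'
#' @param seq character vector of A/C/G/T strings, each >= 14 bases.
#' @return numeric vector of melting temperatures in degrees C.
#' @export
meltingTemp <- function(seq) {
    if (any(nchar(seq) < 14L))
        stop("meltingTemp: approximation requires length >= 14")
    81.5 + 0.41 * gcContent(seq) - 675 / nchar(seq)
}

#' 3'-clamp rule check
#'
#' TRUE iff the maximal run of identical G's or identical C's ending at
#' the 3' terminal base has length at most 1 (at most a single
#' consecutive G or C at the 3' end); a non-G/C terminus passes
#' trivially.
#'
#' @param seq character vector of primer sequences (5'->3').
#' @return logical vector.
#' @export
passesClamp <- function(seq) {
    n <- nchar(seq)
    last <- substr(seq, n, n)
    prev <- substr(seq, n - 1L, n - 1L)
    !(last %in% c("G", "C") & prev == last)
}

#' Design an SSR-flanking primer pair
#'
#' Enumerates every candidate pair (forward primer fully upstream of
#' the SSR tract, reverse primer fully downstream) satisfying all hard
#' constraints -- primer length, product size bounds, GC bounds, and
#' the 3'-clamp rule on both primers -- and returns the pair minimizing
#'
#' `score = |Tm_f - target| + |Tm_r - target| + |Tm_f - Tm_r| +
#'          (|GC_f - gcOpt| + |GC_r - gcOpt|) / 10`
#'
#' Ties break deterministically toward the smaller forward start, then
#' the smaller product. The product strictly contains the SSR tract.
#'
#' @param sequence a single transcript sequence (character or
#'   [Biostrings::DNAString]).
#' @param ssrStart,ssrEnd 1-based inclusive span of the SSR tract.
#' @param constraints a [PrimerConstraints] object.
#' @return a one-row data.frame (forward, reverse, forward_start,
#'   reverse_end, product_size, gc_f, gc_r, tm_f, tm_r, score) or
#'   `NULL` when no pair satisfies the constraints.
#' @export
designPrimers <- function(sequence, ssrStart, ssrEnd,
                          constraints = PrimerConstraints()) {
    seq <- as.character(sequence)
    n <- nchar(seq)
    if (ssrStart < 1L || ssrEnd > n || ssrStart > ssrEnd)
        stop("SSR span outside the sequence")
    cn <- constraints
    x <- strsplit(seq, "", fixed = TRUE)[[1]]
    if (any(!x %in% c("A", "C", "G", "T"))) return(NULL)
    gcc <- c(0L, cumsum(x %in% c("G", "C")))
    fwd <- .candidateWindows(x, gcc, cn,
        startMin = max(1L, ssrEnd + 1L + cn@lenMin - cn@productMax),
        startMax = ssrStart - cn@lenMin,
        endMax = ssrStart - 1L, strand = "+")
    if (is.null(fwd)) return(NULL)
    rev <- .candidateWindows(x, gcc, cn,
        startMin = ssrEnd + 1L,
        startMax = min(n - cn@lenMin + 1L,
                       ssrStart - cn@lenMin + cn@productMax - 1L),
        endMax = min(n, ssrStart - cn@lenMin + cn@productMax - 1L),
        strand = "-")
    if (is.null(rev)) return(NULL)
    ## pair on the product-size constraint
    prod <- outer(fwd$start, rev$end, function(fs, re) re - fs + 1L)
    ok <- which(prod >= cn@productMin & prod <= cn@productMax, arr.ind = TRUE)
    if (nrow(ok) == 0L) return(NULL)
    fi <- ok[, 1L]; ri <- ok[, 2L]
    score <- abs(fwd$tm[fi] - cn@tmTarget) + abs(rev$tm[ri] - cn@tmTarget) +
        abs(fwd$tm[fi] - rev$tm[ri]) +
        (abs(fwd$gc[fi] - cn@gcOpt) + abs(rev$gc[ri] - cn@gcOpt)) / 10
    best <- order(score, fwd$start[fi], prod[ok], fwd$len[fi], rev$len[ri])[1L]
    f <- fi[best]; r <- ri[best]
    data.frame(
        forward = fwd$seq[f],
        reverse = rev$seq[r],
        forward_start = fwd$start[f],
        reverse_end = rev$end[r],
        product_size = rev$end[r] - fwd$start[f] + 1L,
        gc_f = fwd$gc[f], gc_r = rev$gc[r],
        tm_f = fwd$tm[f], tm_r = rev$tm[r],
        score = score[best],
        stringsAsFactors = FALSE)
}

## enumerate primer windows on one side of the SSR, pre-filtered by all
## single-primer hard constraints; strand "-" means the primer is the
## reverse complement of the template window (its 3' end is the window's
## leftmost template base)
.candidateWindows <- function(x, gcc, cn, startMin, startMax, endMax, strand) {
    startMin <- max(1L, startMin)
    if (startMax < startMin) return(NULL)
    cand <- expand.grid(start = startMin:startMax, len = cn@lenMin:cn@lenMax)
    cand$end <- cand$start + cand$len - 1L
    cand <- cand[cand$end <= endMax, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    gc <- 100 * (gcc[cand$end + 1L] - gcc[cand$start]) / cand$len
    keep <- gc >= cn@gcMin & gc <= cn@gcMax
    cand <- cand[keep, , drop = FALSE]; gc <- gc[keep]
    if (nrow(cand) == 0L) return(NULL)
    ## clamp: 3' terminus is the window end (+) or the window start (-);
    ## on the minus strand a template G/C run maps to a primer C/G run
    if (strand == "+") {
        t1 <- x[cand$end]
        t2 <- ifelse(cand$end > 1L, x[cand$end - 1L], "")
    } else {
        t1 <- x[cand$start]
        t2 <- ifelse(cand$start < length(x), x[cand$start + 1L], "")
    }
    keep <- !(t1 %in% c("G", "C") & t2 == t1)
    cand <- cand[keep, , drop = FALSE]; gc <- gc[keep]
    if (nrow(cand) == 0L) return(NULL)
    tm <- 81.5 + 0.41 * gc - 675 / cand$len
    tmpl <- substring(paste(x, collapse = ""), cand$start, cand$end)
    list(start = cand$start, end = cand$end, len = cand$len,
         seq = if (strand == "+") tmpl else .revcomp(tmpl),
         gc = gc, tm = tm)
}

#' Design primers for a set of SSR loci
#'
#' Runs [designPrimers()] over retained loci (in transcript order, then
#' locus order) and assigns sequential marker ids `MSSR1`, `MSSR2`, ...
#' to the loci for which a pair could be designed.
#'
#' @param transcripts a named [Biostrings::DNAStringSet].
#' @param loci retained SSR loci ([filterLoci()] output).
#' @param constraints a [PrimerConstraints] object.
#' @param prefix marker id prefix (default `"MSSR"`).
#' @return a data.frame with one row per designed marker: marker_id,
#'   transcript_id, motif, repeat_count, forward, reverse, product_size,
#'   gc_f, gc_r, tm_f, tm_r, score; attribute `nFailed` counts loci for
#'   which no pair satisfied the constraints.
#' @export
designMarkerPrimers <- function(transcripts, loci,
                                constraints = PrimerConstraints(),
                                prefix = "MSSR") {
    seqs <- as.character(transcripts)
    rows <- list()
    nFailed <- 0L
    for (i in seq_along(loci)) {
        tid <- as.character(GenomicRanges::seqnames(loci))[i]
        if (!tid %in% names(seqs))
            stop("locus references unknown transcript: ", tid)
        pp <- designPrimers(seqs[[tid]], GenomicRanges::start(loci)[i],
                            GenomicRanges::end(loci)[i], constraints)
        if (is.null(pp)) { nFailed <- nFailed + 1L; next }
        pp <- cbind(data.frame(marker_id = NA_character_,
                               transcript_id = tid,
                               motif = mcols(loci)$motif[i],
                               repeat_count = mcols(loci)$repeatCount[i],
                               stringsAsFactors = FALSE), pp)
        rows[[length(rows) + 1L]] <- pp
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(marker_id = character(), transcript_id = character(),
                   motif = character(), repeat_count = integer(),
                   forward = character(), reverse = character(),
                   forward_start = integer(), reverse_end = integer(),
                   product_size = integer(), gc_f = numeric(),
                   gc_r = numeric(), tm_f = numeric(), tm_r = numeric(),
                   score = numeric(), stringsAsFactors = FALSE)
    if (nrow(out))
        out$marker_id <- paste0(prefix, seq_len(nrow(out)))
    rownames(out) <- NULL
    attr(out, "nFailed") <- nFailed
    out
}
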