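#' Canonical representative of a microsatellite motif
#'
#' Motifs that describe the same repeat tract on either strand or in a
#' different phase are pooled into one class: the canonical motif is
#' the lexicographically smallest string among all cyclic rotations of
#' the motif and all cyclic rotations of its reverse complement. This
#' is the usual convention behind motif classes such as AG/CT, AC/GT
#' and AAG/CTT in SSR frequency tables.
#'
#' @param motif character vector of primitive motifs over A/C/G/T,
#'   lengths 1--6.
#' @return character vector of canonical motifs; idempotent.
#' @examples
#' canonicalMotif(c("CT", "GAT"))  # "AG", "ATC"
#' @export
canonicalMotif <- function(motif) {
    vapply(motif, function(m) {
        if (!grepl("^[ACGT]+$", m) || nchar(m) > 6L)
            stop("motif must be a non-empty A/C/G/T string of length <= 6: ", m)
        if (!.isPrimitive(m))
            stop("motif is not primitive: ", m)
        min(c(.rotations(m), .rotations(.revcomp(m))))
    }, "", USE.NAMES = FALSE)
}

.rotations <- function(m) {
    k <- nchar(m)
    d <- paste0(m, m)
    vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), "")
}

.isPrimitive <- function(m) {
    k <- nchar(m)
    for (d in seq_len(k - 1L)) {
        if (k %% d == 0L &&
            m == strrep(substr(m, 1L, d), k %/% d))
            return(FALSE)
    }
    TRUE
}

#' Find perfect microsatellites in transcripts
#'
#' Scans each transcript for maximal perfect tandem repeats whose
#' primitive unit size is in `criteria@unitSizes` and whose reiteration
#' count meets the unit-size threshold. Maximality counts whole units
#' only: a partial trailing unit neither extends the span nor the
#' repeat count. Runs containing N are broken at the N. When maximal
#' runs of distinct motifs overlap, the longer run wins (ties: the
#' leftmost); a repeat tract is reported exactly once, under its
#' primitive unit.
#'
#' @param transcripts a named [Biostrings::DNAStringSet] (or named
#'   character vector) of transcript sequences.
#' @param criteria an [SSRCriteria] object.
#' @return a [GenomicRanges::GRanges] (seqnames = transcript ids,
#'   1-based inclusive spans) with metadata columns `motif`,
#'   `canonicalMotif`, `unitSize`, `repeatCount`, `totalLen`, `ssrType`
#'   (`"I"` if the tract is at least `type1MinLen` bp, else `"II"`) and
#'   `compound` (`NA` until [markCompound()] is applied), sorted by
#'   transcript then start.
#' @seealso [markCompound()], [filterLoci()], [ssrSummary()]
#' @export
findSSRs <- function(transcripts, criteria = SSRCriteria()) {
    stopifnot(is(criteria, "SSRCriteria"))
    seqs <- as.character(transcripts)
    names(seqs) <- names(transcripts)
    if (is.null(names(seqs)))
        stop("transcripts must be named")
    hits <- lapply(names(seqs), function(id)
        .scanOne(id, seqs[[id]], criteria))
    hits <- do.call(rbind, hits)
    if (is.null(hits) || nrow(hits) == 0L) {
        gr <- GenomicRanges::GRanges()
        mcols(gr) <- DataFrame(motif = character(),
                               canonicalMotif = character(),
                               unitSize = integer(), repeatCount = integer(),
                               totalLen = integer(), ssrType = character(),
                               compound = logical())
        return(gr)
    }
    gr <- GenomicRanges::GRanges(
        seqnames = hits$transcript_id,
        ranges = IRanges::IRanges(start = hits$start, end = hits$end))
    mcols(gr) <- DataFrame(
        motif = hits$motif,
        canonicalMotif = canonicalMotif(hits$motif),
        unitSize = hits$unitSize,
        repeatCount = hits$repeatCount,
        totalLen = hits$end - hits$start + 1L,
        ssrType = ifelse(hits$end - hits$start + 1L >= criteria@type1MinLen,
                         "I", "II"),
        compound = NA)
    gr[order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))]
}

## scan one sequence: vectorized shift-match run detection per unit size
.scanOne <- function(id, seq, criteria) {
    x <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(x)
    isN <- x == "N"
    res <- list()
    for (k in sort(criteria@unitSizes)) {
        if (n < 2L * k) next
        minrep <- criteria@minRepeats[[as.character(k)]]
        i <- seq_len(n - k)
        eq <- x[i] == x[i + k] & !isN[i] & !isN[i + k]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (j in which(r$values & r$lengths >= k * (2L - 1L))) {
            L <- r$lengths[j]
            s <- starts[j]
            count <- (L + k) %/% k
            if (count < minrep) next
            motif <- substr(seq, s, s + k - 1L)
            if (!.isPrimitive(motif)) next
            res[[length(res) + 1L]] <- data.frame(
                transcript_id = id, start = s, end = s + count * k - 1L,
                motif = motif, unitSize = k, repeatCount = count,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(res)) return(NULL)
    out <- do.call(rbind, res)
    .resolveOverlaps(out)
}

## distinct-motif overlapping runs: keep the longer, ties -> leftmost
.resolveOverlaps <- function(df) {
    len <- df$end - df$start + 1L
    ord <- order(-len, df$start, df$unitSize)
    keep <- logical(nrow(df))
    kept_start <- integer(0)
    kept_end <- integer(0)
    for (i in ord) {
        if (!any(df$start[i] <= kept_end & df$end[i] >= kept_start)) {
            keep[i] <- TRUE
            kept_start <- c(kept_start, df$start[i])
            kept_end <- c(kept_end, df$end[i])
        }
    }
    df[keep, , drop = FALSE]
}

#' Flag compound (complex) SSRs
#'
#' Two loci on the same transcript whose spans overlap or are separated
#' by at most `compoundMaxGap` bases are both flagged compound; the
#' flag is transitive along chains of nearby loci.
#'
#' @param loci a sorted `GRanges` from [findSSRs()].
#' @param criteria an [SSRCriteria] (only `compoundMaxGap` is used).
#' @return `loci` with the `compound` metadata column filled in.
#' @export
markCompound <- function(loci, criteria = SSRCriteria()) {
    if (length(loci) == 0L) return(loci)
    o <- order(as.character(GenomicRanges::seqnames(loci)),
               GenomicRanges::start(loci))
    if (!identical(o, seq_along(loci)))
        stop("loci must be sorted by transcript and start")
    gap <- criteria@compoundMaxGap
    cl <- GenomicRanges::reduce(loci, min.gapwidth = gap + 1L)
    clIdx <- GenomicRanges::findOverlaps(loci, cl, select = "first")
    sizes <- tabulate(clIdx, nbins = length(cl))
    mcols(loci)$compound <- sizes[clIdx] >= 2L
    loci
}

#' Filter SSR loci for marker development
#'
#' Drops mononucleotide loci, compound loci, and loci whose total tract
#' is shorter than `minTotalLen`; the survivors keep their Type I/II
#' annotation (Type I: tract of at least `type1MinLen` bp).
#'
#' @param loci a `GRanges` with the `compound` flag set (see
#'   [markCompound()]).
#' @param criteria an [SSRCriteria] object.
#' @return the retained loci.
#' @export
filterLoci <- function(loci, criteria = SSRCriteria()) {
    if (length(loci) == 0L) return(loci)
    if (anyNA(mcols(loci)$compound))
        stop("compound flags not set; run markCompound() first")
    keep <- mcols(loci)$unitSize > 1L &
        !mcols(loci)$compound &
        mcols(loci)$totalLen >= criteria@minTotalLen
    out <- loci[keep]
    mcols(out)$ssrType <- ifelse(mcols(out)$totalLen >= criteria@type1MinLen,
                                 "I", "II")
    out
}

#' Frequency summaries of retained SSR loci
#'
#' Tabulates retained loci by unit-size category (di ... hexa) with
#' percentages, counts unigenes carrying one vs two-or-more loci, and
#' builds the canonical-motif-by-repeat-count frequency table.
#'
#' @param loci retained loci from [filterLoci()].
#' @param nUnigenes total number of unigenes scanned (denominator for
#'   the "unigenes with SSR" fraction).
#' @return a list with elements `categories` (data.frame: category,
#'   unitSize, count, percent), `unigenes` (withSSR, fractionPercent,
#'   single, multi), `motifTable` (data.frame: canonicalMotif,
#'   repeatCount, count) and `nLoci`.
#' @export
ssrSummary <- function(loci, nUnigenes) {
    if (length(nUnigenes) != 1L || is.na(nUnigenes) || nUnigenes <= 0)
        stop("nUnigenes must be a positive count")
    catNames <- c("mono", "di", "tri", "tetra", "penta", "hexa")
    us <- mcols(loci)$unitSize
    counts <- vapply(1:6, function(k) sum(us == k), 0L)
    nLoci <- length(loci)
    categories <- data.frame(
        category = catNames, unitSize = 1:6, count = counts,
        percent = if (nLoci) round(100 * counts / nLoci, 2) else rep(0, 6),
        stringsAsFactors = FALSE)
    perTx <- table(as.character(GenomicRanges::seqnames(loci)))
    unigenes <- list(
        withSSR = length(perTx),
        fractionPercent = round(100 * length(perTx) / nUnigenes, 2),
        single = sum(perTx == 1L),
        multi = sum(perTx >= 2L))
    if (nLoci) {
        mt <- as.data.frame(table(
            canonicalMotif = mcols(loci)$canonicalMotif,
            repeatCount = mcols(loci)$repeatCount),
            stringsAsFactors = FALSE)
        mt <- mt[mt$Freq > 0L, , drop = FALSE]
        mt$repeatCount <- as.integer(mt$repeatCount)
        names(mt)[3] <- "count"
        mt <- mt[order(mt$canonicalMotif, mt$repeatCount), , drop = FALSE]
        rownames(mt) <- NULL
    } else {
        mt <- data.frame(canonicalMotif = character(),
                         repeatCount = integer(), count = integer(),
                         stringsAsFactors = FALSE)
    }
    list(categories = categories, unigenes = unigenes,
         motifTable = mt, nLoci = nLoci)
}

#' Convert SSR loci to a plain table
#'
#' @param loci a `GRanges` of SSR loci.
#' @return a data.frame with columns transcript_id, start, end, motif,
#'   canonical_motif, repeat_count, total_len, type, compound.
#' @export
ssrTable <- function(loci) {
    data.frame(
        transcript_id = as.character(GenomicRanges::seqnames(loci)),
        start = GenomicRanges::start(loci),
        end = GenomicRanges::end(loci),
        motif = mcols(loci)$motif,
        canonical_motif = mcols(loci)$canonicalMotif,
        repeat_count = mcols(loci)$repeatCount,
        total_len = mcols(loci)$totalLen,
        type = mcols(loci)$ssrType,
        compound = mcols(loci)$compound,
        stringsAsFactors = FALSE)
}
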