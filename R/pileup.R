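#' Tag read headers with a variety name
#'
#' Appends `"|VARIETY"` to every read id, mirroring the practice of
#' adding the variety name to the header of each read so that
#' per-variety evidence can be recovered after pooled alignment. The
#' pipe delimiter is rare in read names and survives SAM.
#'
#' @param reads a named object (e.g. a
#'   [Biostrings::QualityScaledDNAStringSet]).
#' @param variety a non-empty label without whitespace or `"|"`.
#' @return `reads` with tagged names.
#' @seealso [untagReads()], [varietyOf()]
#' @export
tagReads <- function(reads, variety) {
    if (length(variety) != 1L || !nzchar(variety) ||
        grepl("[|[:space:]]", variety))
        stop("variety label must be non-empty, without whitespace or '|'")
    ids <- names(reads)
    if (any(grepl("|", ids, fixed = TRUE)))
        stop("reads already carry a variety tag")
    names(reads) <- paste0(ids, "|", variety)
    reads
}

#' @rdname tagReads
#' @export
untagReads <- function(reads) {
    names(reads) <- sub("\\|[^|]*$", "", names(reads))
    reads
}

#' @param ids character vector of (tagged) read ids.
#' @return `varietyOf` returns the tag of each id (`NA` if untagged).
#' @rdname tagReads
#' @export
varietyOf <- function(ids) {
    tag <- sub("^.*\\|", "", ids)
    tag[!grepl("|", ids, fixed = TRUE)] <- NA_character_
    tag
}

#' Build per-variety pileups from variety-tagged alignments
#'
#' Walks each mapped alignment's CIGAR: M/=/X operations consume read
#' and reference and contribute (base, quality) to the column at each
#' reference position; I and S consume read only; D consumes reference
#' only. Tallies are kept separately per variety, keyed by the tag
#' parsed from the read id. N base calls are skipped.
#'
#' @param alignments a data.frame as returned by [readSAM()].
#' @param reference a named [Biostrings::DNAStringSet].
#' @param varieties character vector of expected variety labels.
#' @return a [TrioPileup] object.
#' @export
buildPileup <- function(alignments, reference, varieties) {
    refSeqs <- as.character(reference)
    aln <- alignments[!alignments$unmapped, , drop = FALSE]
    nSkipped <- sum(alignments$unmapped) +
        (attr(alignments, "skipped") %||% 0L)
    if (nrow(aln)) {
        unknown <- setdiff(unique(aln$rname), names(refSeqs))
        if (length(unknown))
            stop("alignment references unknown transcript: ", unknown[1L])
        vt <- varietyOf(aln$qname)
        if (anyNA(vt))
            stop("read without variety tag: ", aln$qname[which(is.na(vt))[1L]])
        badv <- setdiff(unique(vt), varieties)
        if (length(badv))
            stop("unexpected variety tag: ", badv[1L])
        aln$varIdx <- match(vt, varieties)
    }
    V <- length(varieties)
    data <- lapply(names(refSeqs), function(tid) {
        L <- nchar(refSeqs[[tid]])
        sub <- aln[aln$rname == tid, , drop = FALSE]
        .pileOne(sub, L, V, refSeqs[[tid]])
    })
    names(data) <- names(refSeqs)
    new("TrioPileup", varieties = varieties, data = data,
        nSkipped = as.integer(nSkipped))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## pile alignments of one transcript into depth/qual arrays
.pileOne <- function(aln, L, V, refSeq) {
    depth <- array(0L, dim = c(4L, L, V))
    qual <- array(0, dim = c(4L, L, V))
    if (nrow(aln)) {
        rl <- nchar(aln$seq)
        simple <- aln$cigar == paste0(rl, "M")
        refIdx <- vector("list", nrow(aln))
        qryIdx <- vector("list", nrow(aln))
        if (any(simple)) {
            w <- which(simple)
            lens <- rl[w]
            refIdx[w] <- split(rep(aln$pos[w], lens) + sequence(lens) - 1L,
                               rep(seq_along(w), lens))
            qryIdx[w] <- split(sequence(lens), rep(seq_along(w), lens))
        }
        for (i in which(!simple)) {
            walk <- .cigarWalk(aln$cigar[i], aln$pos[i])
            refIdx[[i]] <- walk$ref
            qryIdx[[i]] <- walk$qry
        }
        nb <- lengths(refIdx)
        rp <- unlist(refIdx, use.names = FALSE)
        off <- rep(cumsum(c(0L, rl))[seq_len(nrow(aln))], nb)
        qp <- off + unlist(qryIdx, use.names = FALSE)
        bigSeq <- paste(aln$seq, collapse = "")
        bigQual <- paste(aln$qual, collapse = "")
        base <- .baseCodes(bigSeq)[qp]
        qv <- (as.integer(charToRaw(bigQual)) - 33L)[qp]
        vi <- rep(aln$varIdx, nb)
        ok <- !is.na(base) & rp >= 1L & rp <= L
        idx <- base[ok] + 4L * (rp[ok] - 1L) + 4L * L * (vi[ok] - 1L)
        depth[] <- tabulate(idx, nbins = 4L * L * V)
        qs <- rowsum(as.numeric(qv[ok]), idx)
        qual[as.integer(rownames(qs))] <- qs[, 1L]
    }
    list(depth = depth, qual = qual, ref = .baseCodes(refSeq))
}

## aligned (reference position, query position) pairs for one CIGAR
.cigarWalk <- function(cigar, pos) {
    p <- .parseCigar(cigar)
    refs <- integer(0); qrys <- integer(0)
    r <- pos; q <- 1L
    for (i in seq_along(p$ops)) {
        op <- p$ops[i]; len <- p$lengths[i]
        if (op %in% c("M", "=", "X")) {
            refs <- c(refs, r:(r + len - 1L))
            qrys <- c(qrys, q:(q + len - 1L))
            r <- r + len; q <- q + len
        } else if (op %in% c("I", "S")) {
            q <- q + len
        } else if (op == "D") {
            r <- r + len
        } else {
            stop("unsupported CIGAR op '", op, "' in ", cigar)
        }
    }
    list(ref = refs, qry = qrys)
}

#' Call biallelic SNPs from a trio pileup
#'
#' A site is reported iff (i) read depth pooled over varieties is at
#' least `minTotalDepth`; (ii) the mean Phred quality over all bases
#' piled at the position is at least `minAvgBaseQual`; (iii) exactly
#' two alleles are supported, where an allele is supported iff at least
#' `minAlleleReads` reads carry it within at least one variety; and
#' (iv) at least one supported allele differs from the reference base.
#' Alleles with only sub-threshold support in every variety are treated
#' as noise and do not count toward the allele number; a position with
#' more than two supported alleles is dropped as multi-allelic. A
#' single supported allele differing from the reference is a
#' homozygous-variant site and is reported with zero depth on the
#' reference side. When two non-reference alleles are supported, the
#' lexicographically smaller is reported on the ref side and the
#' original reference base is retained in the `ref_base` column.
#'
#' @param pileup a [TrioPileup] from [buildPileup()].
#' @param filters an [SNPFilters] object.
#' @return a data.frame with columns `transcript_id`, `pos`, `ref`,
#'   `alt`, `ref_base`, per-variety `<V>_refDepth` / `<V>_altDepth`,
#'   `avg_qual`, `total_depth`; attribute `dropCounts` tallies why
#'   candidate variant positions were dropped.
#' @export
callSnps <- function(pileup, filters = SNPFilters()) {
    stopifnot(is(pileup, "TrioPileup"), is(filters, "SNPFilters"))
    varieties <- pileup@varieties
    drops <- c(low_depth = 0L, low_avg_quality = 0L,
               multiallelic = 0L, no_supported_alt = 0L)
    rows <- list()
    for (tid in names(pileup@data)) {
        d <- pileup@data[[tid]]
        L <- dim(d$depth)[2L]
        pooledBase <- rowSums(d$depth, dims = 2L)      # 4 x L
        pooled <- colSums(pooledBase)                  # depth per position
        qsum <- colSums(rowSums(d$qual, dims = 2L))
        ## supported alleles: >= minAlleleReads within some variety
        supp <- matrix(FALSE, 4L, L)
        for (v in seq_along(varieties))
            supp <- supp | d$depth[, , v] >= filters@minAlleleReads
        refIdx <- d$ref
        nonref <- pooledBase
        hasRef <- !is.na(refIdx)
        nonref[cbind(refIdx[hasRef], which(hasRef))] <- 0L
        cand <- which(colSums(nonref > 0L) > 0L)       # any non-ref evidence
        if (!length(cand)) next
        avgq <- qsum[cand] / pmax(pooled[cand], 1L)
        okDepth <- pooled[cand] >= filters@minTotalDepth
        okQual <- avgq >= filters@minAvgBaseQual
        nSupp <- colSums(supp)[cand]
        nSuppAlt <- vapply(cand, function(p) {
            length(setdiff(which(supp[, p]), refIdx[p]))
        }, 0L)
        emit <- okDepth & okQual & nSupp <= filters@maxAlleles &
            nSuppAlt >= 1L & !(is.na(refIdx[cand]) & nSupp < 2L)
        drops["low_depth"] <- drops["low_depth"] + sum(!okDepth)
        drops["low_avg_quality"] <- drops["low_avg_quality"] +
            sum(okDepth & !okQual)
        drops["multiallelic"] <- drops["multiallelic"] +
            sum(okDepth & okQual & nSupp > filters@maxAlleles)
        drops["no_supported_alt"] <- drops["no_supported_alt"] +
            sum(okDepth & okQual & nSupp <= filters@maxAlleles & !emit)
        for (j in which(emit)) {
            p <- cand[j]
            alleles <- which(supp[, p])
            if (!is.na(refIdx[p]) && refIdx[p] %in% alleles) {
                refA <- refIdx[p]
                altA <- setdiff(alleles, refA)
            } else if (length(alleles) == 1L) {
                refA <- refIdx[p]
                altA <- alleles
            } else {
                refA <- min(alleles)
                altA <- max(alleles)
            }
            row <- data.frame(transcript_id = tid, pos = p,
                              ref = .BASES[refA], alt = .BASES[altA],
                              ref_base = if (is.na(refIdx[p])) "N" else
                                  .BASES[refIdx[p]],
                              stringsAsFactors = FALSE)
            for (v in seq_along(varieties)) {
                row[[paste0(varieties[v], "_refDepth")]] <- d$depth[refA, p, v]
                row[[paste0(varieties[v], "_altDepth")]] <- d$depth[altA, p, v]
            }
            row$avg_qual <- qsum[p] / pooled[p]
            row$total_depth <- pooled[p]
            rows[[length(rows) + 1L]] <- row
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else {
        tmpl <- data.frame(transcript_id = character(), pos = integer(),
                           ref = character(), alt = character(),
                           ref_base = character(), stringsAsFactors = FALSE)
        for (v in varieties) {
            tmpl[[paste0(v, "_refDepth")]] <- integer()
            tmpl[[paste0(v, "_altDepth")]] <- integer()
        }
        tmpl$avg_qual <- numeric(); tmpl$total_depth <- integer()
        tmpl
    }
    rownames(out) <- NULL
    attr(out, "dropCounts") <- drops
    out
}
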