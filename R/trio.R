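## the eight ordered (parent, parent, hybrid) zygosity patterns;
## row i is trio class i
.CLASS_ZYGOSITY <- data.frame(
    parent1 = c("HM", "HT", "HM", "HT", "HT", "HM", "HM", "HT"),
    parent2 = c("HM", "HM", "HT", "HT", "HT", "HM", "HT", "HM"),
    hybrid  = c("HT", "HT", "HT", "HT", "HM", "HM", "HM", "HM"),
    stringsAsFactors = FALSE)

#' Per-variety zygosity from allele depths
#'
#' A variety is heterozygous (HT) when both alleles reach the minimum
#' read support, homozygous (HM) when exactly one does, and NOCALL when
#' neither does.
#'
#' @param refDepth,altDepth non-negative integer vectors of per-variety
#'   read depths for the site's two alleles.
#' @param minAlleleReads minimum reads for an allele to count (default
#'   2, as in the calling filters).
#' @return character vector over `"HM"`, `"HT"`, `"NOCALL"`.
#' @export
callZygosity <- function(refDepth, altDepth, minAlleleReads = 2L) {
    a <- refDepth >= minAlleleReads
    b <- altDepth >= minAlleleReads
    ifelse(a & b, "HT", ifelse(a | b, "HM", "NOCALL"))
}

#' Classify a parent/parent/hybrid zygosity triple
#'
#' Maps the ordered triple of zygosity calls onto trio classes 1--8:
#' 1=(HM,HM,HT), 2=(HT,HM,HT), 3=(HM,HT,HT), 4=(HT,HT,HT),
#' 5=(HT,HT,HM), 6=(HM,HM,HM), 7=(HM,HT,HM), 8=(HT,HM,HM). The map is
#' a bijection from \{HM,HT\}^3 onto \{1..8\}. A triple containing a
#' NOCALL returns `NA` (the site is excluded from the trio table, which
#' covers only sites with calls common to all three genotypes).
#'
#' @param zParent1,zParent2,zHybrid character vectors of zygosity calls.
#' @return integer vector of trio classes (NA for incomplete triples).
#' @export
classifyTrio <- function(zParent1, zParent2, zHybrid) {
    key <- paste(zParent1, zParent2, zHybrid)
    lut <- structure(seq_len(8L), names = paste(
        .CLASS_ZYGOSITY$parent1, .CLASS_ZYGOSITY$parent2,
        .CLASS_ZYGOSITY$hybrid))
    unname(lut[key])
}

#' Classify SNP sites into the eight trio classes
#'
#' Applies [callZygosity()] per variety to a SNP site table from
#' [callSnps()] and attaches per-variety zygosity columns and the trio
#' `class` column (NA where any variety is NOCALL).
#'
#' @param sites a SNP site table from [callSnps()].
#' @param varieties character(3): parent, parent, hybrid labels,
#'   matching the depth column prefixes of `sites`.
#' @param filters an [SNPFilters] (source of `minAlleleReads`).
#' @return `sites` with added `zyg_<V>` columns and `class`.
#' @export
classifySnpTrio <- function(sites, varieties, filters = SNPFilters()) {
    stopifnot(length(varieties) == 3L)
    z <- lapply(varieties, function(v)
        callZygosity(sites[[paste0(v, "_refDepth")]],
                     sites[[paste0(v, "_altDepth")]],
                     filters@minAlleleReads))
    for (i in 1:3) sites[[paste0("zyg_", varieties[i])]] <- z[[i]]
    sites$class <- classifyTrio(z[[1]], z[[2]], z[[3]])
    sites
}

#' Summarize a classified trio table
#'
#' Computes the eight class counts and the derived heterozygosity
#' metrics: per-variety HT counts (`HT_p1 = c2+c4+c5+c8`,
#' `HT_p2 = c3+c4+c5+c7`, `HT_hyb = c1+c2+c3+c4`) and percentages,
#' novel heterozygosity (`c1`), maintained heterozygosity
#' (`c2+c3+c4`), lost heterozygosity (`c5+c7+c8`), and the
#' SNPs-per-transcript distribution over transcripts bearing at least
#' one classified site.
#'
#' The input may be either a classified site table (see
#' [classifySnpTrio()]) or a bare vector of eight class counts, e.g.
#' a published trio table whose arithmetic is to be reproduced; in the
#' latter case the number of transcripts may be supplied separately.
#'
#' @param x a classified site data.frame with columns `class` and
#'   `transcript_id`, or a numeric vector of 8 class counts.
#' @param varieties character(3) labels for the two parents and hybrid.
#' @param nTranscripts optional transcript count (counts-vector method
#'   only) used for the mean SNPs-per-transcript.
#' @return a [TrioSummary].
#' @export
setGeneric("summarizeTrio", function(x, varieties = c("NEELAM",
    "DASHEHARI", "AMRAPALI"), nTranscripts = NA_integer_)
    standardGeneric("summarizeTrio"))

#' @rdname summarizeTrio
#' @export
setMethod("summarizeTrio", "numeric",
    function(x, varieties, nTranscripts) {
        if (length(x) != 8L || anyNA(x) || any(x < 0))
            stop("expected 8 non-negative class counts")
        perTx <- if (!is.na(nTranscripts) && nTranscripts > 0)
            c(mean = sum(x) / nTranscripts, min = NA_real_, max = NA_real_)
        else c(mean = NA_real_, min = NA_real_, max = NA_real_)
        .newTrioSummary(as.integer(round(x)), varieties,
                        nocall = 0L,
                        nTranscripts = as.integer(nTranscripts),
                        perTx = perTx)
    })

#' @rdname summarizeTrio
#' @export
setMethod("summarizeTrio", "data.frame",
    function(x, varieties, nTranscripts) {
        cl <- x$class
        nocall <- sum(is.na(cl))
        cc <- vapply(1:8, function(k) sum(cl == k, na.rm = TRUE), 0L)
        keep <- !is.na(cl)
        if (any(keep) && !is.null(x$transcript_id)) {
            perTxTab <- table(x$transcript_id[keep])
            perTx <- c(mean = mean(perTxTab), min = min(perTxTab),
                       max = max(perTxTab))
            ntx <- length(perTxTab)
        } else {
            perTx <- c(mean = NA_real_, min = NA_real_, max = NA_real_)
            ntx <- 0L
        }
        .newTrioSummary(cc, varieties, nocall = nocall,
                        nTranscripts = as.integer(ntx), perTx = perTx)
    })

.newTrioSummary <- function(cc, varieties, nocall, nTranscripts, perTx) {
    total <- sum(cc)
    ht <- c(cc[2] + cc[4] + cc[5] + cc[8],
            cc[3] + cc[4] + cc[5] + cc[7],
            cc[1] + cc[2] + cc[3] + cc[4])
    names(ht) <- varieties
    pct <- if (total > 0) 100 * ht / total else c(0, 0, 0)
    names(pct) <- varieties
    new("TrioSummary",
        classCounts = cc, total = as.integer(total),
        htCounts = ht, htPercent = pct,
        novelHet = cc[1], maintainedHet = cc[2] + cc[3] + cc[4],
        lostHet = cc[5] + cc[7] + cc[8],
        nocallExcluded = as.integer(nocall),
        nTranscripts = nTranscripts, snpsPerTranscript = perTx)
}

#' Accessors for TrioSummary
#'
#' @param object a [TrioSummary].
#' @return `classCounts`: integer(8); `htCounts`/`htPercent`: named
#'   numeric(3); `hetPartition`: named numeric with novel, maintained
#'   and lost heterozygosity counts.
#' @name TrioSummary-accessors
NULL

#' @rdname TrioSummary-accessors
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))
#' @rdname TrioSummary-accessors
#' @export
setMethod("classCounts", "TrioSummary", function(object) object@classCounts)

#' @rdname TrioSummary-accessors
#' @export
setGeneric("htCounts", function(object) standardGeneric("htCounts"))
#' @rdname TrioSummary-accessors
#' @export
setMethod("htCounts", "TrioSummary", function(object) object@htCounts)

#' @rdname TrioSummary-accessors
#' @export
setGeneric("htPercent", function(object) standardGeneric("htPercent"))
#' @rdname TrioSummary-accessors
#' @export
setMethod("htPercent", "TrioSummary", function(object) object@htPercent)

#' @rdname TrioSummary-accessors
#' @export
setGeneric("hetPartition", function(object) standardGeneric("hetPartition"))
#' @rdname TrioSummary-accessors
#' @export
setMethod("hetPartition", "TrioSummary", function(object)
    c(novel = object@novelHet, maintained = object@maintainedHet,
      lost = object@lostHet))

#' @rdname TrioSummary-accessors
#' @export
setGeneric("snpsPerTranscript", function(object)
    standardGeneric("snpsPerTranscript"))
#' @rdname TrioSummary-accessors
#' @export
setMethod("snpsPerTranscript", "TrioSummary", function(object)
    object@snpsPerTranscript)

#' Render the trio table report
#'
#' Emits the eight-class table with a totals row (columns: Class, the
#' three varieties, No_of_SNPs) plus a derived-metrics block with the
#' per-variety HT percentages (2 decimal places) and the
#' novel/maintained/lost heterozygosity partition.
#'
#' @param summary a [TrioSummary].
#' @return a list with data.frames `table` and `derived`.
#' @export
heterozygosityReport <- function(summary) {
    stopifnot(is(summary, "TrioSummary"))
    v <- names(summary@htCounts)
    tab <- data.frame(Class = as.character(1:8),
                      .CLASS_ZYGOSITY,
                      No_of_SNPs = summary@classCounts,
                      stringsAsFactors = FALSE)
    names(tab)[2:4] <- v
    tot <- data.frame(Class = "Total",
                      t(sprintf("%d HT", as.integer(summary@htCounts))),
                      No_of_SNPs = summary@total, stringsAsFactors = FALSE)
    names(tot) <- names(tab)
    tab <- rbind(tab, tot)
    derived <- data.frame(
        metric = c(paste0("HT_percent_", v), "novel_het", "maintained_het",
                   "lost_het", "nocall_excluded", "mean_snps_per_transcript"),
        value = c(round(summary@htPercent, 2), summary@novelHet,
                  summary@maintainedHet, summary@lostHet,
                  summary@nocallExcluded,
                  round(summary@snpsPerTranscript[["mean"]], 1)),
        stringsAsFactors = FALSE)
    list(table = tab, derived = derived)
}
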