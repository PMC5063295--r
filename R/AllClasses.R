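#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' SSR search criteria
#'
#' Thresholds controlling microsatellite detection and filtering.
#' Defaults follow common practice for transcriptome (EST) SSR mining:
#' only motifs of 2--6 bp are considered, a di-nucleotide motif must
#' reiterate at least 6 times and tri- to hexa-nucleotide motifs at
#' least 5 times; loci shorter than 10 bp in total are discarded; loci
#' of 20 bp or more are classed Type I (the polymorphism-prone class
#' preferred for marker development), shorter ones Type II; two loci
#' closer than 100 bp are flagged as a compound (complex) SSR.
#'
#' @slot minRepeats named integer vector: minimum reiterations per unit
#'   size (names are unit sizes in bases).
#' @slot minTotalLen minimum total tract length in bp for a locus to be
#'   retained.
#' @slot type1MinLen minimum tract length in bp for Type I status.
#' @slot compoundMaxGap maximum gap in bp between two loci for them to
#'   be flagged compound.
#' @slot unitSizes integer set of motif lengths to scan.
#'
#' @seealso [findSSRs()], [filterLoci()], [markCompound()]
#' @export
setClass("SSRCriteria",
    representation(
        minRepeats = "integer",
        minTotalLen = "integer",
        type1MinLen = "integer",
        compoundMaxGap = "integer",
        unitSizes = "integer"
    )
)

setValidity("SSRCriteria", function(object) {
    msg <- NULL
    if (!all(object@unitSizes %in% 1:6))
        msg <- c(msg, "unitSizes must be a subset of 1..6")
    if (is.null(names(object@minRepeats)) ||
        !all(as.character(object@unitSizes) %in% names(object@minRepeats)))
        msg <- c(msg, "minRepeats must be named and cover every unit size")
    if (any(c(object@minRepeats, object@minTotalLen, object@type1MinLen) < 1L))
        msg <- c(msg, "all thresholds must be >= 1")
    if (object@compoundMaxGap < 0L)
        msg <- c(msg, "compoundMaxGap must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @param minRepeats,minTotalLen,type1MinLen,compoundMaxGap,unitSizes see slots.
#' @return `SSRCriteria()` returns a validated `SSRCriteria` object.
#' @rdname SSRCriteria-class
#' @export
SSRCriteria <- function(minRepeats = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                       `4` = 5L, `5` = 5L, `6` = 5L),
                        minTotalLen = 10L, type1MinLen = 20L,
                        compoundMaxGap = 100L, unitSizes = 2:6) {
    mr <- as.integer(minRepeats)
    names(mr) <- names(minRepeats)
    new("SSRCriteria", minRepeats = mr,
        minTotalLen = as.integer(minTotalLen),
        type1MinLen = as.integer(type1MinLen),
        compoundMaxGap = as.integer(compoundMaxGap),
        unitSizes = as.integer(unitSizes))
}

#' Primer design constraints
#'
#' Hard constraints and targets for SSR-flanking PCR primer pairs:
#' primer length 20--25 bases, product size 100--250 bp, annealing
#' target 65 degrees C, GC content 40--60% with 50% optimum, and at
#' most a single consecutive G or C at each primer's 3' terminus.
#'
#' @slot lenMin,lenMax primer length bounds (bases).
#' @slot productMin,productMax PCR product size bounds (bp).
#' @slot tmTarget target melting/annealing temperature (degrees C).
#' @slot gcMin,gcMax,gcOpt GC-content bounds and optimum (percent).
#'
#' @seealso [designPrimers()]
#' @export
setClass("PrimerConstraints",
    representation(
        lenMin = "integer", lenMax = "integer",
        productMin = "integer", productMax = "integer",
        tmTarget = "numeric",
        gcMin = "numeric", gcMax = "numeric", gcOpt = "numeric"
    )
)

setValidity("PrimerConstraints", function(object) {
    msg <- NULL
    if (object@lenMin > object@lenMax) msg <- c(msg, "lenMin > lenMax")
    if (object@productMin > object@productMax) msg <- c(msg, "productMin > productMax")
    if (!(object@gcMin <= object@gcOpt && object@gcOpt <= object@gcMax))
        msg <- c(msg, "need gcMin <= gcOpt <= gcMax")
    if (is.null(msg)) TRUE else msg
})

#' @param lenMin,lenMax,productMin,productMax,tmTarget,gcMin,gcMax,gcOpt see slots.
#' @return `PrimerConstraints()` returns a validated `PrimerConstraints` object.
#' @rdname PrimerConstraints-class
#' @export
PrimerConstraints <- function(lenMin = 20L, lenMax = 25L,
                              productMin = 100L, productMax = 250L,
                              tmTarget = 65, gcMin = 40, gcMax = 60,
                              gcOpt = 50) {
    new("PrimerConstraints",
        lenMin = as.integer(lenMin), lenMax = as.integer(lenMax),
        productMin = as.integer(productMin), productMax = as.integer(productMax),
        tmTarget = as.numeric(tmTarget), gcMin = as.numeric(gcMin),
        gcMax = as.numeric(gcMax), gcOpt = as.numeric(gcOpt))
}

#' SNP calling filters
#'
#' The three stringency filters applied to pileup columns before a
#' biallelic SNP is reported: minimum pooled read depth at the
#' position, minimum mean Phred base quality over all piled bases, and
#' minimum read support for an allele to count within a variety. A
#' site with more than `maxAlleles` supported alleles is dropped as
#' multi-allelic.
#'
#' @slot minTotalDepth minimum read depth pooled over varieties.
#' @slot minAvgBaseQual minimum mean Phred base quality at the position.
#' @slot minAlleleReads minimum reads carrying an allele within a single
#'   variety for that allele to be "supported".
#' @slot maxAlleles maximum number of supported alleles (fixed at 2).
#'
#' @seealso [callSnps()], [callZygosity()]
#' @export
setClass("SNPFilters",
    representation(
        minTotalDepth = "integer",
        minAvgBaseQual = "numeric",
        minAlleleReads = "integer",
        maxAlleles = "integer"
    )
)

setValidity("SNPFilters", function(object) {
    msg <- NULL
    if (object@minTotalDepth < 1L || object@minAlleleReads < 1L ||
        object@minAvgBaseQual < 1)
        msg <- c(msg, "all filter thresholds must be >= 1")
    if (object@maxAlleles != 2L)
        msg <- c(msg, "maxAlleles must be 2 (biallelic SNPs only)")
    if (is.null(msg)) TRUE else msg
})

#' @param minTotalDepth,minAvgBaseQual,minAlleleReads,maxAlleles see slots.
#' @return `SNPFilters()` returns a validated `SNPFilters` object.
#' @rdname SNPFilters-class
#' @export
SNPFilters <- function(minTotalDepth = 10L, minAvgBaseQual = 25,
                       minAlleleReads = 2L, maxAlleles = 2L) {
    new("SNPFilters", minTotalDepth = as.integer(minTotalDepth),
        minAvgBaseQual = as.numeric(minAvgBaseQual),
        minAlleleReads = as.integer(minAlleleReads),
        maxAlleles = as.integer(maxAlleles))
}

#' Trio simulation configuration
#'
#' Parameters of the synthetic trio experiment: reference transcripts
#' with embedded SSRs, biallelic SNP sites whose parent/parent/hybrid
#' zygosity states follow configurable proportions over the eight trio
#' classes (or arise Mendelianly), and uniform-coverage reads with a
#' per-base substitution error rate and constant Phred quality.
#'
#' Defaults emulate the study design the package targets: three
#' varieties (two parents, one F1 hybrid), 50 bp reads at 30x coverage
#' per variety, constant base quality 30, 1% substitution error, and
#' class proportions matching the empirical eight-class distribution of
#' a crossbred mango trio.
#'
#' @slot nTranscripts number of reference transcripts.
#' @slot lengthRange transcript length range in bp (uniform draw).
#' @slot ssrProb probability that a transcript carries one embedded SSR.
#' @slot snpSitesTotal total number of biallelic truth sites to place.
#' @slot classProportions numeric(8), proportions over the eight trio
#'   classes (direct mode); must sum to 1.
#' @slot mode `"direct"` (draw a class, then consistent genotypes) or
#'   `"mendelian"` (draw parents, hybrid inherits one allele from each).
#' @slot coveragePerVariety mean fold-coverage per variety.
#' @slot readLen read length in bases.
#' @slot errorRate per-base substitution error probability.
#' @slot baseQuality constant Phred quality assigned to every base.
#' @slot varieties character(3): parent, parent, hybrid labels, in the
#'   order used for trio classification.
#' @slot seed integer seed; all randomness flows from it.
#'
#' @seealso [simulateTrioExperiment()]
#' @export
setClass("SimConfig",
    representation(
        nTranscripts = "integer",
        lengthRange = "integer",
        ssrProb = "numeric",
        snpSitesTotal = "integer",
        classProportions = "numeric",
        mode = "character",
        coveragePerVariety = "numeric",
        readLen = "integer",
        errorRate = "numeric",
        baseQuality = "integer",
        varieties = "character",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (length(object@lengthRange) != 2L ||
        object@lengthRange[1] > object@lengthRange[2])
        msg <- c(msg, "lengthRange must be c(min, max) with min <= max")
    if (abs(sum(object@classProportions) - 1) > 1e-9 ||
        length(object@classProportions) != 8L ||
        any(object@classProportions < 0))
        msg <- c(msg, "classProportions must be 8 non-negative values summing to 1")
    if (!object@mode %in% c("direct", "mendelian"))
        msg <- c(msg, "mode must be 'direct' or 'mendelian'")
    if (object@readLen > object@lengthRange[1])
        msg <- c(msg, "readLen must not exceed the shortest transcript")
    if (length(object@varieties) != 3L || anyDuplicated(object@varieties) ||
        any(grepl("[|[:space:]]", object@varieties)))
        msg <- c(msg, "varieties must be 3 distinct labels without whitespace or '|'")
    if (any(c(object@nTranscripts, object@snpSitesTotal, object@readLen) < 1L) ||
        object@coveragePerVariety < 0 || object@errorRate < 0 ||
        object@errorRate > 1 || object@baseQuality < 0L)
        msg <- c(msg, "sizes must be positive; rates within range")
    if (is.null(msg)) TRUE else msg
})

## Eight-class proportions of the reference trio experiment
.TABLE3_COUNTS <- c(6831L, 4158L, 2049L, 1354L, 2061L, 1154L, 1270L, 3429L)

#' @param nTranscripts,lengthRange,ssrProb,snpSitesTotal,classProportions,mode
#'   see slots.
#' @param coveragePerVariety,readLen,errorRate,baseQuality,varieties,seed see
#'   slots.
#' @return `SimConfig()` returns a validated `SimConfig` object.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(nTranscripts = 100L,
                      lengthRange = c(400L, 1500L),
                      ssrProb = 0.5,
                      snpSitesTotal = 1000L,
                      classProportions = .TABLE3_COUNTS / sum(.TABLE3_COUNTS),
                      mode = "direct",
                      coveragePerVariety = 30,
                      readLen = 50L,
                      errorRate = 0.01,
                      baseQuality = 30L,
                      varieties = c("NEELAM", "DASHEHARI", "AMRAPALI"),
                      seed = 1L) {
    new("SimConfig",
        nTranscripts = as.integer(nTranscripts),
        lengthRange = as.integer(lengthRange),
        ssrProb = as.numeric(ssrProb),
        snpSitesTotal = as.integer(snpSitesTotal),
        classProportions = as.numeric(classProportions),
        mode = mode,
        coveragePerVariety = as.numeric(coveragePerVariety),
        readLen = as.integer(readLen),
        errorRate = as.numeric(errorRate),
        baseQuality = as.integer(baseQuality),
        varieties = varieties,
        seed = as.integer(seed))
}

#' Per-variety pileup of variety-tagged alignments
#'
#' Holds, for each transcript, per-position base tallies split by
#' variety: an integer depth array of dimension (base A/C/G/T,
#' position, variety) and a matching Phred quality-sum array, plus the
#' reference base at each position. Built by [buildPileup()] and
#' consumed by [callSnps()].
#'
#' @slot varieties character vector of variety labels (array dimension 3).
#' @slot data named list (one element per transcript) of lists with
#'   elements `depth`, `qual` (arrays) and `ref` (integer base codes).
#' @slot nSkipped number of alignment records skipped (unmapped or
#'   unsupported CIGAR).
#' @export
setClass("TrioPileup",
    representation(
        varieties = "character",
        data = "list",
        nSkipped = "integer"
    )
)

setMethod("show", "TrioPileup", function(object) {
    nt <- length(object@data)
    npos <- sum(vapply(object@data, function(d) dim(d$depth)[2L], 0L))
    cat("TrioPileup:", nt, "transcript(s),", npos, "reference positions\n")
    cat("  varieties:", paste(object@varieties, collapse = ", "), "\n")
    dp <- sum(vapply(object@data, function(d) sum(d$depth), 0))
    cat("  piled bases:", dp,
        sprintf("(mean depth %.1fx pooled)\n", if (npos) dp / npos else 0))
})

#' Summary of a classified SNP trio table
#'
#' Counts of SNP sites in each of the eight parent/parent/hybrid
#' zygosity classes, with the derived heterozygosity metrics: per-variety
#' heterozygous (HT) counts and percentages, and the hybrid-centric
#' partition into novel heterozygosity (both parents homozygous, hybrid
#' heterozygous), maintained heterozygosity (hybrid heterozygous with at
#' least one heterozygous parent) and lost heterozygosity (hybrid
#' homozygous with at least one heterozygous parent).
#'
#' @slot classCounts integer(8), sites per trio class 1..8.
#' @slot total total classified sites.
#' @slot htCounts named numeric(3), HT sites per variety.
#' @slot htPercent named numeric(3), 100 * htCounts / total.
#' @slot novelHet,maintainedHet,lostHet derived hybrid metrics.
#' @slot nocallExcluded sites excluded because a variety had no call.
#' @slot nTranscripts number of transcripts bearing >= 1 classified site.
#' @slot snpsPerTranscript named numeric: mean, min, max sites per
#'   transcript (NA when transcript identities are unknown).
#' @seealso [summarizeTrio()], [heterozygosityReport()]
#' @export
setClass("TrioSummary",
    representation(
        classCounts = "integer",
        total = "integer",
        htCounts = "numeric",
        htPercent = "numeric",
        novelHet = "integer",
        maintainedHet = "integer",
        lostHet = "integer",
        nocallExcluded = "integer",
        nTranscripts = "integer",
        snpsPerTranscript = "numeric"
    )
)

setValidity("TrioSummary", function(object) {
    msg <- NULL
    cc <- object@classCounts
    if (length(cc) != 8L) msg <- c(msg, "classCounts must have length 8")
    if (object@total != sum(cc)) msg <- c(msg, "total must equal sum(classCounts)")
    ht <- unname(object@htCounts)
    exp_ht <- c(cc[2] + cc[4] + cc[5] + cc[8],
                cc[3] + cc[4] + cc[5] + cc[7],
                cc[1] + cc[2] + cc[3] + cc[4])
    if (!isTRUE(all.equal(ht, as.numeric(exp_ht))))
        msg <- c(msg, "htCounts inconsistent with classCounts")
    if (object@novelHet != cc[1] ||
        object@maintainedHet != cc[2] + cc[3] + cc[4] ||
        object@lostHet != cc[5] + cc[7] + cc[8])
        msg <- c(msg, "derived heterozygosity metrics inconsistent with classCounts")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "TrioSummary", function(object) {
    zyg <- .CLASS_ZYGOSITY
    v <- names(object@htCounts)
    cat("TrioSummary:", object@total, "classified SNP sites",
        sprintf("(%d excluded as no-call)\n", object@nocallExcluded))
    tab <- data.frame(Class = 1:8, zyg,
                      No.of.SNPs = object@classCounts,
                      check.names = FALSE)
    names(tab)[2:4] <- v
    print(tab, row.names = FALSE)
    cat(sprintf("  HT counts    : %s\n",
        paste(sprintf("%s=%d", v, as.integer(object@htCounts)), collapse = "  ")))
    cat(sprintf("  HT percent   : %s\n",
        paste(sprintf("%s=%.2f%%", v, object@htPercent), collapse = "  ")))
    cat(sprintf("  hybrid heterozygosity: novel=%d maintained=%d lost=%d\n",
        object@novelHet, object@maintainedHet, object@lostHet))
    if (!is.na(object@snpsPerTranscript["mean"]))
        cat(sprintf("  SNPs/transcript over %d transcripts: mean=%.1f range=%g-%g\n",
            object@nTranscripts, object@snpsPerTranscript["mean"],
            object@snpsPerTranscript["min"], object@snpsPerTranscript["max"]))
})
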