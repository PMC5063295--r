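test_that("variety tagging round-trips and validates labels", {
    reads <- Biostrings::DNAStringSet(c(r1 = "ACGT", r2 = "GGTT"))
    tagged <- tagReads(reads, "NEELAM")
    expect_identical(names(tagged), c("r1|NEELAM", "r2|NEELAM"))
    expect_identical(names(untagReads(tagged)), c("r1", "r2"))
    expect_identical(varietyOf(names(tagged)), c("NEELAM", "NEELAM"))
    expect_true(is.na(varietyOf("r1")))
    expect_error(tagReads(tagged, "X"), "already")
    expect_error(tagReads(reads, "A B"))
    expect_error(tagReads(reads, "A|B"))
})

aln_row <- function(qname, rname, pos, cigar, seq,
                    qual = strrep("I", nchar(seq)), flag = 0L) {
    data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
               cigar = cigar, seq = seq, qual = qual,
               unmapped = bitwAnd(flag, 4L) > 0L, stringsAsFactors = FALSE)
}

ref1 <- Biostrings::DNAStringSet(c(tx1 = strrep("ACGTT", 4)))  # 20 bp

test_that("a perfect-match read piles depth 1 over its span", {
    aln <- aln_row("r1|P1", "tx1", 5L, "10M", substr(strrep("ACGTT", 4), 5, 14))
    pu <- buildPileup(aln, ref1, c("P1", "P2", "HYB"))
    d <- pu@data$tx1$depth
    expect_equal(colSums(d[, , 1]), c(rep(0, 4), rep(1, 10), rep(0, 6)))
    expect_equal(sum(d[, , 2:3]), 0)
})

test_that("overlapping varieties keep separate tallies", {
    s <- substr(strrep("ACGTT", 4), 5, 14)
    aln <- rbind(aln_row("r1|P1", "tx1", 5L, "10M", s),
                 aln_row("r2|HYB", "tx1", 5L, "10M", s))
    pu <- buildPileup(aln, ref1, c("P1", "P2", "HYB"))
    d <- pu@data$tx1$depth
    expect_equal(sum(d[, 10, 1]), 1)
    expect_equal(sum(d[, 10, 2]), 0)
    expect_equal(sum(d[, 10, 3]), 1)
})

test_that("deletions skip reference positions (4M2D4M covers 1-4 and 7-10)", {
    aln <- aln_row("r1|P1", "tx1", 1L, "4M2D4M", "ACGTACGT")
    pu <- buildPileup(aln, ref1, c("P1", "P2", "HYB"))
    cov <- colSums(pu@data$tx1$depth[, , 1])
    expect_equal(which(cov == 1), c(1:4, 7:10))
})

test_that("insertions and soft clips consume the read but not the reference", {
    aln <- aln_row("r1|P1", "tx1", 3L, "2S4M2I4M", "ACCGTTACGTAC")
    pu <- buildPileup(aln, ref1, c("P1", "P2", "HYB"))
    cov <- colSums(pu@data$tx1$depth[, , 1])
    expect_equal(which(cov == 1), 3:10)
    ## bases after the insertion come from the right part of the read
    expect_equal(sum(pu@data$tx1$depth), 8)
})

test_that("pileup depth conservation against CIGAR-placed bases", {
    sim <- simulateTrioExperiment(small_config(nTranscripts = 4L,
                                               snpSitesTotal = 10L))
    pu <- buildPileup(sim$alignments, sim$reference, sim$config@varieties)
    placed <- sum(nchar(sim$alignments$seq))  # all-M truth alignments
    piled <- sum(vapply(pu@data, function(d) sum(d$depth), 0))
    expect_equal(piled, placed)
})

test_that("pileup rejects unknown transcripts and untagged reads", {
    aln <- aln_row("r1|P1", "nope", 1L, "4M", "ACGT")
    expect_error(buildPileup(aln, ref1, c("P1", "P2", "HYB")), "unknown")
    aln <- aln_row("r1", "tx1", 1L, "4M", "ACGT")
    expect_error(buildPileup(aln, ref1, c("P1", "P2", "HYB")), "tag")
})

test_that("callSnps enforces the three stringency filters", {
    refSeq <- strrep("A", 30)
    ## depth 9 (pooled) at a variant position -> not emitted
    pu <- make_pileup(refSeq, snp_column(10, "A", "G",
        list(c(3, 2), c(2, 0), c(1, 1))))
    expect_equal(nrow(callSnps(pu)), 0L)
    expect_equal(attr(callSnps(pu), "dropCounts")[["low_depth"]], 1L)
    ## depth 12 but mean quality 24.9 -> not emitted
    pu <- make_pileup(refSeq, snp_column(10, "A", "G",
        list(c(4, 2), c(3, 0), c(2, 1)), qual = 24.9))
    expect_equal(nrow(callSnps(pu)), 0L)
    expect_equal(attr(callSnps(pu), "dropCounts")[["low_avg_quality"]], 1L)
    ## same depths at quality 25 -> emitted
    pu <- make_pileup(refSeq, snp_column(10, "A", "G",
        list(c(4, 2), c(3, 0), c(2, 1)), qual = 25))
    out <- callSnps(pu)
    expect_equal(nrow(out), 1L)
    expect_equal(out$ref, "A")
    expect_equal(out$alt, "G")
    expect_equal(out$P1_altDepth, 2L)
    ## a variety with counts {A:9, G:1}: G unsupported there
    pu <- make_pileup(refSeq, snp_column(10, "A", "G",
        list(c(9, 1), c(5, 0), c(5, 0))))
    expect_equal(nrow(callSnps(pu)), 0L)
    ## three alleles each supported in one variety -> multi-allelic drop
    pu <- make_pileup(refSeq, c(
        snp_column(10, "A", "C", list(c(5, 4), c(0, 0), c(0, 0))),
        list(list(pos = 10, variety = "P1", base = "T", n = 3, qual = 30))))
    out <- callSnps(pu)
    expect_equal(nrow(out), 0L)
    expect_equal(attr(out, "dropCounts")[["multiallelic"]], 1L)
})

test_that("homozygous-variant and ref-unsupported sites are reported deterministically", {
    refSeq <- strrep("A", 30)
    ## all varieties homozygous for the same alt allele
    pu <- make_pileup(refSeq, snp_column(10, "A", "G",
        list(c(0, 10), c(0, 10), c(0, 10))))
    out <- callSnps(pu)
    expect_equal(nrow(out), 1L)
    expect_equal(out$ref, "A")
    expect_equal(out$alt, "G")
    expect_equal(out$P1_refDepth, 0L)
    ## two supported non-reference alleles: lexicographically smaller on
    ## the ref side, original reference base kept alongside
    pu <- make_pileup(refSeq, snp_column(10, "T", "G",
        list(c(6, 5), c(6, 0), c(0, 5))))
    out <- callSnps(pu)
    expect_equal(nrow(out), 1L)
    expect_equal(out$ref, "G")
    expect_equal(out$alt, "T")
    expect_equal(out$ref_base, "A")
})

test_that("emitted sites always satisfy the filters", {
    sim <- simulateTrioExperiment(small_config(seed = 33L,
                                               errorRate = 0.01))
    pu <- buildPileup(sim$alignments, sim$reference, sim$config@varieties)
    flt <- SNPFilters()
    out <- callSnps(pu, flt)
    expect_true(all(out$total_depth >= flt@minTotalDepth))
    expect_true(all(out$avg_qual >= flt@minAvgBaseQual))
    expect_true(all(out$ref != out$alt))
})
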