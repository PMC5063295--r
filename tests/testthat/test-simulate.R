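test_that("the simulator is deterministic for a fixed seed", {
    a <- simulateTrioExperiment(small_config())
    b <- simulateTrioExperiment(small_config())
    expect_identical(as.character(a$reference), as.character(b$reference))
    expect_identical(a$truth, b$truth)
    expect_identical(a$alignments$seq, b$alignments$seq)
    ## stage-level determinism with an explicit seed
    r1 <- simulateReference(small_config(), seed = 5L)
    r2 <- simulateReference(small_config(), seed = 5L)
    expect_identical(as.character(r1$reference), as.character(r2$reference))
    expect_identical(r1$ssrTruth, r2$ssrTruth)
})

test_that("ssrProb 0 embeds nothing; embedded SSRs are recovered by the miner", {
    none <- simulateReference(small_config(ssrProb = 0), seed = 2L)
    expect_equal(nrow(none$ssrTruth), 0L)
    some <- simulateReference(small_config(nTranscripts = 30L, ssrProb = 1),
                              seed = 3L)
    expect_equal(nrow(some$ssrTruth), 30L)
    found <- ssrTable(findSSRs(some$reference))
    for (i in seq_len(nrow(some$ssrTruth))) {
        tr <- some$ssrTruth[i, ]
        ## random flank bases can extend the tract by a partial unit and
        ## shift the maximal whole-unit window, so match by overlap
        hit <- found[found$transcript_id == tr$transcript_id &
                     found$start <= tr$end & found$end >= tr$start, ]
        expect_equal(nrow(hit), 1L, info = tr$transcript_id)
        expect_equal(hit$canonical_motif, canonicalMotif(tr$motif),
                     info = tr$transcript_id)
        expect_gte(hit$repeat_count, tr$repeat_count)
    }
})

test_that("truth sites keep read-length spacing and stay off the ends", {
    cfg <- small_config(nTranscripts = 12L, snpSitesTotal = 60L)
    sim <- simulateTrioExperiment(cfg)
    rl <- cfg@readLen
    lens <- setNames(Biostrings::width(sim$reference), names(sim$reference))
    expect_equal(nrow(sim$truth), 60L)
    for (tx in unique(sim$truth$transcript_id)) {
        p <- sort(sim$truth$pos[sim$truth$transcript_id == tx])
        expect_true(all(p >= rl & p <= lens[[tx]] - rl + 1L))
        if (length(p) > 1L) expect_true(all(diff(p) >= rl))
    }
})

test_that("direct-mode genotypes are consistent with their class", {
    cfg <- small_config(snpSitesTotal = 200L, nTranscripts = 35L)
    sim <- simulateTrioExperiment(cfg)
    v <- cfg@varieties
    ## class column equals classifyTrio applied to the truth zygosities
    expect_equal(sim$truth$class,
                 classifyTrio(sim$truth[[paste0("zyg_", v[1])]],
                              sim$truth[[paste0("zyg_", v[2])]],
                              sim$truth[[paste0("zyg_", v[3])]]))
    ## every site carries the alt on at least one haplotype
    gts <- do.call(paste, sim$truth[paste0("gt_", v)])
    hasAlt <- mapply(function(g, a) grepl(a, g, fixed = TRUE), gts,
                     sim$truth$alt)
    expect_true(all(hasAlt))
    ## class-1 sites have contrasting homozygous parents
    c1 <- sim$truth[sim$truth$class == 1L, ]
    expect_true(all(c1[[paste0("gt_", v[1])]] != c1[[paste0("gt_", v[2])]]))
})

test_that("single-class proportions force the drawn pattern", {
    cfg <- small_config(snpSitesTotal = 50L,
                        classProportions = c(1, rep(0, 7)))
    sim <- simulateTrioExperiment(cfg)
    expect_true(all(sim$truth$class == 1L))
})

test_that("mendelian hybrids inherit one allele from each parent", {
    cfg <- small_config(mode = "mendelian", snpSitesTotal = 150L,
                        nTranscripts = 30L)
    sim <- simulateTrioExperiment(cfg)
    v <- cfg@varieties
    split_gt <- function(g) strsplit(g, "/", fixed = TRUE)
    p1 <- split_gt(sim$truth[[paste0("gt_", v[1])]])
    p2 <- split_gt(sim$truth[[paste0("gt_", v[2])]])
    hyb <- split_gt(sim$truth[[paste0("gt_", v[3])]])
    ok <- mapply(function(a, b, h) {
        (h[1] %in% a && h[2] %in% b) || (h[1] %in% b && h[2] %in% a)
    }, p1, p2, hyb)
    expect_true(all(ok))
    ## no hybrid allele absent from both parents
    unionOk <- mapply(function(a, b, h) all(h %in% c(a, b)), p1, p2, hyb)
    expect_true(all(unionOk))
})

test_that("direct-mode class frequencies match the configured proportions", {
    ## multinomial goodness of fit at the target proportions
    cfg <- SimConfig(nTranscripts = 120L, lengthRange = c(1100L, 1300L),
                     snpSitesTotal = 2500L, coveragePerVariety = 0,
                     errorRate = 0, seed = 17L, ssrProb = 0)
    set.seed(cfg@seed)
    ref <- simulateReference(cfg)
    truth <- simulateTrioGenotypes(cfg, ref$reference)
    obs <- table(factor(truth$class, levels = 1:8))
    gof <- suppressWarnings(
        stats::chisq.test(obs, p = cfg@classProportions))
    expect_gt(gof$p.value, 0.01)
})

test_that("read counts follow the coverage arithmetic", {
    cfg <- small_config(nTranscripts = 5L, snpSitesTotal = 10L)
    sim <- simulateTrioExperiment(cfg)
    lens <- setNames(Biostrings::width(sim$reference), names(sim$reference))
    for (v in cfg@varieties) {
        aln <- sim$alignments[varietyOf(sim$alignments$qname) == v, ]
        cnt <- table(aln$rname)
        for (tx in names(cnt)) {
            expected <- cfg@coveragePerVariety * lens[[tx]] / cfg@readLen
            expect_lte(abs(cnt[[tx]] - expected), 1)
        }
    }
    ## zero coverage gives empty read sets
    empty <- simulateTrioExperiment(small_config(coveragePerVariety = 0))
    expect_true(all(vapply(empty$reads, length, 0L) == 0L))
})

test_that("error-free pileups reproduce the truth genotypes exactly", {
    sim <- simulateTrioExperiment(small_config(seed = 55L))
    pu <- buildPileup(sim$alignments, sim$reference, sim$config@varieties)
    v <- sim$config@varieties
    for (i in seq_len(nrow(sim$truth))) {
        tr <- sim$truth[i, ]
        d <- pu@data[[tr$transcript_id]]
        for (vi in seq_along(v)) {
            gt <- strsplit(tr[[paste0("gt_", v[vi])]], "/")[[1]]
            bases <- c("A", "C", "G", "T")
            piled <- bases[d$depth[, tr$pos, vi] > 0L]
            expect_setequal(piled, unique(gt))
        }
    }
})

test_that("truth tables round-trip through the TSV writer", {
    sim <- simulateTrioExperiment(small_config(nTranscripts = 4L,
                                               snpSitesTotal = 8L))
    p <- withr::local_tempfile(fileext = ".tsv")
    writeTruth(sim$truth, p)
    back <- readTsv(p)
    expect_equal(back, sim$truth)
    writeTruth(sim$truth[0, ], p)
    expect_equal(length(readLines(p)), 1L)
})

test_that("simulation output files are written where requested", {
    outdir <- withr::local_tempdir()
    sim <- simulateTrioExperiment(small_config(nTranscripts = 3L,
                                               snpSitesTotal = 6L), outdir)
    files <- list.files(outdir)
    expect_true(all(c("ref.fasta", "truth.sam", "truth_sites.tsv",
                      "truth_ssrs.tsv") %in% files))
    expect_true(all(paste0(tolower(sim$config@varieties), ".fastq") %in%
                    files))
    ## the FASTQ is valid Phred+33 with the configured constant quality
    rd <- readReads(file.path(outdir, "neelam.fastq"))
    expect_true(all(unlist(readQualities(rd)) == sim$config@baseQuality))
})
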