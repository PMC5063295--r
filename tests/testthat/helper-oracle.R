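## Independent oracles and small fixture builders shared across tests.

suppressPackageStartupMessages({
    library(Biostrings)
    library(GenomicRanges)
})

## ---- brute-force SSR oracle -------------------------------------------
## Independent route: perl regex backreference matching finds maximal
## whole-unit tandem runs; filtering rules are re-stated from scratch.

oracle_is_primitive <- function(m) {
    k <- nchar(m)
    divs <- seq_len(max(k - 1L, 0L))
    divs <- divs[k %% divs == 0L]
    !any(vapply(divs, function(d)
        identical(m, strrep(substr(m, 1, d), k / d)), TRUE))
}

oracle_find_ssrs <- function(seq, minrep = c(`2` = 6L, `3` = 5L, `4` = 5L,
                                             `5` = 5L, `6` = 5L)) {
    hits <- list()
    for (k in as.integer(names(minrep))) {
        pat <- sprintf("([ACGT]{%d})\\1+", k)
        m <- gregexpr(pat, seq, perl = TRUE)[[1]]
        if (m[1] == -1L) next
        lens <- attr(m, "match.length")
        for (i in seq_along(m)) {
            count <- lens[i] %/% k
            motif <- substr(seq, m[i], m[i] + k - 1L)
            if (count < minrep[[as.character(k)]]) next
            if (!oracle_is_primitive(motif)) next
            hits[[length(hits) + 1L]] <- data.frame(
                start = m[i], end = m[i] + count * k - 1L,
                motif = motif, unitSize = k, repeatCount = count,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(hits))
        return(data.frame(start = integer(), end = integer(),
                          motif = character(), unitSize = integer(),
                          repeatCount = integer(), stringsAsFactors = FALSE))
    df <- do.call(rbind, hits)
    ## overlap rule, restated: longer wins, ties leftmost, then smaller unit
    df <- df[order(-(df$end - df$start + 1L), df$start, df$unitSize), ]
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
        if (!keep[i]) next
        if (i < nrow(df)) {
            later <- (i + 1L):nrow(df)
            ov <- df$start[later] <= df$end[i] & df$end[later] >= df$start[i]
            keep[later][ov] <- FALSE
        }
    }
    df <- df[keep, ]
    df[order(df$start), , drop = FALSE]
}

## ---- canonical motif oracle -------------------------------------------
## enumerate a motif's full equivalence class by brute force

oracle_motif_class <- function(m) {
    rc <- function(s) {
        chartr("ACGT", "TGCA",
               paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    }
    rots <- function(s) {
        k <- nchar(s); d <- paste0(s, s)
        vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), "")
    }
    sort(unique(c(rots(m), rots(rc(m)))))
}

all_primitive_motifs <- function(k) {
    grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k))
    motifs <- apply(grid, 1L, paste, collapse = "")
    motifs[vapply(motifs, oracle_is_primitive, TRUE)]
}

## ---- random sequences --------------------------------------------------

random_dna <- function(n, len, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), "")
}

## ---- hand-built pileups ------------------------------------------------
## construct a TrioPileup directly from per-variety base/quality columns:
## columns is a list of lists: list(pos=, variety=, base=, n=, qual=)

make_pileup <- function(refSeq, columns,
                        varieties = c("P1", "P2", "HYB"),
                        transcript = "tx1") {
    L <- nchar(refSeq)
    depth <- array(0L, dim = c(4L, L, length(varieties)))
    qual <- array(0, dim = c(4L, L, length(varieties)))
    bidx <- function(b) match(b, c("A", "C", "G", "T"))
    for (col in columns) {
        v <- match(col$variety, varieties)
        b <- bidx(col$base)
        depth[b, col$pos, v] <- depth[b, col$pos, v] + col$n
        qual[b, col$pos, v] <- qual[b, col$pos, v] + col$n * col$qual
    }
    data <- list(list(depth = depth, qual = qual,
                      ref = bidx(strsplit(refSeq, "")[[1]])))
    names(data) <- transcript
    new("TrioPileup", varieties = varieties, data = data, nSkipped = 0L)
}

## shorthand for a biallelic column across the three varieties
snp_column <- function(pos, ref, alt, depths, qual = 30) {
    cols <- list()
    varieties <- c("P1", "P2", "HYB")
    for (i in 1:3) {
        d <- depths[[i]]  # c(refN, altN)
        if (d[1] > 0) cols[[length(cols) + 1L]] <-
            list(pos = pos, variety = varieties[i], base = ref,
                 n = d[1], qual = qual)
        if (d[2] > 0) cols[[length(cols) + 1L]] <-
            list(pos = pos, variety = varieties[i], base = alt,
                 n = d[2], qual = qual)
    }
    cols
}

## small deterministic sim config for fast tests (overridable defaults)
small_config <- function(...) {
    args <- utils::modifyList(
        list(nTranscripts = 8L, lengthRange = c(400L, 600L),
             snpSitesTotal = 40L, coveragePerVariety = 30,
             errorRate = 0, seed = 101L, ssrProb = 0.6),
        list(...))
    do.call(SimConfig, args)
}

table3_counts <- c(6831, 4158, 2049, 1354, 2061, 1154, 1270, 3429)
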