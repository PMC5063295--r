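#' Simulate a reference transcript set with embedded SSRs
#'
#' Draws random A/C/G/T transcripts with lengths uniform in
#' `lengthRange`; with probability `ssrProb` a transcript receives one
#' embedded perfect SSR (unit size uniform over 2--6, a random
#' primitive motif, reiterations sampled to straddle the Type I
#' boundary) at a position leaving at least 60 bp of flank on each
#' side. The exact embedded spans are recorded as truth.
#'
#' @param config a [SimConfig].
#' @param seed optional integer; when given, seeds the RNG so the call
#'   is reproducible in isolation. Inside
#'   [simulateTrioExperiment()] the seed is set once for the whole
#'   experiment.
#' @return a list with `reference` (named [Biostrings::DNAStringSet])
#'   and `ssrTruth` (data.frame: transcript_id, start, end, motif,
#'   unit_size, repeat_count).
#' @export
simulateReference <- function(config, seed = NULL) {
    stopifnot(is(config, "SimConfig"))
    if (!is.null(seed)) set.seed(seed)
    maxSSRLen <- 6L * 12L
    if (config@lengthRange[1] < maxSSRLen + 120L)
        stop("shortest transcripts cannot host an SSR with 60 bp flanks; ",
             "increase lengthRange[1] to at least ", maxSSRLen + 120L)
    n <- config@nTranscripts
    lens <- sample(config@lengthRange[1]:config@lengthRange[2], n,
                   replace = TRUE)
    ids <- sprintf("TX%05d", seq_len(n))
    seqs <- vapply(lens, function(L)
        paste(sample(.BASES, L, replace = TRUE), collapse = ""), "")
    hasSSR <- stats::runif(n) < config@ssrProb
    truth <- list()
    for (i in which(hasSSR)) {
        k <- sample(2:6, 1L)
        motif <- .randomPrimitiveMotif(k)
        ## reiterations straddle the Type I boundary (20 bp tract)
        minrep <- if (k == 2L) 6L else 5L
        reps <- sample(minrep:(minrep + 7L), 1L)
        tract <- strrep(motif, reps)
        L <- lens[i]
        tlen <- nchar(tract)
        start <- sample(61:(L - tlen - 59L), 1L)
        seqs[i] <- paste0(substr(seqs[i], 1L, start - 1L), tract,
                          substr(seqs[i], start + tlen, L))
        truth[[length(truth) + 1L]] <- data.frame(
            transcript_id = ids[i], start = start,
            end = start + tlen - 1L, motif = motif, unit_size = k,
            repeat_count = reps, stringsAsFactors = FALSE)
    }
    ssrTruth <- if (length(truth)) do.call(rbind, truth) else
        data.frame(transcript_id = character(), start = integer(),
                   end = integer(), motif = character(),
                   unit_size = integer(), repeat_count = integer(),
                   stringsAsFactors = FALSE)
    reference <- Biostrings::DNAStringSet(seqs)
    names(reference) <- ids
    list(reference = reference, ssrTruth = ssrTruth)
}

.randomPrimitiveMotif <- function(k) {
    repeat {
        m <- paste(sample(.BASES, k, replace = TRUE), collapse = "")
        if (.isPrimitive(m)) return(m)
    }
}

#' Simulate diploid trio genotypes at biallelic sites
#'
#' Places `snpSitesTotal` sites on the transcripts, each at least
#' `readLen` from either end and no two sites within one read length
#' of each other (so a read overlaps at most one site). In `direct`
#' mode each site draws a trio class from `classProportions` and
#' genotypes are assigned uniformly among the allele configurations
#' consistent with that class's HM/HT pattern (both-parents-HM with a
#' heterozygous hybrid means contrasting parental homozygotes; an
#' all-homozygous trio is drawn among patterns where at least one
#' variety differs from the reference base, so the site remains a
#' detectable variant). In `mendelian` mode parental genotypes are
#' drawn with independent allele draws and the hybrid inherits one
#' allele from each parent; the class is recorded post hoc.
#'
#' @param config a [SimConfig].
#' @param reference named [Biostrings::DNAStringSet] from
#'   [simulateReference()].
#' @param seed optional integer seed (see [simulateReference()]).
#' @return a data.frame of truth sites: transcript_id, pos, ref, alt,
#'   `gt_<V>` genotype strings (`"A/G"` etc.), zygosity columns
#'   `zyg_<V>`, and `class` (1--8).
#' @export
simulateTrioGenotypes <- function(config, reference, seed = NULL) {
    stopifnot(is(config, "SimConfig"))
    if (!is.null(seed)) set.seed(seed)
    rl <- config@readLen
    lens <- Biostrings::width(reference)
    ids <- names(reference)
    ## capacity per transcript: sites in [rl, L - rl + 1] spaced >= rl
    lo <- rl
    hi <- lens - rl + 1L
    cap <- pmax(0L, (hi - lo) %/% rl + 1L)
    total <- config@snpSitesTotal
    if (sum(cap) < total)
        stop("too many SNP sites for the sequence space: capacity ",
             sum(cap), " < ", total)
    ## spread sites over transcripts proportionally to capacity
    nPer <- pmin(cap, stats::rmultinom(1L, total, cap / sum(cap))[, 1L])
    deficit <- total - sum(nPer)
    while (deficit > 0L) {
        room <- which(nPer < cap)
        add <- room[seq_len(min(deficit, length(room)))]
        nPer[add] <- nPer[add] + 1L
        deficit <- total - sum(nPer)
    }
    refChars <- as.character(reference)
    rows <- vector("list", sum(nPer > 0L))
    ri <- 0L
    for (i in which(nPer > 0L)) {
        k <- nPer[i]
        ## k sorted draws from the gap-reduced range, then re-spaced
        u <- sort(sample.int(hi[i] - lo + 1L - (k - 1L) * (rl - 1L), k))
        pos <- lo - 1L + u + (seq_len(k) - 1L) * (rl - 1L)
        refb <- substring(refChars[[i]], pos, pos)
        altb <- vapply(refb, function(b)
            sample(setdiff(.BASES, b), 1L), "", USE.NAMES = FALSE)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(transcript_id = ids[i], pos = pos,
                                 ref = refb, alt = altb,
                                 stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    n <- nrow(truth)
    if (config@mode == "direct") {
        cls <- sample.int(8L, n, replace = TRUE,
                          prob = config@classProportions)
        gt <- t(vapply(cls, .directGenotypes, integer(6L)))
    } else {
        gt <- matrix(0L, n, 6L)
        for (i in seq_len(n)) gt[i, ] <- .mendelianGenotypes()
        cls <- NA_integer_
    }
    ## gt columns: p1a1 p1a2 p2a1 p2a2 hyb1 hyb2 with 0 = ref, 1 = alt
    al <- function(j) ifelse(gt[, j] == 0L, truth$ref, truth$alt)
    v <- config@varieties
    truth[[paste0("gt_", v[1])]] <- paste(al(1), al(2), sep = "/")
    truth[[paste0("gt_", v[2])]] <- paste(al(3), al(4), sep = "/")
    truth[[paste0("gt_", v[3])]] <- paste(al(5), al(6), sep = "/")
    zyg <- function(a, b) ifelse(gt[, a] == gt[, b], "HM", "HT")
    truth[[paste0("zyg_", v[1])]] <- zyg(1, 2)
    truth[[paste0("zyg_", v[2])]] <- zyg(3, 4)
    truth[[paste0("zyg_", v[3])]] <- zyg(5, 6)
    truth$class <- classifyTrio(truth[[paste0("zyg_", v[1])]],
                                truth[[paste0("zyg_", v[2])]],
                                truth[[paste0("zyg_", v[3])]])
    if (config@mode == "direct" && !identical(truth$class, cls))
        stop("internal error: drawn classes inconsistent with genotypes")
    truth
}

## uniform draw among allele configurations consistent with a class's
## HM/HT pattern; 0 = ref allele, 1 = alt allele
.directGenotypes <- function(cls) {
    patt <- .CLASS_ZYGOSITY[cls, ]
    het <- c(0L, 1L)
    repeat {
        g <- integer(6L)
        for (j in 1:3) {
            z <- patt[[j]]
            idx <- c(2L * j - 1L, 2L * j)
            if (z == "HT") g[idx] <- het
            else g[idx] <- rep(sample(0:1, 1L), 2L)
        }
        ## class 1 pattern (HM,HM,HT): hybrid carries both alleles, so
        ## parents must be contrasting homozygotes
        if (cls == 1L && g[1] == g[3]) next
        if (any(g == 1L)) return(g)
    }
}

## parents drawn with independent Bernoulli(1/2) alleles; hybrid takes
## one allele from each parent; redrawn until the site carries the alt
.mendelianGenotypes <- function() {
    repeat {
        p1 <- sample(0:1, 2L, replace = TRUE)
        p2 <- sample(0:1, 2L, replace = TRUE)
        hyb <- c(p1[sample(1:2, 1L)], p2[sample(1:2, 1L)])
        g <- c(p1, p2, hyb)
        if (any(g == 1L)) return(g)
    }
}

#' Simulate per-variety reads with a truth alignment table
#'
#' For each variety and each of its two haplotypes per transcript,
#' draws reads of `readLen` bases at uniform start positions to reach
#' `coveragePerVariety` (the expected read count per transcript and
#' variety is `coverage * length / readLen`, deterministic up to
#' rounding). Each read copies its haplotype (truth SNP alleles
#' substituted into the reference), then per-base substitution errors
#' are applied at `errorRate` (to a uniformly chosen different base);
#' qualities are constant at `baseQuality`. Read ids carry the
#' `"|VARIETY"` tag; the truth alignment table records the true origin
#' with an all-M CIGAR.
#'
#' @param config a [SimConfig].
#' @param reference named [Biostrings::DNAStringSet].
#' @param truth truth-site table from [simulateTrioGenotypes()].
#' @param seed optional integer seed (see [simulateReference()]).
#' @return a list with `reads` (named list of
#'   [Biostrings::QualityScaledDNAStringSet], one per variety) and
#'   `alignments` (data.frame in [readSAM()] layout).
#' @export
simulateReads <- function(config, reference, truth, seed = NULL) {
    stopifnot(is(config, "SimConfig"))
    if (!is.null(seed)) set.seed(seed)
    rl <- config@readLen
    lens <- Biostrings::width(reference)
    ids <- names(reference)
    refChars <- as.character(reference)
    qualChar <- rawToChar(as.raw(config@baseQuality + 33L))
    varieties <- config@varieties
    readsOut <- list()
    alnOut <- list()
    for (vi in seq_along(varieties)) {
        v <- varieties[vi]
        gtCol <- paste0("gt_", v)
        truthByTx <- split(truth, truth$transcript_id)
        accSeq <- list(); accStart <- list(); accTx <- list()
        for (i in seq_along(ids)) {
            L <- lens[i]
            nTotal <- round(config@coveragePerVariety * L / rl)
            if (nTotal < 1L) next
            nHap <- c(ceiling(nTotal / 2), floor(nTotal / 2))
            tsites <- truthByTx[[ids[i]]]
            if (is.null(tsites))
                tsites <- truth[0L, , drop = FALSE]
            haps <- .haplotypes(refChars[[i]], tsites, gtCol)
            for (h in 1:2) {
                if (nHap[h] < 1L) next
                starts <- sample.int(L - rl + 1L, nHap[h], replace = TRUE)
                accSeq[[length(accSeq) + 1L]] <-
                    substring(haps[h], starts, starts + rl - 1L)
                accStart[[length(accStart) + 1L]] <- starts
                accTx[[length(accTx) + 1L]] <- rep(ids[i], nHap[h])
            }
        }
        allSeq <- unlist(accSeq, use.names = FALSE) %||% character(0)
        allStart <- unlist(accStart, use.names = FALSE) %||% integer(0)
        allTx <- unlist(accTx, use.names = FALSE) %||% character(0)
        nReads <- length(allSeq)
        if (nReads && config@errorRate > 0) {
            allSeq <- .applyErrors(allSeq, rl, config@errorRate)
        }
        rid <- sprintf("%s_r%06d|%s", allTx, seq_len(max(nReads, 0L)), v)
        if (nReads) {
            qs <- Biostrings::QualityScaledDNAStringSet(
                Biostrings::DNAStringSet(allSeq),
                Biostrings::PhredQuality(rep(strrep(qualChar, rl), nReads)))
            names(qs) <- rid
        } else {
            qs <- Biostrings::QualityScaledDNAStringSet(
                Biostrings::DNAStringSet(character(0)),
                Biostrings::PhredQuality(character(0)))
        }
        readsOut[[v]] <- qs
        alnOut[[v]] <- data.frame(
            qname = rid[seq_len(nReads)], flag = rep(0L, nReads),
            rname = allTx, pos = allStart,
            cigar = rep(paste0(rl, "M"), nReads),
            seq = allSeq, qual = rep(strrep(qualChar, rl), nReads),
            unmapped = rep(FALSE, nReads), stringsAsFactors = FALSE)
    }
    alignments <- do.call(rbind, alnOut)
    rownames(alignments) <- NULL
    attr(alignments, "skipped") <- 0L
    list(reads = readsOut, alignments = alignments)
}

## the two haplotype sequences of one variety on one transcript
.haplotypes <- function(refSeq, tsites, gtCol) {
    h1 <- h2 <- refSeq
    if (nrow(tsites)) {
        alleles <- strsplit(tsites[[gtCol]], "/", fixed = TRUE)
        a1 <- vapply(alleles, `[[`, "", 1L)
        a2 <- vapply(alleles, `[[`, "", 2L)
        for (j in seq_len(nrow(tsites))) {
            p <- tsites$pos[j]
            substr(h1, p, p) <- a1[j]
            substr(h2, p, p) <- a2[j]
        }
    }
    c(h1, h2)
}

## per-base substitution errors over a vector of equal-length reads,
## applied through one concatenated byte vector for speed
.applyErrors <- function(reads, rl, rate) {
    n <- length(reads)
    nErr <- stats::rbinom(n, rl, rate)
    tot <- sum(nErr)
    if (tot == 0L) return(reads)
    big <- charToRaw(paste(reads, collapse = ""))
    readIdx <- rep.int(seq_len(n), nErr)
    posIn <- unlist(lapply(nErr[nErr > 0L], function(k)
        sample.int(rl, k)), use.names = FALSE)
    at <- (readIdx - 1L) * rl + posIn
    cur <- as.integer(big[at])
    code <- integer(256L)
    code[as.integer(charToRaw(paste(.BASES, collapse = "")))] <- 1:4
    ## the three alternatives of each base, indexed by (base, draw)
    altMat <- matrix(charToRaw(paste(c("C", "G", "T", "A", "G", "T",
                                       "A", "C", "T", "A", "C", "G"),
                                     collapse = "")),
                     nrow = 4L, byrow = TRUE)
    big[at] <- altMat[cbind(code[cur], sample.int(3L, tot, replace = TRUE))]
    substring(rawToChar(big), (seq_len(n) - 1L) * rl + 1L,
              seq_len(n) * rl)
}

#' Write a truth-site table
#'
#' @param truth truth-site table from [simulateTrioGenotypes()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
    writeTsv(truth, path)
}

#' Run the full synthetic trio experiment
#'
#' Seeds the RNG once from `config@seed` and chains
#' [simulateReference()], [simulateTrioGenotypes()] and
#' [simulateReads()]. With `outdir` set, writes `ref.fasta`, one FASTQ
#' per variety, `truth.sam`, `truth_sites.tsv` and `truth_ssrs.tsv`.
#'
#' @param config a [SimConfig].
#' @param outdir optional output directory (created if needed).
#' @return a list with `reference`, `ssrTruth`, `truth`, `reads`,
#'   `alignments` and `config`.
#' @export
simulateTrioExperiment <- function(config = SimConfig(), outdir = NULL) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@seed)
    ref <- simulateReference(config)
    truth <- simulateTrioGenotypes(config, ref$reference)
    rd <- simulateReads(config, ref$reference, truth)
    out <- list(reference = ref$reference, ssrTruth = ref$ssrTruth,
                truth = truth, reads = rd$reads,
                alignments = rd$alignments, config = config)
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        writeTranscripts(out$reference, file.path(outdir, "ref.fasta"))
        for (v in names(out$reads))
            writeReads(out$reads[[v]],
                       file.path(outdir, paste0(tolower(v), ".fastq")))
        writeSAM(out$alignments, out$reference,
                 file.path(outdir, "truth.sam"))
        writeTruth(out$truth, file.path(outdir, "truth_sites.tsv"))
        writeTsv(out$ssrTruth, file.path(outdir, "truth_ssrs.tsv"))
    }
    out
}
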