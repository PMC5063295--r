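#' Read a pipeline configuration file
#'
#' YAML key/value configuration for [runPipeline()]. Recognized
#' top-level keys: `reference` (FASTA path), `alignments` (SAM path),
#' `varieties` (3 labels: parent, parent, hybrid), `seed`, `simulate`
#' (logical; when TRUE the inputs are generated by
#' [simulateTrioExperiment()]), and optional blocks `ssr`, `primers`,
#' `snp`, `sim` overriding the defaults of [SSRCriteria()],
#' [PrimerConstraints()], [SNPFilters()] and [SimConfig()].
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path)
    yaml::read_yaml(path)
}

.applyOverrides <- function(constructor, overrides) {
    if (is.null(overrides)) return(constructor())
    do.call(constructor, overrides)
}

#' Run the whole marker pipeline
#'
#' Chains the stages end to end: (optional) simulation, SSR mining,
#' compound marking and filtering, primer design, pileup construction,
#' SNP calling, trio classification and summarization. Writes
#' `ssr_loci.tsv`, `primers.tsv`, `snp_sites.tsv`, `snp_sites.vcf`,
#' `trio_table.tsv`, `trio_summary.tsv` and a `manifest.yaml`
#' recording every threshold applied and the per-stage drop counts.
#' Idempotent for a fixed seed.
#'
#' @param config a list as returned by [readPipelineConfig()], or a
#'   path to a YAML config file.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results
#'   (`ssrLoci`, `primers`, `snpSites`, `trioTable`, `summary`,
#'   `manifest`).
#' @export
runPipeline <- function(config, outdir) {
    if (is.character(config)) config <- readPipelineConfig(config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    criteria <- .applyOverrides(SSRCriteria, config$ssr)
    constraints <- .applyOverrides(PrimerConstraints, config$primers)
    filters <- .applyOverrides(SNPFilters, config$snp)
    varieties <- config$varieties %||% c("NEELAM", "DASHEHARI", "AMRAPALI")
    manifest <- list(
        package_version = as.character(utils::packageVersion("triohet")),
        varieties = varieties,
        seed = config$seed %||% NA,
        parameters = list(
            ssr = list(minRepeats = as.list(criteria@minRepeats),
                       minTotalLen = criteria@minTotalLen,
                       type1MinLen = criteria@type1MinLen,
                       compoundMaxGap = criteria@compoundMaxGap,
                       unitSizes = criteria@unitSizes),
            primers = list(lenMin = constraints@lenMin,
                           lenMax = constraints@lenMax,
                           productMin = constraints@productMin,
                           productMax = constraints@productMax,
                           tmTarget = constraints@tmTarget,
                           gcMin = constraints@gcMin,
                           gcMax = constraints@gcMax,
                           gcOpt = constraints@gcOpt),
            snp = list(minTotalDepth = filters@minTotalDepth,
                       minAvgBaseQual = filters@minAvgBaseQual,
                       minAlleleReads = filters@minAlleleReads)))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    if (isTRUE(config$simulate)) {
        simArgs <- config$sim %||% list()
        if (!is.null(config$seed)) simArgs$seed <- config$seed
        if (!is.null(varieties)) simArgs$varieties <- varieties
        simcfg <- do.call(SimConfig, simArgs)
        sim <- stage("simulate", simulateTrioExperiment(
            simcfg, outdir = file.path(outdir, "sim")))
        reference <- sim$reference
        alignments <- sim$alignments
        manifest$alignment_source <- "simulated truth SAM"
    } else {
        if (is.null(config$reference))
            stop("config missing 'reference' (FASTA path)")
        if (!file.exists(config$reference))
            stop("reference not found: ", config$reference)
        reference <- stage("read-reference",
                           readTranscripts(config$reference))
        if (is.null(config$alignments))
            stop("config missing 'alignments' (SAM path)")
        if (!file.exists(config$alignments))
            stop("alignments not found: ", config$alignments)
        alignments <- stage("read-alignments", readSAM(config$alignments))
        manifest$alignment_source <- config$alignments
    }
    ## SSR mining
    loci <- stage("mine-ssr", {
        l <- findSSRs(reference, criteria)
        l <- markCompound(l, criteria)
        l
    })
    retained <- stage("filter-ssr", filterLoci(loci, criteria))
    writeTsv(ssrTable(retained), file.path(outdir, "ssr_loci.tsv"))
    summ <- ssrSummary(retained, length(reference))
    writeTsv(summ$categories, file.path(outdir, "ssr_summary.tsv"))
    manifest$drop_counts$ssr <- list(
        found = length(loci),
        dropped = length(loci) - length(retained),
        retained = length(retained))
    ## primer design
    primers <- stage("design-primers",
                     designMarkerPrimers(reference, retained, constraints))
    writeTsv(primers, file.path(outdir, "primers.tsv"))
    manifest$drop_counts$primers <- list(
        designed = nrow(primers), no_valid_pair = attr(primers, "nFailed"))
    ## SNP calling
    pileup <- stage("build-pileup",
                    buildPileup(alignments, reference, varieties))
    sites <- stage("call-snps", callSnps(pileup, filters))
    writeSnpVcf(sites, varieties, file.path(outdir, "snp_sites.vcf"))
    manifest$drop_counts$snp <- as.list(attr(sites, "dropCounts"))
    manifest$drop_counts$alignments_skipped <- pileup@nSkipped
    ## trio classification
    trio <- stage("classify-trio", classifySnpTrio(sites, varieties, filters))
    writeTsv(trio, file.path(outdir, "snp_sites.tsv"))
    smry <- summarizeTrio(trio, varieties = varieties)
    rep <- heterozygosityReport(smry)
    writeTsv(rep$table, file.path(outdir, "trio_table.tsv"))
    writeTsv(rep$derived, file.path(outdir, "trio_summary.tsv"))
    manifest$drop_counts$trio_nocall_excluded <- smry@nocallExcluded
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
    invisible(list(ssrLoci = retained, primers = primers, snpSites = sites,
                   trioTable = trio, summary = smry, manifest = manifest))
}
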