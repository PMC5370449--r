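.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

.writeJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    path
}

#' Run the full analysis pipeline on a simulated study
#'
#' Generates a synthetic four-group methylome plus annotations, expression
#' and TG tables, writes them in their external formats (bismark-style
#' coverage, BED, TSV, JSON), reads them back, and runs every stage:
#' high-observation and coverage filters, 50-CpG binning, the four
#' pairwise DMR contrasts, the amelioration analysis with permutation
#' nulls, element-catalog enrichment of age-related DMRs, whole-gene-body
#' detection and methylation-expression coupling on the old-age diet
#' contrast, and the TG chain-length/saturation statistics. All outputs
#' are plain text and fully determined by the config seed, so two runs
#' with the same config produce identical files.
#'
#' @param config A [simConfig()] object.
#' @param outdir output directory (created).
#' @param nPerm permutations per scheme for the amelioration nulls.
#' @return Invisibly, a list with the main in-memory results (`bins`,
#'   `dmrs`, `amelioration`, `enrichment`, `wholegene`, `coupling`,
#'   `lipid`, `truth`) and the output `paths`.
#' @export
runPipeline <- function(config = simConfig(), outdir, nPerm = 50L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()

    ## ---- simulate and write inputs ----
    sim <- simulateMethylome(config)
    anno <- simulateAnnotations(config)
    de <- simulateExpression(sim$truth, seed = config$seed)
    tg <- simulateTGTable(seed = config$seed)
    paths$coverage <- writeCoverage(sim$counts, file.path(outdir, "coverage"))
    annoDir <- file.path(outdir, "annotations")
    dir.create(annoDir, showWarnings = FALSE)
    for (nm in names(anno))
        paths[[paste0("bed_", nm)]] <-
            writeBed(anno[[nm]], file.path(annoDir, paste0(nm, ".bed")))
    paths$de <- .writeTsv(de, file.path(outdir, "de_table.tsv"))
    paths$tg <- .writeTsv(tg$abundance, file.path(outdir, "tg_abundance.tsv"))
    paths$tg_samples <- .writeTsv(tg$samples,
                                  file.path(outdir, "tg_samples.tsv"))
    paths$truth <- .writeJson(sim$truth[c("regions", "genes")],
                              file.path(outdir, "ground_truth.json"))

    ## ---- read back, filter, bin ----
    groupMap <- setNames(as.character(sampleGroups(sim$counts)),
                         colnames(sim$counts))
    mc <- readCoverage(paths$coverage, groupMap)
    mc <- filterHighObservation(mc)
    merged <- filterMinCoverage(mergeReplicates(mc))
    bins <- makeBins(merged)
    paths$bins <- .writeTsv(
        cbind(data.frame(chrom = as.character(seqnames(rowRanges(bins))),
                         start = start(rowRanges(bins)),
                         end = end(rowRanges(bins)),
                         bin_id = rowData(bins)$bin_id),
              as.data.frame(assay(bins, "level"))),
        file.path(outdir, "bins.tsv"))

    ## ---- DMR contrasts ----
    dmrs <- lapply(setNames(nm = names(.CONTRASTS)),
                   function(ct) callDMRs(bins, ct))
    counts <- list()
    for (ct in names(dmrs)) {
        d <- dmrSet(dmrs[[ct]])
        paths[[paste0("dmr_", ct)]] <-
            .writeTsv(d, file.path(outdir, sprintf("dmrs_%s.tsv", ct)))
        if (nrow(d))
            writeBed(dmrRanges(d), file.path(outdir, sprintf("dmrs_%s.bed", ct)))
        counts[[ct]] <- list(n = nrow(d),
                             hyper = sum(d$direction == "hyper"),
                             hypo = sum(d$direction == "hypo"))
    }
    paths$dmr_summary <- .writeJson(counts,
                                    file.path(outdir, "dmr_summary.json"))

    ## ---- amelioration ----
    am <- ameliorationAnalysis(bins, dmrs$age_AL, nPerm = nPerm,
                               seed = config$seed)
    paths$amelioration <- .writeJson(
        list(fit_AL = am@fitAL, fit_DR = am@fitDR, sigma = am@sigma,
             cutoff = am@cutoff,
             n_ameliorated = sum(amelioratedDMRs(am)$ameliorated),
             perm_envelopes = if (nrow(am@perms)) lapply(
                 split(am@perms, am@perms$scheme), function(p)
                     lapply(p[c("slope_AL", "r_AL", "slope_DR", "r_DR")],
                            function(v) unname(quantile(v, c(0.025, 0.975)))))
                 else NULL),
        file.path(outdir, "amelioration.json"))
    paths$ameliorated <- .writeTsv(amelioratedDMRs(am),
                                   file.path(outdir, "ameliorated_dmrs.tsv"))
    paths$deltas <- .writeTsv(am@deltas, file.path(outdir, "bin_deltas.tsv"))

    ## ---- element enrichment of age-related DMRs ----
    proms <- buildPromoters(anno$genes)
    catalog <- buildChromatinElements(
        c(anno[c("H3K4me1", "H3K27ac", "H3K4me3", "H3K9ac", "H3K27me3",
                 "coChIP")], list(repeats = anno$repeats)),
        proms, anno$genes, anno$cgis)
    enr <- enrichCatalog(dmrRanges(dmrSet(dmrs$age_AL)),
                         rowRanges(bins), catalog)
    paths$enrichment <- .writeTsv(enr, file.path(outdir, "enrichment.tsv"))

    ## ---- gene-level analyses on the old-age diet contrast ----
    dmrWg <- callDMRs(bins, "diet_old", minDiff = 2.5)
    wg <- wholeGeneBodyGenes(dmrWg, bins, anno$genes, merged)
    paths$wholegene <- .writeTsv(wg, file.path(outdir, "wholegene.tsv"))
    cp <- methExprCorrelation(dmrs$diet_old, anno$genes, de)
    paths$coupling <- .writeJson(
        list(n_genes = nrow(cp$genes), quadrants = cp$quadrants,
             fisher_p = cp$fisher_p, r = cp$r,
             fisher_p_deg = cp$fisher_p_deg, r_deg = cp$r_deg),
        file.path(outdir, "coupling.json"))
    paths$coupling_genes <- .writeTsv(cp$genes,
                                      file.path(outdir, "coupling_genes.tsv"))

    ## ---- lipidomics ----
    rel <- normalizeTG(tg$abundance)
    lip <- list()
    smp <- tg$samples
    for (key in c("carbons", "double_bonds")) {
        agg <- aggregateBy(rel, key)
        paths[[paste0("tg_", key)]] <-
            .writeTsv(agg, file.path(outdir, sprintf("tg_%s.tsv", key)))
        grp <- smp$group[match(colnames(agg)[-1L], smp$sample)]
        paths[[paste0("tg_test_", key)]] <- .writeTsv(
            perCategoryTest(agg, grp),
            file.path(outdir, sprintf("tg_tests_%s.tsv", key)))
        iv <- if (key == "carbons") list(left = c(38, 52), right = c(54, 60))
              else list(low = c(0, 3), high = c(4, 12))
        dir1 <- if (key == "carbons") c("greater", "less")
                else c("less", "greater")  # DR: shorter chains, more double bonds
        for (age in c("young", "old")) {
            pair <- paste0(c("DR_", "AL_"), age)
            for (k in seq_along(iv))
                lip[[sprintf("%s_%s_%s", key, age, names(iv)[k])]] <-
                    intervalTest(agg, grp, pair[1], pair[2], iv[[k]],
                                 alternative = dir1[k])$p
        }
    }
    ia <- tgContentInteraction(smp$total, smp$age, smp$diet)
    lip$interaction_p <- ia["age:diet", "Pr(>F)"]
    paths$lipid <- .writeJson(lip, file.path(outdir, "lipid_tests.json"))

    invisible(list(bins = bins, dmrs = dmrs, amelioration = am,
                   enrichment = enr, wholegene = wg, coupling = cp,
                   lipid = lip, truth = sim$truth, paths = paths))
}

#' Match bins to planted ground-truth regions
#'
#' Utility for recovery statistics on simulated data: flags, for a set of
#' bin spans, which lie fully inside a planted region and which overlap
#' one at all.
#'
#' @param binGr `GRanges` of bin (or DMR) spans.
#' @param regions ground-truth region data.frame (`truth$regions`,
#'   optionally pre-filtered by class/sign).
#' @return data.frame with logicals `within` and `overlaps` per bin.
#' @export
matchPlanted <- function(binGr, regions) {
    if (is.null(regions) || !nrow(regions))
        return(data.frame(within = rep(FALSE, length(binGr)),
                          overlaps = rep(FALSE, length(binGr))))
    rg <- GRanges(regions$chrom, IRanges(regions$start, regions$end))
    data.frame(within = overlapsAny(binGr, rg, type = "within"),
               overlaps = overlapsAny(binGr, rg))
}
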