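test_that("simulation is byte-identical under a fixed seed", {
    cfg <- simConfig(nChroms = 1, nCpgsPerChrom = 3000, nAgeDMR = 4,
                     nDietDMR = 2, nGenes = 4, nWholeGene = 2, seed = 9)
    a <- simulateMethylome(cfg)
    b <- simulateMethylome(cfg)
    expect_identical(methCounts(a$counts), methCounts(b$counts))
    expect_identical(unmethCounts(a$counts), unmethCounts(b$counts))
    expect_identical(a$truth$regions, b$truth$regions)
    annoA <- simulateAnnotations(cfg)
    annoB <- simulateAnnotations(cfg)
    expect_identical(annoA, annoB)
    ## annotations and methylome share the same layout
    expect_identical(annoA$genes$gene_id, a$truth$genes$gene_id)
    expect_identical(GenomicRanges::start(annoA$genes), a$truth$genes$start)
})

test_that("config validation rejects out-of-range parameters", {
    expect_error(simConfig(islandFraction = 1.2), "islandFraction")
    expect_error(simConfig(dispersion = 1), "dispersion")
    expect_error(simConfig(effectRange = c(0.3, 0.1)), "effectRange")
    expect_error(simConfig(attenuationFactor = 2), "attenuationFactor")
    expect_error(simConfig(islandFraction = 1e-4), "island")
    ## plants that cannot fit on the chromosome
    expect_error(simulateMethylome(
        simConfig(nChroms = 1, nCpgsPerChrom = 600, nAgeDMR = 20,
                  islandFraction = 0)), "too small")
})

test_that("noise-free limit reproduces the group means", {
    cfg <- simConfig(nChroms = 1, nCpgsPerChrom = 800, islandFraction = 0,
                     nAgeDMR = 0, nDietDMR = 0, nGenes = 0, nWholeGene = 0,
                     dispersion = 0, depthMean = 10000, seed = 2)
    sim <- simulateMethylome(cfg)
    ## at pooled depth ~30000 every merged per-CpG level is within 1 point
    ## of the flat 85% baseline
    lv <- methylationLevel(mergeReplicates(sim$counts))
    expect_true(all(abs(lv - 85) < 1))
    expect_lt(mean(abs(methylationLevel(sim$counts) - 85)), 0.5)
})

test_that("overdispersion inflates replicate variance beyond binomial", {
    base <- list(nChroms = 1, nCpgsPerChrom = 600, islandFraction = 0,
                 nAgeDMR = 0, nDietDMR = 0, nGenes = 0, nWholeGene = 0,
                 depthMean = 30, seed = 5)
    v <- sapply(c(0, 0.2), function(rho) {
        sim <- simulateMethylome(do.call(simConfig, c(base, dispersion = rho)))
        lv <- methylationLevel(sim$counts)
        mean(apply(lv, 1, var, na.rm = TRUE), na.rm = TRUE)
    })
    expect_gt(v[2], 2 * v[1])
})

test_that("attenuation factor 1 leaves the DR age effect equal to AL", {
    cfg <- simConfig(nChroms = 1, nCpgsPerChrom = 4000, nAgeDMR = 6,
                     nDietDMR = 0, nGenes = 0, nWholeGene = 0,
                     ameliorationFraction = 1, attenuationFactor = 1,
                     dispersion = 0, depthMean = 3000, seed = 3)
    sim <- simulateMethylome(cfg)
    merged <- mergeReplicates(sim$counts)
    lv <- methylationLevel(merged)
    tr <- sim$truth$regions
    rg <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start, tr$end))
    inR <- IRanges::overlapsAny(SummarizedExperiment::rowRanges(merged), rg)
    dAL <- lv[inR, "AL_old"] - lv[inR, "AL_young"]
    dDR <- lv[inR, "DR_old"] - lv[inR, "DR_young"]
    expect_true(all(abs(dAL - dDR) < 5))
    expect_gt(mean(abs(dAL)), 8)  # the age effect itself is present
})

test_that("ground truth respects its own invariants", {
    x <- sharedSim()
    tr <- x$sim$truth
    ## planted regions lie within simulated chromosomes
    gr <- SummarizedExperiment::rowRanges(x$sim$counts)
    for (cc in unique(tr$regions$chrom)) {
        r <- tr$regions[tr$regions$chrom == cc, ]
        pos <- GenomicRanges::start(gr)[
            as.character(GenomicRanges::seqnames(gr)) == cc]
        expect_true(all(r$start >= min(pos) & r$end <= max(pos) + 1))
    }
    ## ameliorated regions are a subset of the age-effect regions
    expect_true(all(tr$regions$class[tr$regions$ameliorated] == "age"))
    ## whole-gene plants span at least 4 bins' worth of CpGs
    wg <- tr$genes[tr$genes$class == "wholegene", ]
    expect_true(all(wg$cpgTo - wg$cpgFrom + 1 >= 125))
})

test_that("annotations contain every element ingredient", {
    x <- sharedSim()
    anno <- simulateAnnotations(x$cfg)
    expect_true(all(GenomicRanges::start(anno$genes) >= 1))
    proms <- buildPromoters(anno$genes)
    cls <- classifyCGIs(anno$cgis, proms, anno$genes)
    expect_gt(length(cls$promoter), 0)
    expect_gt(length(cls$gene), 0)
    expect_gt(length(cls$intergenic), 0)
    for (tk in c("H3K4me1", "H3K27ac", "H3K4me3", "H3K9ac", "H3K27me3",
                 "coChIP"))
        expect_gt(length(anno[[tk]]), 0)
})

test_that("expression tables couple inversely to planted methylation", {
    cfg <- simConfig(nChroms = 2, nCpgsPerChrom = 15000, nAgeDMR = 4,
                     nDietDMR = 2, nGenes = 10, nWholeGene = 50, seed = 8)
    sim <- simulateMethylome(cfg)
    ## zero noise: sign is exactly opposite to the planted effect
    de0 <- simulateExpression(sim$truth, noiseSd = 0, seed = 1)
    wg <- sim$truth$genes$class == "wholegene"
    expect_true(all(sign(de0$log2FC[wg]) == -sign(sim$truth$genes$effect[wg])))
    expect_true(all(de0$padj >= 0 & de0$padj <= 1))
    ## moderate noise: planted genes still anti-correlate
    de <- simulateExpression(sim$truth, noiseSd = 0.1, seed = 2)
    expect_lt(cor(sim$truth$genes$effect[wg], de$log2FC[wg]), 0)
})

test_that("TG tables are positive, normalizable and unshifted at shift 0", {
    tg <- simulateTGTable(nSamplesPerGroup = 20, shift = 0, seed = 4)
    cols <- setdiff(colnames(tg$abundance),
                    c("species", "carbons", "double_bonds"))
    expect_true(all(colSums(tg$abundance[cols]) > 0))
    rel <- normalizeTG(tg$abundance)
    expect_equal(unname(colSums(as.matrix(rel[cols]))),
                 rep(100, length(cols)))
    ## scale invariance of normalization
    sc <- tg$abundance; sc[cols] <- sc[cols] * 7
    expect_equal(normalizeTG(sc)[cols], rel[cols])
    ## with no shift the diet profiles agree in expectation
    agg <- aggregateBy(rel, "carbons")
    grp <- tg$samples$group[match(colnames(agg)[-1], tg$samples$sample)]
    mAL <- rowMeans(agg[, -1][, grepl("AL", grp)])
    mDR <- rowMeans(agg[, -1][, grepl("DR", grp)])
    expect_true(max(abs(mAL - mDR)) < 1)
})
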