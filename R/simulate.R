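#' Configuration for the synthetic methylome generator
#'
#' Bundles and validates all parameters of the simulated study: two diets
#' (ad libitum, dietary restriction) crossed with two ages, `nReplicates`
#' animals per group. CpG sites are laid out as a uniform background plus
#' dense CpG-island-like clusters; per-CpG, per-sample counts are drawn
#' beta-binomially around group means. Regions with planted age effects,
#' diet effects, DR-attenuated ("ameliorated") age effects and whole-gene
#' diet effects provide ground truth for every downstream stage.
#'
#' @param nChroms number of simulated chromosomes.
#' @param chromLen approximate chromosome length in bp (drives background
#'   CpG spacing).
#' @param nCpgsPerChrom CpGs per chromosome.
#' @param islandFraction fraction of CpGs placed in dense island clusters.
#' @param islandSize CpGs per island cluster (clusters span >= 200 bp).
#' @param nReplicates animals per treatment group (study design: 3).
#' @param depthMean mean Poisson read coverage per CpG per sample.
#' @param dispersion beta-binomial overdispersion rho in `[0, 1)`; 0 gives
#'   pure binomial sampling around the group mean.
#' @param baselineHigh mean methylation fraction of non-island CpGs.
#' @param baselineLow mean methylation fraction of promoter-island CpGs.
#' @param nAgeDMR,nDietDMR number of planted age- and diet-effect regions.
#' @param ameliorationFraction fraction of age-effect regions whose age
#'   effect under DR is scaled by `attenuationFactor`.
#' @param attenuationFactor multiplier in `[0, 1]` applied to the age effect
#'   in the DR arm of ameliorated regions (1 = no amelioration).
#' @param effectRange absolute methylation-shift range `(min, max)` for
#'   planted effects, default `c(0.10, 0.35)`.
#' @param nGenes number of unplanted background genes.
#' @param nWholeGene number of genes with a planted whole-gene-body diet
#'   effect (these genes anti-correlate with expression).
#' @param wholeGeneEffect absolute methylation shift of whole-gene plants.
#' @param regionCpgs CpGs per planted region; regions are aligned to the
#'   25-CpG bin grid so each plant fully covers two 50-CpG bins.
#' @param geneCpgs CpGs per gene body (spans >= 4 bins).
#' @param seed integer RNG seed; identical seed and config give
#'   byte-identical output.
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(nChroms = 2L, chromLen = 6e6, nCpgsPerChrom = 25000L,
                      islandFraction = 0.2, islandSize = 60L,
                      nReplicates = 3L, depthMean = 30, dispersion = 0.05,
                      baselineHigh = 0.85, baselineLow = 0.10,
                      nAgeDMR = 40L, nDietDMR = 20L,
                      ameliorationFraction = 0.3, attenuationFactor = 0.1,
                      effectRange = c(0.10, 0.35),
                      nGenes = 20L, nWholeGene = 10L, wholeGeneEffect = 0.15,
                      regionCpgs = 75L, geneCpgs = 150L, seed = 1L) {
    cfg <- list(nChroms = as.integer(nChroms), chromLen = chromLen,
                nCpgsPerChrom = as.integer(nCpgsPerChrom),
                islandFraction = islandFraction, islandSize = as.integer(islandSize),
                nReplicates = as.integer(nReplicates), depthMean = depthMean,
                dispersion = dispersion, baselineHigh = baselineHigh,
                baselineLow = baselineLow, nAgeDMR = as.integer(nAgeDMR),
                nDietDMR = as.integer(nDietDMR),
                ameliorationFraction = ameliorationFraction,
                attenuationFactor = attenuationFactor,
                effectRange = effectRange, nGenes = as.integer(nGenes),
                nWholeGene = as.integer(nWholeGene),
                wholeGeneEffect = wholeGeneEffect,
                regionCpgs = as.integer(regionCpgs),
                geneCpgs = as.integer(geneCpgs), seed = as.integer(seed))
    fr <- c("islandFraction", "ameliorationFraction")
    for (f in fr)
        if (cfg[[f]] < 0 || cfg[[f]] > 1)
            stop(sprintf("'%s' must lie in [0, 1]", f))
    if (cfg$attenuationFactor < 0 || cfg$attenuationFactor > 1)
        stop("'attenuationFactor' must lie in [0, 1]")
    if (cfg$dispersion < 0 || cfg$dispersion >= 1)
        stop("'dispersion' must lie in [0, 1)")
    for (f in c("baselineHigh", "baselineLow"))
        if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
            stop(sprintf("'%s' must lie in (0, 1)", f))
    if (length(cfg$effectRange) != 2L || any(cfg$effectRange <= 0) ||
        any(cfg$effectRange >= 1) || diff(cfg$effectRange) < 0)
        stop("'effectRange' must be an increasing pair within (0, 1)")
    for (f in c("nChroms", "nCpgsPerChrom", "nReplicates"))
        if (cfg[[f]] < 1L) stop(sprintf("'%s' must be positive", f))
    if (cfg$depthMean <= 0) stop("'depthMean' must be positive")
    if (cfg$islandFraction > 0 &&
        cfg$islandFraction * cfg$nCpgsPerChrom < cfg$islandSize)
        stop("islandFraction * nCpgsPerChrom is smaller than one island")
    class(cfg) <- "SimConfig"
    cfg
}

#' @export
print.SimConfig <- function(x, ...) {
    cat(sprintf("SimConfig: %d chrom(s) x %d CpGs, %d reps/group, depth %g, rho %g\n",
                x$nChroms, x$nCpgsPerChrom, x$nReplicates, x$depthMean,
                x$dispersion))
    cat(sprintf("  plants: %d age (%.0f%% ameliorated x%g), %d diet, %d whole-gene (%+.0f pts); seed %d\n",
                x$nAgeDMR, 100 * x$ameliorationFraction, x$attenuationFactor,
                x$nDietDMR, x$nWholeGene, 100 * x$wholeGeneEffect, x$seed))
    invisible(x)
}

## Allocate a free index block of `len` CpGs on one chromosome, start aligned
## to `align`. A 25-CpG margin is reserved around each block so partial bins
## never mix two different plants. Returns the start index or NA.
.allocBlock <- function(occ, len, align = 25L) {
    n <- length(occ)
    ## bins start at 1-based CpG index 1, 26, 51, ...; aligned blocks start
    ## on that grid so a 75-CpG plant fully covers two 50-CpG bins
    cand <- seq.int(align + 1L, n - len - align, by = align)
    cand <- cand[!vapply(cand, function(s)
        any(occ[max(1L, s - align):min(n, s + len + align - 1L)]), logical(1))]
    if (!length(cand)) return(NA_integer_)
    cand[sample.int(length(cand), 1L)]
}

## Deterministic layout shared by simulateMethylome() and
## simulateAnnotations(): CpG positions, island runs, planted regions, genes
## and per-CpG group-mean methylation. Consumes the RNG stream; callers must
## seed first.
.simLayout <- function(config) {
    cf <- config
    chroms <- paste0("chr", seq_len(cf$nChroms))
    n <- cf$nCpgsPerChrom
    bgGap <- max(10, round(cf$chromLen / n) - 2L)

    regions <- genes <- islands <- list()
    layout <- vector("list", cf$nChroms); names(layout) <- chroms

    ## round-robin assignment of plants to chromosomes
    rrChrom <- function(k) if (k < 1L) integer(0) else (seq_len(k) - 1L) %% cf$nChroms + 1L
    ageChr <- rrChrom(cf$nAgeDMR); dietChr <- rrChrom(cf$nDietDMR)
    wgChr <- rrChrom(cf$nWholeGene); bgChr <- rrChrom(cf$nGenes)
    nAmel <- round(cf$ameliorationFraction * cf$nAgeDMR)
    geneId <- 0L

    for (ci in seq_len(cf$nChroms)) {
        occ <- logical(n)
        mark <- function(s, len) {
            lo <- max(1L, s - 25L); hi <- min(n, s + len + 24L)
            occ[lo:hi] <<- TRUE
        }
        put <- function(k, len) {
            starts <- integer(0)
            for (i in seq_len(k)) {
                s <- .allocBlock(occ, len)
                if (is.na(s)) stop("simulated chromosome too small for the requested plants")
                mark(s, len); starts <- c(starts, s)
            }
            starts
        }
        ageS <- put(sum(ageChr == ci), cf$regionCpgs)
        dietS <- put(sum(dietChr == ci), cf$regionCpgs)
        wgS <- put(sum(wgChr == ci), cf$geneCpgs)
        bgS <- put(sum(bgChr == ci), cf$geneCpgs)

        ## islands: promoter/body islands ride on background genes; the rest
        ## of the island budget is intergenic
        nIsl <- max(0L, floor(cf$islandFraction * n / cf$islandSize))
        islRuns <- data.frame(from = integer(0), to = integer(0),
                              class = character(0))
        nBg <- length(bgS)
        promGene <- rep(FALSE, nBg); bodyGene <- rep(FALSE, nBg)
        if (nBg) {
            promGene <- seq_len(nBg) %% 2L == 1L           # odd genes: promoter CGI
            bodyGene <- !promGene & seq_len(nBg) %% 4L == 2L
        }
        for (j in seq_len(nBg)) {
            if (nIsl <= nrow(islRuns)) break
            if (promGene[j])
                islRuns <- rbind(islRuns, data.frame(
                    from = bgS[j], to = bgS[j] + cf$islandSize - 1L,
                    class = "promoter"))
            else if (bodyGene[j]) {
                mid <- bgS[j] + (cf$geneCpgs - cf$islandSize) %/% 2L
                islRuns <- rbind(islRuns, data.frame(
                    from = mid, to = mid + cf$islandSize - 1L, class = "body"))
            }
        }
        while (nrow(islRuns) < nIsl) {
            s <- .allocBlock(occ, cf$islandSize, align = 1L)
            if (is.na(s)) break
            mark(s, cf$islandSize)
            islRuns <- rbind(islRuns, data.frame(
                from = s, to = s + cf$islandSize - 1L, class = "intergenic"))
        }

        ## inter-CpG gaps: dense inside islands, wide background elsewhere
        isl <- logical(n)
        for (j in seq_len(nrow(islRuns))) isl[islRuns$from[j]:islRuns$to[j]] <- TRUE
        gaps <- ifelse(isl, 2L + rpois(n, 8), 2L + rpois(n, bgGap))
        pos <- 1000L + cumsum(gaps)

        ## baseline: high background, low at promoter-island CpGs
        base <- rep(cf$baselineHigh, n)
        promIsl <- logical(n)
        for (j in which(islRuns$class == "promoter"))
            promIsl[islRuns$from[j]:islRuns$to[j]] <- TRUE
        base[promIsl] <- cf$baselineLow

        means <- matrix(base, n, 4L, dimnames = list(NULL, .GROUPS))

        addRegion <- function(s, len, cls, sign, effect, amel = FALSE,
                              wgEffect = NA) {
            idx <- s:(s + len - 1L)
            b <- if (sign > 0) runif(1, 0.30, 0.50) else runif(1, 0.70, 0.90)
            means[idx, ] <<- b
            if (cls == "age") {
                means[idx, "AL_old"] <<- b + sign * effect
                att <- if (amel) cf$attenuationFactor else 1
                means[idx, "DR_old"] <<- b + sign * effect * att
            } else {  # diet effect in both DR groups
                means[idx, "DR_young"] <<- b + sign * effect
                means[idx, "DR_old"] <<- b + sign * effect
            }
            data.frame(chrom = chroms[ci], cpgFrom = s, cpgTo = s + len - 1L,
                       start = pos[s], end = pos[s + len - 1L] + 1L,
                       class = cls, sign = sign, effect = effect,
                       ameliorated = amel)
        }

        globalAge <- which(ageChr == ci)   # global indices of this chrom's age plants
        for (j in seq_along(ageS)) {
            gidx <- globalAge[j]
            regions <- c(regions, list(addRegion(
                ageS[j], cf$regionCpgs, "age",
                sign = if (gidx %% 2L == 1L) 1 else -1,
                effect = runif(1, cf$effectRange[1], cf$effectRange[2]),
                amel = gidx <= nAmel)))
        }
        globalDiet <- which(dietChr == ci)
        for (j in seq_along(dietS)) {
            gidx <- globalDiet[j]
            regions <- c(regions, list(addRegion(
                dietS[j], cf$regionCpgs, "diet",
                sign = if (gidx %% 2L == 1L) 1 else -1,
                effect = runif(1, cf$effectRange[1], cf$effectRange[2]))))
        }

        addGene <- function(s, len, cls, sign = 0, effect = 0, prom = FALSE,
                            body = FALSE) {
            geneId <<- geneId + 1L
            idx <- s:(s + len - 1L)
            if (cls == "wholegene") {
                b <- if (sign > 0) runif(1, 0.35, 0.55) else runif(1, 0.70, 0.90)
                means[idx, ] <<- b
                means[idx, "DR_young"] <<- b + sign * effect
                means[idx, "DR_old"] <<- b + sign * effect
            }
            ## promoter islands sit at the block start, which is the TSS
            ## only on the plus strand, so those genes are forced to "+"
            data.frame(gene_id = sprintf("gene%03d", geneId),
                       chrom = chroms[ci], cpgFrom = s, cpgTo = s + len - 1L,
                       start = pos[s] - 100L, end = pos[s + len - 1L] + 100L,
                       strand = if (prom || geneId %% 2L == 1L) "+" else "-",
                       class = cls, sign = sign, effect = sign * effect,
                       promoterIsland = prom, bodyIsland = body)
        }
        globalWg <- which(wgChr == ci)
        for (j in seq_along(wgS)) {
            gidx <- globalWg[j]
            genes <- c(genes, list(addGene(
                wgS[j], cf$geneCpgs, "wholegene",
                sign = if (gidx %% 2L == 1L) 1 else -1,
                effect = cf$wholeGeneEffect)))
        }
        for (j in seq_along(bgS))
            genes <- c(genes, list(addGene(bgS[j], cf$geneCpgs, "background",
                                           prom = promGene[j], body = bodyGene[j])))

        if (nrow(islRuns))
            islands <- c(islands, list(data.frame(
                chrom = chroms[ci], cpgFrom = islRuns$from, cpgTo = islRuns$to,
                start = pos[islRuns$from] - 50L, end = pos[islRuns$to] + 50L,
                class = islRuns$class)))

        means[means < 0.001] <- 0.001
        means[means > 0.999] <- 0.999
        layout[[ci]] <- list(pos = pos, means = means, island = isl,
                             chromEnd = pos[n] + 1000L)
    }
    bindRows <- function(l) if (length(l)) do.call(rbind, l) else NULL
    list(chroms = chroms, perChrom = layout,
         regions = bindRows(regions), genes = bindRows(genes),
         islands = bindRows(islands))
}

#' Simulate a four-group bisulfite methylome with known ground truth
#'
#' Lays out CpG sites (uniform background plus island clusters), plants
#' age-effect, diet-effect, ameliorated and whole-gene regions, and draws
#' per-CpG, per-sample methylated/unmethylated counts beta-binomially
#' (mean = group mean, overdispersion `dispersion`) at Poisson coverage.
#' Ameliorated regions receive the age effect scaled by
#' `attenuationFactor` in the DR arm only.
#'
#' @param config A [simConfig()] object.
#' @return A list with elements `counts` (a [MethylCounts-class] with
#'   `nReplicates` samples per group) and `truth` (list with data.frames
#'   `regions` and `genes` giving planted coordinates, signs, effect sizes
#'   and amelioration flags, plus the generating `config`).
#' @examples
#' sim <- simulateMethylome(simConfig(nCpgsPerChrom = 2000, nChroms = 1,
#'                                    nAgeDMR = 4, nDietDMR = 2,
#'                                    nGenes = 2, nWholeGene = 2, seed = 7))
#' sim$counts
#' @export
simulateMethylome <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    layout <- .simLayout(config)
    samples <- as.vector(vapply(.GROUPS, function(g)
        sprintf("%s_r%d", g, seq_len(config$nReplicates)),
        character(config$nReplicates)))
    groups <- rep(.GROUPS, each = config$nReplicates)
    rho <- config$dispersion

    methL <- unmethL <- list(); chromV <- posV <- list()
    for (ci in seq_along(layout$chroms)) {
        lc <- layout$perChrom[[ci]]
        n <- length(lc$pos)
        m <- u <- matrix(0L, n, length(samples),
                         dimnames = list(NULL, samples))
        for (si in seq_along(samples)) {
            mu <- lc$means[, groups[si]]
            depth <- rpois(n, config$depthMean)
            p <- if (rho > 0)
                rbeta(n, mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho)
            else mu
            m[, si] <- rbinom(n, depth, p)
            u[, si] <- depth - m[, si]
        }
        methL[[ci]] <- m; unmethL[[ci]] <- u
        chromV[[ci]] <- rep(layout$chroms[ci], n); posV[[ci]] <- lc$pos
    }
    gr <- GRanges(factor(unlist(chromV), levels = layout$chroms),
                  IRanges(unlist(posV), width = 1L))
    mc <- MethylCounts(do.call(rbind, methL), do.call(rbind, unmethL),
                       gr, groups)
    list(counts = mc,
         truth = list(regions = layout$regions, genes = layout$genes,
                      islands = layout$islands, config = config))
}

#' Simulate annotation tracks matching a methylome layout
#'
#' Regenerates (from the same seed) the CpG/gene/island layout used by
#' [simulateMethylome()] and derives annotation interval sets: gene bodies
#' with strand, CpG islands (some at TSSs, some in gene bodies, some
#' intergenic), random repeats, histone-mark peak tracks placed so that each
#' rule-based chromatin element class is represented (active promoters with
#' H3K4me3 + nearby H3K9ac, narrow promoter H3K27me3, gene-body enhancers
#' with H3K4me1 + H3K27ac, broad gene-body H3K27me3, distal enhancers), and
#' coChIP peaks over a subset of islands (bivalent CGIs).
#'
#' @param config A [simConfig()] object (same config/seed as the methylome).
#' @return Named list of `GRanges`: `genes`, `cgis`, `repeats`, `H3K4me1`,
#'   `H3K27ac`, `H3K4me3`, `H3K9ac`, `H3K27me3`, `coChIP`.
#' @export
simulateAnnotations <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    layout <- .simLayout(config)
    chromFac <- function(x) factor(x, levels = layout$chroms)
    g <- layout$genes
    genes <- GRanges(chromFac(g$chrom), IRanges(g$start, g$end),
                     strand = g$strand, gene_id = g$gene_id, class = g$class)
    isl <- layout$islands
    cgis <- if (!is.null(isl))
        GRanges(chromFac(isl$chrom), IRanges(isl$start, isl$end)) else GRanges()

    reps <- list()
    for (ci in seq_along(layout$chroms)) {
        len <- layout$perChrom[[ci]]$chromEnd
        st <- sort(sample.int(len - 700L, 40L))
        reps[[ci]] <- GRanges(chromFac(layout$chroms[ci]),
                              IRanges(st, width = sample(150:600, 40L, TRUE)))
    }
    repeats <- do.call(c, reps)

    tss <- ifelse(g$strand == "+", g$start, g$end)
    mid <- (g$start + g$end) %/% 2L
    cls <- seq_len(nrow(g)) %% 5L
    mk <- function(sel, from, to) GRanges(chromFac(g$chrom[sel]),
                                          IRanges(from[sel], to[sel]))
    H3K4me3 <- mk(cls %in% c(0L, 1L), tss - 300L, tss + 500L)
    H3K9ac <- mk(cls %in% c(0L, 1L), tss - 250L, tss + 550L)
    H3K27me3 <- c(mk(cls == 2L, tss - 1000L, tss + 1000L),     # narrow, promoter
                  mk(cls == 4L, mid - 2500L, mid + 2500L))     # broad, gene body
    H3K4me1 <- c(mk(cls == 3L, mid - 400L, mid + 400L))
    H3K27ac <- c(mk(cls == 3L, mid - 350L, mid + 450L))
    ## distal enhancers: intergenic H3K4me1/H3K27ac pairs clear of genes
    for (ci in seq_along(layout$chroms)) {
        len <- layout$perChrom[[ci]]$chromEnd
        cand <- GRanges(chromFac(layout$chroms[ci]),
                        IRanges(sort(sample.int(len - 2000L, 25L)), width = 800L))
        far <- !overlapsAny(cand + 6000L, genes)
        cand <- head(cand[far], 5L)
        H3K4me1 <- c(H3K4me1, cand)
        H3K27ac <- c(H3K27ac, GenomicRanges::shift(cand, 60L))
    }
    biv <- if (length(cgis)) cgis[seq_along(cgis) %% 3L == 0L] else GRanges()
    coChIP <- if (length(biv)) GenomicRanges::resize(biv, width = 400L, fix = "center")
              else GRanges()
    list(genes = genes, cgis = cgis, repeats = repeats,
         H3K4me1 = sort(H3K4me1), H3K27ac = sort(H3K27ac),
         H3K4me3 = sort(H3K4me3), H3K9ac = sort(H3K9ac),
         H3K27me3 = sort(H3K27me3), coChIP = sort(coChIP))
}

#' Simulate a differential-expression table coupled to planted methylation
#'
#' Genes with a planted whole-gene methylation effect receive a log2 fold
#' change (DR vs AL) of sign opposite to the methylation shift
#' (`log2FC = -5 * effect + noise`); background genes are pure noise. An
#' approximate p-value is derived from the standardized fold change and
#' BH-adjusted.
#'
#' @param truth Ground-truth list from [simulateMethylome()].
#' @param noiseSd Gaussian noise standard deviation on log2FC.
#' @param seed RNG seed.
#' @return data.frame with `gene_id`, `log2FC`, `padj`, `expressed`.
#' @export
simulateExpression <- function(truth, noiseSd = 0.2, seed = 1L) {
    g <- truth$genes
    set.seed(seed)
    lfc <- -5 * g$effect + rnorm(nrow(g), 0, noiseSd)
    sd0 <- max(noiseSd, 0.05)
    p <- 2 * pnorm(-abs(lfc) / sd0)
    data.frame(gene_id = g$gene_id, log2FC = lfc,
               padj = p.adjust(p, "BH"), expressed = TRUE)
}

#' Simulate a triglyceride species abundance table
#'
#' TG species live on the grid of even total acyl carbons 38-60 by total
#' double bonds 0-12. Group mean profiles are discretized bivariate normals
#' over (carbons, double bonds); the DR groups' carbon-number profile is
#' displaced toward shorter chains by `shift` categories (one category =
#' 2 carbons) relative to the AL center at 54 carbons. Per-sample
#' species abundances get multiplicative log-normal noise; an optional
#' `alOldBoost` scales total TG of the old AL group to plant a diet-by-age
#' interaction in total TG content.
#'
#' @param nSamplesPerGroup scalar or length-4 vector (order `AL_young`,
#'   `AL_old`, `DR_young`, `DR_old`); default `c(4, 3, 4, 3)` (4 young and
#'   3 old animals per diet).
#' @param shift chain-length displacement of the DR groups in categories.
#' @param seed RNG seed.
#' @param speciesCV log-normal coefficient of variation of species
#'   abundances.
#' @param totalCV log-normal coefficient of variation of per-sample total TG.
#' @param alOldBoost multiplier on old-AL total TG (1 = no interaction).
#' @return list with `abundance` (data.frame: `species`, `carbons`,
#'   `double_bonds`, one column per sample) and `samples` (data.frame:
#'   `sample`, `group`, `age`, `diet`, `total`).
#' @export
simulateTGTable <- function(nSamplesPerGroup = c(4L, 3L, 4L, 3L), shift = 1,
                            seed = 1L, speciesCV = 0.15, totalCV = 0.1,
                            alOldBoost = 1) {
    if (length(nSamplesPerGroup) == 1L)
        nSamplesPerGroup <- rep(nSamplesPerGroup, 4L)
    stopifnot(length(nSamplesPerGroup) == 4L, all(nSamplesPerGroup >= 1L))
    set.seed(seed)
    grid <- expand.grid(carbons = seq(38L, 60L, 2L), double_bonds = 0:12)
    ab <- data.frame(species = sprintf("TG%d:%d", grid$carbons, grid$double_bonds),
                     carbons = grid$carbons, double_bonds = grid$double_bonds)
    samp <- NULL
    for (gi in seq_along(.GROUPS)) {
        grp <- .GROUPS[gi]
        diet <- sub("_.*", "", grp); age <- sub(".*_", "", grp)
        center <- 54 - 2 * shift * (diet == "DR")
        w <- dnorm(grid$carbons, center, 4) * dnorm(grid$double_bonds, 3, 2)
        w <- w / sum(w)
        for (ri in seq_len(nSamplesPerGroup[gi])) {
            total <- 100 * (if (grp == "AL_old") alOldBoost else 1) *
                rlnorm(1, -totalCV^2 / 2, totalCV)
            noise <- rlnorm(nrow(grid), -speciesCV^2 / 2, speciesCV)
            sm <- sprintf("%s_r%d", grp, ri)
            ab[[sm]] <- total * w * noise
            samp <- rbind(samp, data.frame(sample = sm, group = grp,
                                           age = age, diet = diet,
                                           total = sum(ab[[sm]])))
        }
    }
    list(abundance = ab, samples = samp)
}
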