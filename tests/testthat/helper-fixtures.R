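## shared fixture builders; everything is generated in code at test time

GROUPS <- c("AL_young", "AL_old", "DR_young", "DR_old")

## MethylCounts from plain vectors/matrices
mcFrom <- function(pos, meth, unmeth, group, chrom = "chr1") {
    meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
    if (is.null(colnames(meth)))
        colnames(meth) <- colnames(unmeth) <-
            paste0("s", seq_len(ncol(meth)))
    MethylCounts(meth, unmeth,
                 GenomicRanges::GRanges(chrom,
                                        IRanges::IRanges(pos, width = 1)),
                 group)
}

## BinSet directly from a level matrix (counts derived unless given)
binSetFrom <- function(level, meth = NULL, unmeth = NULL, chrom = "chr1") {
    level <- as.matrix(level)
    n <- nrow(level)
    if (is.null(meth)) {
        meth <- round(level * 15)
        unmeth <- round((100 - level) * 15)
    }
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(seq(1, by = 2000, length.out = n),
                                width = 1500))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(level = level, meth = as.matrix(meth),
                      unmeth = as.matrix(unmeth)),
        rowRanges = gr,
        colData = S4Vectors::DataFrame(
            group = factor(colnames(level), levels = GROUPS),
            row.names = colnames(level)))
    SummarizedExperiment::rowData(se)$bin_id <- sprintf("b%05d", seq_len(n))
    SummarizedExperiment::rowData(se)$cpg_first <- (seq_len(n) - 1L) * 25L + 1L
    new("BinSet", se)
}

## four-group level matrix with given noise, for amelioration fixtures
levelMatrix <- function(base, n, noiseSd = 1, seed = 1) {
    set.seed(seed)
    m <- matrix(rep(base, each = n), n, 4) + rnorm(4 * n, 0, noiseSd)
    colnames(m) <- GROUPS
    pmin(pmax(m, 0), 100)
}

## small default-scale simulation shared by several test files
sharedSim <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- simConfig(seed = 42)
            sim <- simulateMethylome(cfg)
            merged <- filterMinCoverage(mergeReplicates(sim$counts))
            bins <- makeBins(merged)
            cache <<- list(cfg = cfg, sim = sim, merged = merged,
                           bins = bins)
        }
        cache
    }
})
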