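#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps promoters trim distanceToNearest
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges colData rowData rowData<-
#' @importFrom stats aov cor lm p.adjust pchisq phyper fisher.test
#'   quantile rbeta rbinom rnorm rpois runif rlnorm sd TukeyHSD wilcox.test
#'   median pnorm ks.test coef residuals setNames dnorm
#' @importFrom utils read.table write.table head
NULL

## The four treatment groups: diet (ad libitum vs dietary restriction)
## crossed with age (young vs old).
.GROUPS <- c("AL_young", "AL_old", "DR_young", "DR_old")

#' Per-CpG methylation counts across samples
#'
#' `MethylCounts` extends `RangedSummarizedExperiment` and stores, for every
#' CpG site (rows, width-1 ranges at the cytosine position) and every sample
#' or merged group (columns), the number of methylated and unmethylated
#' read observations in the assays `"meth"` and `"unmeth"`. `colData` carries
#' a `group` factor assigning each sample to one of the four treatment groups
#' `AL_young`, `AL_old`, `DR_young`, `DR_old`. Missing coverage is represented
#' as a (0, 0) count pair, never as `NA`.
#'
#' @seealso [MethylCounts()] for construction, [mergeReplicates()],
#'   [makeBins()]
#' @export
setClass("MethylCounts", contains = "RangedSummarizedExperiment")

setValidity("MethylCounts", function(object) {
    msg <- NULL
    if (!all(c("meth", "unmeth") %in% names(assays(object))))
        msg <- c(msg, "assays 'meth' and 'unmeth' are required")
    else {
        m <- assay(object, "meth"); u <- assay(object, "unmeth")
        if (any(m < 0) || any(u < 0))
            msg <- c(msg, "counts must be non-negative")
    }
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        g <- colData(object)$group
        if (any(is.na(g)) || !all(g %in% .GROUPS))
            msg <- c(msg, sprintf("groups must be one of: %s",
                                  paste(.GROUPS, collapse = ", ")))
    }
    if (length(object) > 1L) {
        chr <- as.character(seqnames(rowRanges(object)))
        pos <- start(rowRanges(object))
        o <- order(chr, pos)
        if (!identical(o, seq_along(pos)))
            msg <- c(msg, "CpG positions must be sorted by chromosome and position")
        same <- chr[-1L] == chr[-length(chr)]
        if (any(same & diff(pos) == 0L))
            msg <- c(msg, "duplicate CpG positions within a chromosome")
    }
    if (is.null(msg)) TRUE else msg
})

#' Fixed-CpG-count methylation bins
#'
#' `BinSet` extends `RangedSummarizedExperiment`. Each row is a sliding
#' window covering exactly `size` consecutive retained CpGs (default 50,
#' stepped by 25), with genomic span from the first contained CpG to one
#' base past the last (covering both strands of the terminal CpG
#' dinucleotide). Assays: `"level"` (percent methylation per group,
#' unweighted mean over per-CpG percentages), `"meth"` and `"unmeth"`
#' (pooled counts per group, used by the chi-squared test). `rowData`
#' holds `bin_id` and the 1-based index of the first CpG on its chromosome.
#'
#' @seealso [makeBins()], [binLevels()], [callDMRs()]
#' @export
setClass("BinSet", contains = "RangedSummarizedExperiment")

setValidity("BinSet", function(object) {
    msg <- NULL
    need <- c("level", "meth", "unmeth")
    if (!all(need %in% names(assays(object))))
        msg <- c(msg, "assays 'level', 'meth' and 'unmeth' are required")
    else {
        lv <- assay(object, "level")
        if (any(lv < -1e-9 | lv > 100 + 1e-9, na.rm = TRUE))
            msg <- c(msg, "levels must lie in [0, 100]")
    }
    if (!all(c("bin_id", "cpg_first") %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must contain 'bin_id' and 'cpg_first'")
    if (is.null(msg)) TRUE else msg
})

#' Result of the amelioration analysis
#'
#' Holds the per-bin deltas (`d_age_AL`, `d_age_DR`, `d_diet_old`), the two
#' ordinary-least-squares fits of the old-age diet difference on the aging
#' change under each diet, the residual standard deviation of the AL fit
#' (`sigma`, whose doubling is the classification `cutoff`), the classified
#' ameliorated DMRs, and the permutation-null distributions of slope and
#' Pearson r under the three label-shuffling schemes.
#'
#' @slot deltas data.frame of per-bin deltas (percentage points).
#' @slot fitAL,fitDR lists with elements `slope`, `intercept`, `r`.
#' @slot sigma numeric(1), sample standard deviation of AL-fit residuals.
#' @slot cutoff numeric(1), `2 * sigma`.
#' @slot ameliorated data.frame of age-related DMRs flagged as ameliorated.
#' @slot perms data.frame of permutation-null statistics (one row per
#'   permutation per scheme), empty if permutations were not requested.
#' @export
setClass("AmeliorationResult",
    representation(deltas = "data.frame", fitAL = "list", fitDR = "list",
                   sigma = "numeric", cutoff = "numeric",
                   ameliorated = "data.frame", perms = "data.frame"))

setValidity("AmeliorationResult", function(object) {
    msg <- NULL
    if (length(object@sigma) != 1L || is.na(object@sigma) || object@sigma < 0)
        msg <- c(msg, "sigma must be a single non-negative number")
    if (length(object@cutoff) != 1L || object@cutoff < 0)
        msg <- c(msg, "cutoff must be a single non-negative number")
    if (is.null(msg)) TRUE else msg
})
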