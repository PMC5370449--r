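## Pairwise contrasts of the 2x2 design: (first group, second group);
## delta is always second minus first.
.CONTRASTS <- list(
    age_AL     = c("AL_young", "AL_old"),
    age_DR     = c("DR_young", "DR_old"),
    diet_young = c("AL_young", "DR_young"),
    diet_old   = c("AL_old", "DR_old"))

#' Groups compared by a named contrast
#'
#' @param contrast one of `"age_AL"`, `"age_DR"`, `"diet_young"`,
#'   `"diet_old"`. The methylation difference is reported as the second
#'   group minus the first (old minus young; DR minus AL).
#' @return character(2): the (first, second) group names.
#' @export
contrastGroups <- function(contrast) {
    if (!contrast %in% names(.CONTRASTS))
        stop("unknown contrast '", contrast, "'; must be one of: ",
             paste(names(.CONTRASTS), collapse = ", "))
    .CONTRASTS[[contrast]]
}

#' Pearson chi-squared test on pooled bin counts
#'
#' Tests the 2x2 table `[[methA, unmethA], [methB, unmethB]]` with one
#' degree of freedom and no continuity correction (pooled bin counts are
#' large: 50 CpGs times sequencing depth). Vectorized over bins. Tables
#' with a zero marginal (all-methylated or all-unmethylated in both
#' groups, or an empty group) return `chi2 = 0`, `p = 1`.
#'
#' @param methA,unmethA,methB,unmethB numeric vectors of pooled counts.
#' @return list with numeric vectors `chi2` and `p`.
#' @examples
#' chiSquareBinTest(90, 10, 50, 50)  # chi2 = 38.095, p = 6.7e-10
#' @export
chiSquareBinTest <- function(methA, unmethA, methB, unmethB) {
    a <- as.numeric(methA); b <- as.numeric(unmethA)
    c <- as.numeric(methB); d <- as.numeric(unmethB)
    n <- a + b + c + d
    denom <- (a + b) * (c + d) * (a + c) * (b + d)
    chi2 <- ifelse(denom > 0, n * (a * d - b * c)^2 / denom, 0)
    list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Call differentially methylated regions for a pairwise contrast
#'
#' Each bin is tested by [chiSquareBinTest()] on its pooled counts;
#' p-values are Benjamini-Hochberg adjusted across all tested bins of the
#' contrast. A bin is a DMR when `padj < alpha` and the absolute
#' methylation difference (from the mean-of-CpG-percentages quantitation)
#' is at least `minDiff` percentage points. The three named DMR sets of
#' the study design are `age_AL` ("age-related DMRs"), `diet_young`
#' ("Young-DR DMRs") and `diet_old` ("Old-DR DMRs").
#'
#' @param bins A [BinSet-class] object.
#' @param contrast contrast name, see [contrastGroups()].
#' @param minDiff minimal absolute difference in percentage points
#'   (default 10).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param levelMethod quantitation used for the reported difference,
#'   see [binLevels()].
#' @return data.frame with one row per tested bin: `bin_id`, coordinates,
#'   the two group levels, `delta` (second minus first group), `chi2`,
#'   `p`, `padj`, `direction` (`"hyper"` iff `delta > 0`) and the logical
#'   `dmr` flag. The contrast and its groups are kept in attributes
#'   `"contrast"` and `"groups"`.
#' @export
callDMRs <- function(bins, contrast, minDiff = 10, alpha = 0.05,
                     levelMethod = "mean") {
    gps <- contrastGroups(contrast)
    if (!all(gps %in% colnames(bins)))
        stop("bins lack group(s): ",
             paste(setdiff(gps, colnames(bins)), collapse = ", "))
    lv <- binLevels(bins, levelMethod)
    m <- assay(bins, "meth"); u <- assay(bins, "unmeth")
    tst <- chiSquareBinTest(m[, gps[1]], u[, gps[1]], m[, gps[2]], u[, gps[2]])
    delta <- lv[, gps[2]] - lv[, gps[1]]
    padj <- p.adjust(tst$p, method = "BH")
    gr <- rowRanges(bins)
    res <- data.frame(
        bin_id = rowData(bins)$bin_id,
        chrom = as.character(seqnames(gr)), start = start(gr), end = end(gr),
        level1 = lv[, gps[1]], level2 = lv[, gps[2]], delta = delta,
        chi2 = tst$chi2, p = tst$p, padj = padj,
        direction = ifelse(delta > 0, "hyper", "hypo"),
        dmr = is.finite(delta) & abs(delta) >= minDiff & padj < alpha,
        row.names = NULL)
    attr(res, "contrast") <- contrast
    attr(res, "groups") <- gps
    res
}

#' Extract the DMR rows of a contrast result
#'
#' @param res data.frame from [callDMRs()].
#' @return The subset of rows flagged as DMRs.
#' @export
dmrSet <- function(res) res[res$dmr, , drop = FALSE]

#' Convert DMR/bin result rows to genomic ranges
#'
#' @param res data.frame with `chrom`, `start`, `end` (e.g. from
#'   [callDMRs()] or [dmrSet()]).
#' @return A `GRanges` with a `bin_id` metadata column when present.
#' @export
dmrRanges <- function(res) {
    gr <- GRanges(res$chrom, IRanges(res$start, res$end))
    if (!is.null(res$bin_id)) gr$bin_id <- res$bin_id
    gr
}

#' Summarize DMR magnitude per direction
#'
#' Reports, separately for hyper- and hypomethylated DMRs, the median
#' methylation level in a reference group and the median difference, plus
#' the full delta distribution for export (the density-scatter summary of
#' DMR magnitude relative to a reference condition).
#'
#' @param res data.frame from [callDMRs()].
#' @param reference `"level1"` or `"level2"`: which contrast group anchors
#'   the reported reference level (default the first group, e.g. young AL).
#' @return list with a `summary` data.frame (direction, n, median reference
#'   level, median delta) and the vector of `deltas`.
#' @export
summarizeMagnitude <- function(res, reference = c("level1", "level2")) {
    reference <- match.arg(reference)
    d <- dmrSet(res)
    if (!nrow(d))
        return(list(summary = data.frame(direction = character(0),
                                         n = integer(0),
                                         median_reference = numeric(0),
                                         median_delta = numeric(0)),
                    deltas = numeric(0)))
    sm <- do.call(rbind, lapply(split(d, d$direction), function(x)
        data.frame(direction = x$direction[1], n = nrow(x),
                   median_reference = median(x[[reference]]),
                   median_delta = median(x$delta))))
    rownames(sm) <- NULL
    list(summary = sm, deltas = d$delta)
}
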