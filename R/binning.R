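#' Remove regions with unusually high observation counts
#'
#' Total read observations (methylated + unmethylated, summed over all
#' columns) are tallied in non-overlapping windows of `windowSize` bp.
#' Windows whose total exceeds `Q3 + stringency * IQR` of the window-count
#' distribution (quartiles by linear interpolation, configurable via
#' `quartileType`) are removed, dropping every CpG they contain. This guards
#' the downstream chi-squared statistics against PCR or mapping pile-ups.
#'
#' @param x A [MethylCounts-class] object (per-sample or merged).
#' @param windowSize window width in bp (default 25000).
#' @param stringency IQR multiplier above the third quartile (default 10);
#'   `Inf` disables filtering.
#' @param quartileType quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return The filtered [MethylCounts-class]; the number of removed windows
#'   and CpGs is reported via `message()`.
#' @examples
#' # windows with totals 10,11,12,13,1000: Q1=11, Q3=13, threshold 33,
#' # so only the 1000-count window is removed
#' @export
filterHighObservation <- function(x, windowSize = 25000, stringency = 10,
                                  quartileType = 7) {
    if (nrow(x) == 0L) stop("empty methylation table")
    gr <- rowRanges(x)
    win <- paste(as.character(seqnames(gr)),
                 (start(gr) - 1L) %/% as.integer(windowSize))
    tot <- rowSums(methCounts(x)) + rowSums(unmethCounts(x))
    winTot <- rowsum(tot, win)
    if (is.infinite(stringency)) return(x)
    q <- quantile(winTot[, 1L], c(0.25, 0.75), type = quartileType,
                  names = FALSE)
    thr <- q[2L] + stringency * (q[2L] - q[1L])
    bad <- rownames(winTot)[winTot[, 1L] > thr]
    drop <- win %in% bad
    message(sprintf("high-observation filter: removed %d window(s), %d CpG(s)",
                    length(bad), sum(drop)))
    x[!drop, ]
}

#' Keep CpGs covered in every condition
#'
#' Retains CpGs whose total observations (methylated + unmethylated) reach
#' `minObs` in every column. Intended to be applied to the merged per-group
#' table so that all four conditions contribute to every retained CpG.
#'
#' @param x A merged [MethylCounts-class] object (one column per group).
#' @param minObs minimum observations per condition (default 3).
#' @return The filtered [MethylCounts-class] object.
#' @export
filterMinCoverage <- function(x, minObs = 3) {
    cov <- methCounts(x) + unmethCounts(x)
    x[rowSums(cov >= minObs) == ncol(x), ]
}

#' Build fixed-CpG-count sliding windows
#'
#' Per chromosome, bins cover exactly `size` consecutive retained CpGs and
#' start every `step` CpGs; trailing partial windows are dropped, so a
#' chromosome with n >= size CpGs yields `floor((n - size)/step) + 1` bins.
#' Fixing the CpG count (rather than the bp width) equalizes data content
#' and statistical power across CpG-density regimes. Two quantitations are
#' stored per group: the `"level"` assay is the unweighted mean of per-CpG
#' methylation percentages (the reporting quantitation); the `"meth"` and
#' `"unmeth"` assays hold pooled counts (the testing quantitation). The
#' genomic span runs from the first CpG to one base past the last,
#' covering both strands of the terminal CpG dinucleotide.
#'
#' @param x A merged, filtered [MethylCounts-class] object.
#' @param size CpGs per bin (default 50).
#' @param step CpGs between bin starts (default 25).
#' @return A [BinSet-class] object.
#' @export
makeBins <- function(x, size = 50L, step = 25L) {
    size <- as.integer(size); step <- as.integer(step)
    stopifnot(size > 0L, step > 0L)
    gr <- rowRanges(x)
    chr <- as.character(seqnames(gr)); pos <- start(gr)
    m <- methCounts(x); u <- unmethCounts(x)
    cov <- m + u
    pct <- ifelse(cov > 0, 100 * m / cov, 0)
    covered <- cov > 0
    ng <- ncol(x)

    rows <- list()
    for (cc in unique(chr)) {
        i <- which(chr == cc); n <- length(i)
        if (n < size) {
            warning(sprintf("chromosome %s has %d < %d CpGs; no bins emitted",
                            cc, n, size))
            next
        }
        starts <- seq.int(1L, n - size + 1L, by = step)
        ends <- starts + size - 1L
        csum <- function(v) rbind(0, apply(v, 2, cumsum))
        cm <- csum(m[i, , drop = FALSE]); cu <- csum(u[i, , drop = FALSE])
        cp <- csum(pct[i, , drop = FALSE])
        cn <- csum(covered[i, , drop = FALSE] + 0)
        wm <- cm[ends + 1L, , drop = FALSE] - cm[starts, , drop = FALSE]
        wu <- cu[ends + 1L, , drop = FALSE] - cu[starts, , drop = FALSE]
        wp <- cp[ends + 1L, , drop = FALSE] - cp[starts, , drop = FALSE]
        wn <- cn[ends + 1L, , drop = FALSE] - cn[starts, , drop = FALSE]
        level <- wp / wn  # mean over covered CpGs; NaN if none covered
        rows[[cc]] <- list(
            gr = GRanges(factor(cc, levels = unique(chr)),
                         IRanges(pos[i][starts], pos[i][ends] + 1L)),
            level = level, meth = wm, unmeth = wu, first = starts)
    }
    if (!length(rows)) stop("no chromosome had enough CpGs to form a bin")
    bind <- function(f) do.call(rbind, lapply(rows, `[[`, f))
    grAll <- do.call(c, unname(lapply(rows, `[[`, "gr")))
    level <- bind("level"); meth <- bind("meth"); unmeth <- bind("unmeth")
    colnames(level) <- colnames(meth) <- colnames(unmeth) <- colnames(x)
    rowData <- DataFrame(
        bin_id = sprintf("%s_b%06d", as.character(seqnames(grAll)),
                         unlist(lapply(rows, function(r) seq_along(r$first)))),
        cpg_first = unname(unlist(lapply(rows, `[[`, "first"))))
    se <- SummarizedExperiment(
        assays = list(level = level, meth = meth, unmeth = unmeth),
        rowRanges = grAll, colData = colData(x))
    rowData(se) <- cbind(rowData(se), rowData)
    new("BinSet", se)
}

#' Bin methylation levels under either quantitation
#'
#' `"mean"` returns the unweighted mean of per-CpG methylation percentages
#' (the default reporting quantitation); `"pooled"` recomputes levels as
#' `100 * meth/(meth + unmeth)` from the pooled bin counts (the
#' quantitation implied by the count-based chi-squared test). The two agree
#' when per-CpG depths are equal and diverge when they are not.
#'
#' @param x A [BinSet-class] object.
#' @param method `"mean"` or `"pooled"`.
#' @return Numeric matrix (bins x groups) of percent methylation.
#' @export
binLevels <- function(x, method = c("mean", "pooled")) {
    method <- match.arg(method)
    if (method == "mean") return(assay(x, "level"))
    m <- assay(x, "meth"); u <- assay(x, "unmeth")
    100 * m / (m + u)
}

#' @describeIn BinSet-class compact display
#' @param object A `BinSet` object.
#' @export
setMethod("show", "BinSet", function(object) {
    cat(sprintf("BinSet: %d bins x %d groups; median span %d bp\n",
                nrow(object), ncol(object),
                as.integer(median(width(rowRanges(object))))))
})
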