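#' Construct a MethylCounts object
#'
#' @param meth,unmeth integer matrices (CpG x sample) of methylated and
#'   unmethylated observation counts. Missing coverage is `(0, 0)`.
#' @param positions `GRanges` of CpG cytosine positions (width 1), or a
#'   data.frame with columns `chrom` and `pos` (1-based).
#' @param group character or factor of length `ncol(meth)` assigning each
#'   sample to one of `AL_young`, `AL_old`, `DR_young`, `DR_old`.
#' @return A [MethylCounts-class] object sorted by chromosome and position.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 50), width = 1))
#' m <- matrix(c(3, 2, 1, 0), 2, dimnames = list(NULL, c("s1", "s2")))
#' u <- matrix(c(1, 2, 3, 4), 2, dimnames = list(NULL, c("s1", "s2")))
#' mc <- MethylCounts(m, u, gr, c("AL_young", "AL_old"))
#' @export
MethylCounts <- function(meth, unmeth, positions, group) {
    if (is.data.frame(positions))
        positions <- GRanges(positions$chrom,
                             IRanges(positions$pos, width = 1L))
    meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
    storage.mode(meth) <- "integer"; storage.mode(unmeth) <- "integer"
    o <- order(as.character(seqnames(positions)), start(positions))
    se <- SummarizedExperiment(
        assays = list(meth = meth[o, , drop = FALSE],
                      unmeth = unmeth[o, , drop = FALSE]),
        rowRanges = positions[o],
        colData = DataFrame(group = factor(group, levels = .GROUPS),
                            row.names = colnames(meth)))
    new("MethylCounts", se)
}

#' Accessors for methylation count objects
#'
#' `methCounts()` and `unmethCounts()` return the count matrices,
#' `sampleGroups()` the per-column group factor, and `methylationLevel()`
#' the per-CpG percent methylation `100 * meth / (meth + unmeth)` (`NaN`
#' where a CpG has no coverage in a sample).
#'
#' @param x A [MethylCounts-class] object.
#' @return A matrix (counts, levels) or factor (groups).
#' @name methylcounts-accessors
#' @export
methCounts <- function(x) assay(x, "meth")

#' @rdname methylcounts-accessors
#' @export
unmethCounts <- function(x) assay(x, "unmeth")

#' @rdname methylcounts-accessors
#' @export
sampleGroups <- function(x) colData(x)$group

#' @rdname methylcounts-accessors
#' @export
methylationLevel <- function(x) {
    m <- methCounts(x); cov <- m + unmethCounts(x)
    100 * m / cov
}

#' @describeIn MethylCounts-class compact display
#' @param object A `MethylCounts` object.
#' @export
setMethod("show", "MethylCounts", function(object) {
    cat(sprintf("MethylCounts: %d CpGs x %d samples (%d chromosome%s)\n",
                nrow(object), ncol(object),
                length(unique(as.character(seqnames(rowRanges(object))))),
                if (length(unique(as.character(seqnames(rowRanges(object))))) == 1L) "" else "s"))
    tb <- table(sampleGroups(object))
    cat("  samples/group:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
})

#' Merge replicate samples into per-group pooled counts
#'
#' Sums methylated and unmethylated counts per CpG across the replicates of
#' each treatment group, producing one column per group. Pooling replicates
#' enhances coverage before binning and differential testing.
#'
#' @param x A [MethylCounts-class] object with >= 1 sample per present group.
#' @return A [MethylCounts-class] object with one column per group.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, width = 1))
#' m <- matrix(c(3L, 2L), 1); u <- matrix(c(1L, 2L), 1)
#' colnames(m) <- colnames(u) <- c("a", "b")
#' merged <- mergeReplicates(MethylCounts(m, u, gr, c("AL_young", "AL_young")))
#' methCounts(merged)  # 5
#' @export
setGeneric("mergeReplicates", function(x) standardGeneric("mergeReplicates"))

#' @rdname mergeReplicates
#' @export
setMethod("mergeReplicates", "MethylCounts", function(x) {
    g <- droplevels(sampleGroups(x))
    if (ncol(x) == 0L || nlevels(g) == 0L || any(table(g) < 1L))
        stop("every group must contain at least one sample")
    groups <- levels(g)
    m <- vapply(groups, function(k)
        rowSums(methCounts(x)[, g == k, drop = FALSE]), numeric(nrow(x)))
    u <- vapply(groups, function(k)
        rowSums(unmethCounts(x)[, g == k, drop = FALSE]), numeric(nrow(x)))
    if (nrow(x) == 1L) { m <- rbind(m); u <- rbind(u) }
    dimnames(m) <- dimnames(u) <- list(NULL, groups)
    MethylCounts(m, u, rowRanges(x), groups)
})
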