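#' Read bismark-style coverage files into a MethylCounts object
#'
#' Each file is tab-separated with six columns: chromosome, 1-based start,
#' 1-based end, percent methylation, methylated count, unmethylated count.
#' Counts are the primary data: if the percent column disagrees with
#' `100 * meth / (meth + unmeth)` by more than 0.5 percentage points a
#' warning is raised and the counts win. Positions absent from a sample are
#' recorded as `(0, 0)` (outer join over CpG positions).
#'
#' @param paths character vector of coverage file paths.
#' @param sampleGroups named character vector mapping sample name to
#'   treatment group; names default to the file base names (without
#'   extension), and must cover every file.
#' @return A [MethylCounts-class] object with one column per file.
#' @export
readCoverage <- function(paths, sampleGroups) {
    sampleNames <- sub("\\.[^.]*$", "", basename(paths))
    if (is.null(names(sampleGroups)))
        names(sampleGroups) <- sampleNames
    missing <- setdiff(sampleNames, names(sampleGroups))
    if (length(missing))
        stop("no group given for sample(s): ", paste(missing, collapse = ", "))
    tabs <- list()
    for (i in seq_along(paths)) {
        tab <- tryCatch(
            read.table(paths[i], sep = "\t", header = FALSE,
                       colClasses = c("character", "integer", "integer",
                                      "numeric", "integer", "integer"),
                       col.names = c("chrom", "start", "end", "pct",
                                     "meth", "unmeth")),
            error = function(e) stop(sprintf("malformed coverage file '%s': %s",
                                             paths[i], conditionMessage(e))))
        dup <- duplicated(tab[c("chrom", "start")])
        if (any(dup))
            stop(sprintf("duplicate position in '%s' (line %d)",
                         paths[i], which(dup)[1]))
        cov <- tab$meth + tab$unmeth
        expect <- ifelse(cov > 0, 100 * tab$meth / cov, 0)
        bad <- abs(tab$pct - expect) > 0.5
        if (any(bad))
            warning(sprintf(
                "%d line(s) in '%s' have a %% column inconsistent with the counts; counts used",
                sum(bad), basename(paths[i])))
        tabs[[sampleNames[i]]] <- tab[c("chrom", "start", "meth", "unmeth")]
    }
    key <- unique(do.call(rbind, lapply(tabs, `[`, c("chrom", "start"))))
    key <- key[order(key$chrom, key$start), , drop = FALSE]
    id <- paste(key$chrom, key$start)
    m <- u <- matrix(0L, nrow(key), length(tabs),
                     dimnames = list(NULL, names(tabs)))
    for (s in names(tabs)) {
        j <- match(paste(tabs[[s]]$chrom, tabs[[s]]$start), id)
        m[j, s] <- tabs[[s]]$meth
        u[j, s] <- tabs[[s]]$unmeth
    }
    MethylCounts(m, u, data.frame(chrom = key$chrom, pos = key$start),
                 unname(sampleGroups[colnames(m)]))
}

#' Write one bismark-style coverage file per sample
#'
#' @param x A [MethylCounts-class] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths (named by sample).
#' @export
writeCoverage <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gr <- rowRanges(x)
    chrom <- as.character(seqnames(gr)); pos <- start(gr)
    paths <- character(0)
    for (s in colnames(x)) {
        m <- methCounts(x)[, s]; u <- unmethCounts(x)[, s]
        keep <- m + u > 0
        pct <- 100 * m[keep] / (m[keep] + u[keep])
        df <- data.frame(chrom[keep], pos[keep], pos[keep],
                         formatC(pct, digits = 6, format = "g"),
                         m[keep], u[keep])
        p <- file.path(dir, paste0(s, ".cov"))
        write.table(df, p, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        paths[s] <- p
    }
    invisible(paths)
}

#' Read and write BED interval files
#'
#' Thin wrappers over `rtracklayer::import`/`export` that preserve the
#' BED 0-based half-open to GRanges 1-based closed conversion, honor the
#' strand column when present, and reject degenerate intervals. For BED12
#' gene models the full chromStart..chromEnd span is used as the gene body
#' (transcript span including the TSS); block structure is ignored.
#'
#' @param path File path.
#' @param set A `GRanges` to write.
#' @return `readBed` returns a `GRanges`; `writeBed` invisibly returns
#'   `path`.
#' @export
readBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (any(width(gr) < 1))
        stop("BED interval with start >= end in '", path, "'")
    gr
}

#' @rdname readBed
#' @export
writeBed <- function(set, path) {
    if (any(width(set) < 1)) stop("refusing to write empty intervals")
    rtracklayer::export(set, path, format = "BED")
    invisible(path)
}
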