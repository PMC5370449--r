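#' Gene-body methylation from pooled CpG counts
#'
#' Quantifies each gene over all CpGs within its body (the full transcript
#' span including the TSS): per group, pooled methylated/unmethylated
#' counts give `100 * meth/(meth + unmeth)`. Genes with no covered CpG
#' return `NA` levels.
#'
#' @param genes `GRanges` with a `gene_id` metadata column.
#' @param x A merged [MethylCounts-class] object (one column per group).
#' @return data.frame: `gene_id`, `n_cpgs`, one level column per group.
#' @export
geneBodyQuantify <- function(genes, x) {
    if (is.null(genes$gene_id)) stop("genes need a 'gene_id' column")
    if (anyDuplicated(genes$gene_id)) {
        dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
        stop("duplicated gene id(s): ", paste(head(dup), collapse = ", "))
    }
    hits <- findOverlaps(rowRanges(x), genes)
    out <- data.frame(gene_id = genes$gene_id,
                      n_cpgs = countOverlaps(genes, rowRanges(x)))
    m <- methCounts(x); u <- unmethCounts(x)
    for (g in colnames(x)) {
        ms <- rowsum(m[S4Vectors::queryHits(hits), g],
                     S4Vectors::subjectHits(hits))
        us <- rowsum(u[S4Vectors::queryHits(hits), g],
                     S4Vectors::subjectHits(hits))
        lev <- rep(NA_real_, length(genes))
        idx <- as.integer(rownames(ms))
        tot <- ms[, 1L] + us[, 1L]
        lev[idx] <- ifelse(tot > 0, 100 * ms[, 1L] / tot, NA_real_)
        out[[g]] <- lev
    }
    out
}

#' Detect whole-gene-body differential methylation
#'
#' Tests each gene with at least `minBins` overlapping bins for enrichment
#' of DMR bins (one-sided Fisher, gene bins vs the genome-wide bin set,
#' Benjamini-Hochberg across tested genes). Significant genes are then
#' quantified over all gene-body CpGs and retained only if the gene-wide
#' methylation difference reaches `minDelta` percentage points — the
#' signature of differential methylation distributed across an entire
#' gene body rather than concentrated in isolated bins.
#'
#' @param dmrRes data.frame from [callDMRs()] (all tested bins; its `dmr`
#'   flag defines DMR bins and its contrast defines the reported delta).
#' @param bins The [BinSet-class] the contrast was called on.
#' @param genes `GRanges` with `gene_id`.
#' @param x Merged [MethylCounts-class] for gene-wide quantification.
#' @param minBins minimum overlapping bins per tested gene (default 4).
#' @param alpha BH-adjusted p threshold (default 0.05).
#' @param minDelta minimal absolute gene-wide difference in percentage
#'   points (default 2.5).
#' @param excludeSelf drop the gene's own bins from the background row of
#'   the Fisher table (default `FALSE`).
#' @param useAdjusted threshold on adjusted (`TRUE`, default) or raw
#'   p-values.
#' @return data.frame with one row per tested gene: `gene_id`, `n_bins`,
#'   `n_dmrs`, `fisher_p`, `padj`, `genebody_delta`, group levels and the
#'   `selected` flag. Genes with fewer than `minBins` bins are excluded
#'   (count reported via `message()`).
#' @export
wholeGeneBodyGenes <- function(dmrRes, bins, genes, x, minBins = 4L,
                               alpha = 0.05, minDelta = 2.5,
                               excludeSelf = FALSE, useAdjusted = TRUE) {
    gps <- attr(dmrRes, "groups")
    if (is.null(gps)) stop("dmrRes must come from callDMRs()")
    hits <- findOverlaps(rowRanges(bins), genes)
    isDmr <- dmrRes$dmr[match(rowData(bins)$bin_id, dmrRes$bin_id)]
    nBins <- countOverlaps(genes, rowRanges(bins))
    nDmrs <- tabulate(S4Vectors::subjectHits(hits)[
        isDmr[S4Vectors::queryHits(hits)]], length(genes))
    tested <- nBins >= minBins
    message(sprintf("%d gene(s) excluded with < %d overlapping bins",
                    sum(!tested), minBins))
    A <- sum(isDmr); B <- sum(!isDmr)
    fp <- rep(NA_real_, length(genes))
    for (i in which(tested)) {
        bg <- if (excludeSelf) c(A - nDmrs[i], B - (nBins[i] - nDmrs[i]))
              else c(A, B)
        fp[i] <- fisher.test(matrix(c(nDmrs[i], nBins[i] - nDmrs[i], bg),
                                    nrow = 2, byrow = TRUE),
                             alternative = "greater")$p.value
    }
    quant <- geneBodyQuantify(genes[tested], x)
    delta <- quant[[gps[2]]] - quant[[gps[1]]]
    padj <- p.adjust(fp[tested], "BH")
    pUse <- if (useAdjusted) padj else fp[tested]
    out <- data.frame(gene_id = quant$gene_id, n_bins = nBins[tested],
                      n_dmrs = nDmrs[tested], fisher_p = fp[tested],
                      padj = padj, genebody_delta = delta,
                      level1 = quant[[gps[1]]], level2 = quant[[gps[2]]],
                      selected = !is.na(pUse) & pUse < alpha &
                          !is.na(delta) & abs(delta) >= minDelta,
                      row.names = NULL)
    attr(out, "groups") <- gps
    out
}

#' Methylation-expression coupling of DMR-bearing genes
#'
#' Genes overlapped by at least `minDmrs` gene-body DMRs get the average
#' delta of their overlapping DMRs; genes below `minDelta` average
#' difference are dropped (unclear cases with balanced hyper- and
#' hypomethylation). Each retained gene falls in one of four quadrants of
#' (methylation difference, log2 fold change); the quadrant table is
#' tested one-sided by Fisher's exact test for the inverse relationship
#' (hyper with down, hypo with up), and a Pearson correlation is computed
#' over the retained genes. The analysis is repeated restricted to
#' significantly differentially expressed genes.
#'
#' @param dmrRes data.frame from [callDMRs()].
#' @param genes `GRanges` with `gene_id`.
#' @param deTable data.frame with `gene_id`, `log2FC`, `padj`.
#' @param minDmrs minimum overlapping DMRs per gene (default 2).
#' @param minDelta minimal absolute average DMR delta (default 10).
#' @param degAlpha adjusted-p cutoff defining significant DEGs for the
#'   restricted analysis (default 0.05).
#' @return list with `genes` (per-gene table with `mean_dmr_delta`,
#'   `n_dmrs`, `log2FC`, `quadrant`), `quadrants` (2x2 matrix), `fisher_p`,
#'   `r`, and `fisher_p_deg`/`r_deg` for the DEG-restricted repeat
#'   (`NA` when fewer than 3 genes remain).
#' @export
methExprCorrelation <- function(dmrRes, genes, deTable, minDmrs = 2L,
                                minDelta = 10, degAlpha = 0.05) {
    d <- dmrSet(dmrRes)
    hits <- findOverlaps(dmrRanges(d), genes)
    nd <- tabulate(S4Vectors::subjectHits(hits), length(genes))
    meanDelta <- rep(NA_real_, length(genes))
    agg <- rowsum(d$delta[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits))
    meanDelta[as.integer(rownames(agg))] <- agg[, 1L] / nd[as.integer(rownames(agg))]
    keep <- nd >= minDmrs & !is.na(meanDelta) & abs(meanDelta) >= minDelta
    tab <- data.frame(gene_id = genes$gene_id[keep], n_dmrs = nd[keep],
                      mean_dmr_delta = meanDelta[keep])
    tab <- merge(tab, deTable[c("gene_id", "log2FC", "padj")], by = "gene_id")
    if (!nrow(tab)) {
        warning("no genes pass the DMR-count and delta filters")
        return(list(genes = tab, quadrants = matrix(0L, 2, 2),
                    fisher_p = NA_real_, r = NA_real_,
                    fisher_p_deg = NA_real_, r_deg = NA_real_))
    }
    tab$quadrant <- paste0(ifelse(tab$mean_dmr_delta > 0, "hyper", "hypo"),
                           "_", ifelse(tab$log2FC < 0, "down", "up"))
    quad <- function(t) matrix(c(sum(t$quadrant == "hyper_down"),
                                 sum(t$quadrant == "hyper_up"),
                                 sum(t$quadrant == "hypo_down"),
                                 sum(t$quadrant == "hypo_up")),
                               nrow = 2, byrow = TRUE,
                               dimnames = list(c("hyper", "hypo"),
                                               c("down", "up")))
    stat <- function(t) {
        if (nrow(t) < 3L) return(list(p = NA_real_, r = NA_real_))
        list(p = fisher.test(quad(t), alternative = "greater")$p.value,
             r = cor(t$mean_dmr_delta, t$log2FC))
    }
    all <- stat(tab)
    deg <- stat(tab[!is.na(tab$padj) & tab$padj < degAlpha, , drop = FALSE])
    list(genes = tab, quadrants = quad(tab), fisher_p = all$p, r = all$r,
         fisher_p_deg = deg$p, r_deg = deg$r)
}
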