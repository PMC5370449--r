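## edge-to-edge proximity: TRUE for ranges of x with a range of y within
## `gap` bp (overlap counts as distance 0)
.near <- function(x, y, gap = 100L) {
    if (!length(x)) return(logical(0))
    if (!length(y)) return(rep(FALSE, length(x)))
    hits <- distanceToNearest(x, y)
    out <- rep(FALSE, length(x))
    out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance <= gap
    out
}

#' Build promoter regions
#'
#' Strand-aware regions from 5 kb upstream to 100 bp downstream of the
#' transcription start site, trimmed at chromosome start.
#'
#' @param genes `GRanges` of gene bodies with strand (`+` or `-`).
#' @return `GRanges` of promoter regions (metadata columns preserved).
#' @export
buildPromoters <- function(genes) {
    if (any(as.character(strand(genes)) == "*"))
        stop("genes must be stranded to define promoters")
    p <- suppressWarnings(promoters(genes, upstream = 5000L,
                                    downstream = 100L))
    ## clip at the chromosome start (works without seqlengths)
    GenomicRanges::restrict(p, start = 1L)
}

#' Classify CpG islands by overlap precedence
#'
#' Promoter beats gene body beats intergenic: a CGI overlapping both a
#' promoter and a gene body is a promoter CGI. The three classes are
#' disjoint and exhaustive over the input.
#'
#' @param cgis `GRanges` of CpG islands.
#' @param promoters `GRanges` from [buildPromoters()].
#' @param genes `GRanges` of gene bodies.
#' @return Named list of `GRanges`: `promoter`, `gene`, `intergenic`.
#' @export
classifyCGIs <- function(cgis, promoters, genes) {
    inProm <- overlapsAny(cgis, promoters)
    inGene <- !inProm & overlapsAny(cgis, genes)
    list(promoter = cgis[inProm], gene = cgis[inGene],
         intergenic = cgis[!inProm & !inGene])
}

#' Build the rule-based chromatin element catalog
#'
#' Applies the literal element definitions to histone-mark peak tracks:
#' * active enhancer: H3K4me1 peak overlapping an H3K27ac peak; `geneic`
#'   if it overlaps a gene or promoter, else `distal`;
#' * active promoter chromatin: H3K4me3 peak within 100 bp (edge-to-edge)
#'   of an H3K9ac peak, not within 100 bp of H3K27me3, overlapping a
#'   promoter region;
#' * repressive promoter chromatin: narrow H3K27me3 peak (< 3500 bp) not
#'   within 100 bp of H3K27ac or H3K4me3, overlapping a promoter;
#' * repressive geneic chromatin: H3K27me3 (any width) with the same
#'   exclusions, overlapping a gene body but not a promoter (promoter
#'   precedence keeps the two repressive classes disjoint);
#' * bivalent CGI: CGI overlapped by at least one coChIP peak
#'   (H3K4me3-H3K27me3 on the same nucleosome).
#'
#' @param peaks named list of `GRanges` with tracks `H3K4me1`, `H3K27ac`,
#'   `H3K4me3`, `H3K9ac`, `H3K27me3`, `coChIP`.
#' @param promoters `GRanges` from [buildPromoters()].
#' @param genes `GRanges` of gene bodies.
#' @param cgis `GRanges` of CpG islands.
#' @param maxRepressiveWidth width cap (bp) for the repressive *promoter*
#'   class (default 3500).
#' @param proximity edge-to-edge distance (bp) for the "within 100 bp"
#'   rules.
#' @return Named list of `GRanges`: `promoters`, CGI classes
#'   (`cgi_promoter`, `cgi_gene`, `cgi_intergenic`), `repeats` when
#'   supplied in `peaks`, `enhancer_geneic`, `enhancer_distal`,
#'   `active_promoter`, `repressive_promoter`, `repressive_geneic`,
#'   `bivalent_cgi`.
#' @export
buildChromatinElements <- function(peaks, promoters, genes, cgis,
                                   maxRepressiveWidth = 3500L,
                                   proximity = 100L) {
    need <- c("H3K4me1", "H3K27ac", "H3K4me3", "H3K9ac", "H3K27me3", "coChIP")
    miss <- setdiff(need, names(peaks))
    if (length(miss))
        stop("missing required peak track(s): ", paste(miss, collapse = ", "))

    enh <- peaks$H3K4me1[overlapsAny(peaks$H3K4me1, peaks$H3K27ac)]
    enhGeneic <- overlapsAny(enh, genes) | overlapsAny(enh, promoters)

    k4 <- peaks$H3K4me3
    actProm <- k4[.near(k4, peaks$H3K9ac, proximity) &
                  !.near(k4, peaks$H3K27me3, proximity) &
                  overlapsAny(k4, promoters)]

    k27 <- peaks$H3K27me3
    clean <- !.near(k27, peaks$H3K27ac, proximity) &
        !.near(k27, peaks$H3K4me3, proximity)
    onProm <- overlapsAny(k27, promoters)
    repProm <- k27[clean & onProm & width(k27) < maxRepressiveWidth]
    repGeneic <- k27[clean & !onProm & overlapsAny(k27, genes)]

    cgiClasses <- classifyCGIs(cgis, promoters, genes)
    bivalent <- cgis[overlapsAny(cgis, peaks$coChIP)]

    out <- list(promoters = promoters,
                cgi_promoter = cgiClasses$promoter,
                cgi_gene = cgiClasses$gene,
                cgi_intergenic = cgiClasses$intergenic,
                enhancer_geneic = enh[enhGeneic],
                enhancer_distal = enh[!enhGeneic],
                active_promoter = actProm,
                repressive_promoter = repProm,
                repressive_geneic = repGeneic,
                bivalent_cgi = bivalent)
    if (!is.null(peaks$repeats)) out$repeats <- peaks$repeats
    out
}

#' Fisher enrichment of DMRs over an element
#'
#' Counts DMR bins and background bins overlapping (>= 1 bp) the element,
#' forms the 2x2 table `[DMR overlapping, DMR not] x [background
#' overlapping, background not]` and applies a one-sided Fisher exact test
#' (`"greater"` for enrichment; `"less"` detects depletion, e.g. of
#' transposons). The observed/expected ratio is the DMR overlap frequency
#' divided by the genome-wide background frequency.
#'
#' @param dmrs `GRanges` of DMR spans (e.g. `dmrRanges(dmrSet(res))`).
#' @param background `GRanges` of all background bins (the full bin set).
#' @param element `GRanges` of the element class.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return One-row data.frame: `n_dmr`, `n_dmr_overlap`, `n_background`,
#'   `n_background_overlap`, `obs_exp`, `p`.
#' @export
enrichElement <- function(dmrs, background, element,
                          alternative = c("greater", "less")) {
    alternative <- match.arg(alternative)
    n <- length(dmrs); N <- length(background)
    k <- sum(overlapsAny(dmrs, element))
    K <- sum(overlapsAny(background, element))
    obsExp <- if (K == 0 || n == 0) NA_real_ else (k / n) / (K / N)
    p <- if (n == 0 || N == 0) NA_real_ else
        fisher.test(matrix(c(k, n - k, K, N - K), nrow = 2, byrow = TRUE),
                    alternative = alternative)$p.value
    data.frame(n_dmr = n, n_dmr_overlap = k, n_background = N,
               n_background_overlap = K, obs_exp = obsExp, p = p)
}

#' Enrichment of a DMR set over an element catalog
#'
#' Runs [enrichElement()] for every element class and adjusts p-values by
#' Benjamini-Hochberg across the elements tested in the run.
#'
#' @param dmrs,background `GRanges` as in [enrichElement()].
#' @param catalog named list of element `GRanges` (e.g. from
#'   [buildChromatinElements()]).
#' @param alternative `"greater"` or `"less"`, recycled over elements.
#' @return data.frame with one row per element: overlap counts, `obs_exp`,
#'   `p`, `padj` and `neg_log10_padj`.
#' @export
enrichCatalog <- function(dmrs, background, catalog,
                          alternative = "greater") {
    alternative <- rep_len(alternative, length(catalog))
    rows <- lapply(seq_along(catalog), function(i)
        cbind(element = names(catalog)[i],
              enrichElement(dmrs, background, catalog[[i]], alternative[i])))
    out <- do.call(rbind, rows)
    out$padj <- p.adjust(out$p, "BH")
    out$neg_log10_padj <- -log10(out$padj)
    out
}
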