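GR <- function(chrom, start, end, strand = NULL, ...) {
    if (is.null(strand))
        GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
    else
        GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand, ...)
}

test_that("promoters run 5 kb upstream to 100 bp past the TSS", {
    genes <- GR("chr1", c(10001, 5001), c(20000, 10000), c("+", "-"))
    p <- buildPromoters(genes)
    ## plus strand, TSS at 10001: [5001, 10100]
    expect_equal(GenomicRanges::start(p)[1], 5001)
    expect_equal(GenomicRanges::end(p)[1], 10100)
    ## minus strand, TSS at 10000: [9901, 15000]
    expect_equal(GenomicRanges::start(p)[2], 9901)
    expect_equal(GenomicRanges::end(p)[2], 15000)
    ## clipped at the chromosome start
    pc <- buildPromoters(GR("chr1", 101, 5000, "+"))
    expect_equal(GenomicRanges::start(pc), 1)
    expect_error(buildPromoters(GR("chr1", 1, 10, "*")), "strand")
})

test_that("CGI classification applies promoter > gene > intergenic", {
    genes <- GR("chr1", 10000, 30000, "+")
    proms <- buildPromoters(genes)
    cgis <- GR("chr1", c(9900, 20000, 50000), c(10300, 20400, 50400))
    cls <- classifyCGIs(cgis, proms, genes)
    ## first CGI overlaps both promoter and gene body: promoter wins
    expect_equal(GenomicRanges::start(cls$promoter), 9900)
    expect_equal(GenomicRanges::start(cls$gene), 20000)
    expect_equal(GenomicRanges::start(cls$intergenic), 50000)
    ## classes are disjoint and exhaustive
    expect_equal(sum(lengths(cls)), length(cgis))
})

test_that("chromatin element rules are applied literally", {
    genes <- GR("chr1", 50000, 90000, "+", gene_id = "g1")
    proms <- buildPromoters(genes)
    cgis <- GR("chr1", c(49900, 70000), c(50300, 70500))
    peaks <- list(
        ## enhancer pair inside the gene + a distal pair far away
        H3K4me1 = GR("chr1", c(70100, 200000), c(70300, 200200)),
        H3K27ac = GR("chr1", c(70150, 200150), c(70450, 200350)),
        ## one K4me3 near K9ac on the promoter, one 150 bp away from K9ac
        H3K4me3 = GR("chr1", c(49800, 300000), c(50200, 300400)),
        H3K9ac = GR("chr1", c(49850, 300550), c(50250, 300900)),
        ## narrow K27me3 on the promoter; 4000 bp K27me3 on a promoter;
        ## broad K27me3 mid-gene
        H3K27me3 = GR("chr1", c(46000, 400000), c(47000, 404000)),
        coChIP = GR("chr1", 70100, 70200))
    ## a second gene whose promoter holds the 4 kb K27me3 mark
    genes2 <- c(genes, GR("chr1", 405000, 420000, "+", gene_id = "g2"))
    proms2 <- buildPromoters(genes2)
    cat <- buildChromatinElements(peaks, proms2, genes2, cgis)
    expect_equal(GenomicRanges::start(cat$enhancer_geneic), 70100)
    expect_equal(GenomicRanges::start(cat$enhancer_distal), 200000)
    ## K4me3 150 bp from its K9ac is not an active promoter
    expect_equal(GenomicRanges::start(cat$active_promoter), 49800)
    ## the 4000 bp K27me3 fails the < 3.5 kb narrowness rule
    expect_equal(GenomicRanges::start(cat$repressive_promoter), 46000)
    expect_false(400000 %in% GenomicRanges::start(cat$repressive_promoter))
    ## promoter precedence keeps the repressive classes disjoint
    expect_false(any(IRanges::overlapsAny(cat$repressive_geneic, proms2)))
    ## bivalent: CGI under the coChIP peak
    expect_equal(GenomicRanges::start(cat$bivalent_cgi), 70000)
    expect_error(buildChromatinElements(peaks[-1], proms2, genes2, cgis),
                 "H3K4me1")
    ## idempotent
    expect_identical(cat, buildChromatinElements(peaks, proms2, genes2, cgis))
})

test_that("enrichment arithmetic and Fisher tail match the oracles", {
    ## k=4 of 10 DMRs overlap, K=100 of 1000 bins: obs/exp = 4
    bins <- GR("chr1", seq(1, by = 1000, length.out = 1000),
               seq(501, by = 1000, length.out = 1000))
    element <- bins[1:100]
    dmrs <- c(bins[1:4], bins[101:106])
    row <- enrichElement(dmrs, bins, element)
    expect_equal(row$n_dmr_overlap, 4)
    expect_equal(row$n_background_overlap, 100)
    expect_equal(row$obs_exp, 4)
    expect_equal(row$p,
                 fisher.test(matrix(c(4, 6, 100, 900), 2, byrow = TRUE),
                             alternative = "greater")$p.value)
    ## one-sided Fisher equals the hypergeometric tail on random tables
    set.seed(3)
    for (i in 1:50) {
        a <- sample(0:8, 1); b <- sample(0:8, 1)
        c_ <- sample(0:8, 1); d <- sample(0:8, 1)
        p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                         alternative = "greater")$p.value
        expect_equal(p, phyper(a - 1, a + b, c_ + d, a + c_,
                               lower.tail = FALSE), tolerance = 1e-12)
    }
    ## empty element: ratio undefined
    expect_true(is.na(enrichElement(dmrs, bins, GR("chr1", 1, 2)[0])$obs_exp))
})

test_that("catalog enrichment detects bias and flips for depletion", {
    set.seed(11)
    bins <- GR("chr1", seq(1, by = 1000, length.out = 2000),
               seq(501, by = 1000, length.out = 2000))
    inEl <- seq_len(2000) <= 200
    element <- bins[inEl]
    ## biased DMRs: 5x preference for element bins
    w <- ifelse(inEl, 5, 1)
    dmrs <- bins[sample(2000, 80, prob = w)]
    out <- enrichCatalog(dmrs, bins, list(el = element, other = bins[1500:1600]))
    expect_gt(out$obs_exp[out$element == "el"], 2)
    expect_lt(out$padj[out$element == "el"], 0.05)
    ## depletion of the same element is caught with the flipped side
    dep <- bins[sample(which(!inEl), 80)]
    outDep <- enrichCatalog(dep, bins, list(el = element),
                            alternative = "less")
    expect_lt(outDep$p, 0.05)
})
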