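## tiny TG fixture: two species, two samples
tinyTG <- function() data.frame(species = c("TG52:2", "TG54:3"),
                                carbons = c(52L, 54L),
                                double_bonds = c(2L, 3L),
                                s1 = c(30, 70), s2 = c(10, 30))

test_that("normalization yields percentages and flags odd carbons", {
    rel <- normalizeTG(tinyTG())
    expect_equal(rel$s1, c(30, 70))
    expect_equal(rel$s2, c(25, 75))
    one <- normalizeTG(data.frame(carbons = 52L, double_bonds = 2L, s1 = 3))
    expect_equal(one$s1, 100)
    bad <- tinyTG(); bad$s1 <- c(0, 0)
    expect_error(normalizeTG(bad), "s1")
    odd <- rbind(tinyTG(),
                 data.frame(species = "TG51:1", carbons = 51L,
                            double_bonds = 1L, s1 = 5, s2 = 5))
    expect_warning(out <- normalizeTG(odd), "odd-carbon")
    expect_equal(nrow(out), 3L)  # retained, not dropped
})

test_that("aggregation conserves mass along either axis", {
    rel <- normalizeTG(tinyTG())
    byC <- aggregateBy(rel, "carbons")
    expect_equal(byC$carbons, c(52L, 54L))
    expect_equal(byC$s1, c(30, 70))
    byD <- aggregateBy(rel, "double_bonds")
    expect_equal(byD$s2, c(25, 75))
    ## columns sum to 100 exactly on a full simulated table
    tg <- simulateTGTable(seed = 6)
    agg <- aggregateBy(normalizeTG(tg$abundance), "carbons")
    expect_equal(unname(colSums(as.matrix(agg[, -1]))),
                 rep(100, ncol(agg) - 1))
    ## aggregation is invariant to species row order
    set.seed(1)
    shuf <- tg$abundance[sample(nrow(tg$abundance)), ]
    expect_equal(aggregateBy(normalizeTG(shuf), "carbons"), agg)
})

test_that("per-category ANOVA matches t-test algebra and handles ties", {
    ## two equal-sized groups: F = t^2
    set.seed(2)
    mat <- data.frame(carbons = 52L,
                      a1 = rnorm(1), a2 = rnorm(1), a3 = rnorm(1),
                      b1 = rnorm(1), b2 = rnorm(1), b3 = rnorm(1))
    ## build 5 categories to make the fixture non-trivial
    mat <- do.call(rbind, lapply(1:5, function(i) {
        m <- mat; m$carbons <- 50L + 2L * i
        m[-1] <- rnorm(6); m
    }))
    grp <- rep(c("A", "B"), each = 3)
    out <- perCategoryTest(mat, grp)
    for (i in 1:5) {
        y <- as.numeric(mat[i, -1])
        tt <- t.test(y[1:3], y[4:6], var.equal = TRUE)
        expect_equal(out$anova_F[i], unname(tt$statistic)^2, tolerance = 1e-9)
        expect_equal(out$anova_p[i], tt$p.value, tolerance = 1e-9)
    }
    ## identical group values: F ~ 0
    same <- data.frame(carbons = 52L, a1 = 5, a2 = 5, a3 = 5,
                       b1 = 5, b2 = 5, b3 = 5)
    expect_lt(perCategoryTest(same, grp)$anova_F, 1e-20)
    ## Tukey columns present for the 4-group design
    tg <- simulateTGTable(seed = 3)
    agg <- aggregateBy(normalizeTG(tg$abundance), "carbons")
    g4 <- tg$samples$group[match(colnames(agg)[-1], tg$samples$sample)]
    out4 <- perCategoryTest(agg, g4)
    expect_equal(sum(grepl("^tukey_", colnames(out4))), 6L)
    ## group with < 2 samples: skipped with message
    expect_message(skip <- perCategoryTest(agg[, 1:3], c("A", "B")),
                   "skipped")
    expect_equal(nrow(skip), 0L)
})

test_that("signed-rank interval test has the exact 2^-k tail", {
    ## 8 left-tail categories all higher in group A: p = 1/256
    mat <- data.frame(carbons = seq(38L, 60L, 2L))
    set.seed(4)
    base <- 100 * exp(-(mat$carbons - 54)^2 / 32)
    for (s in c("A1", "A2")) mat[[s]] <- base * c(rep(1.3, 8), rep(0.8, 4))
    for (s in c("B1", "B2")) mat[[s]] <- base
    out <- intervalTest(mat, c("A", "A", "B", "B"), "A", "B", c(38, 52),
                        alternative = "greater")
    expect_equal(out$p, 2^-8)
    expect_equal(length(out$differences), 8L)
    expect_true(all(out$differences > 0))
    ## identical profiles: p = 1
    same <- mat; same$A1 <- same$A2 <- same$B1
    expect_equal(intervalTest(same, c("A", "A", "B", "B"), "A", "B",
                              c(38, 52))$p, 1)
    ## an interval with < 2 categories is undefined
    expect_error(intervalTest(mat, c("A", "A", "B", "B"), "A", "B",
                              c(38, 38)), "fewer than 2")
})

test_that("two-way ANOVA decomposes balanced designs exactly", {
    set.seed(5)
    age <- rep(c("young", "old"), each = 6)
    diet <- rep(rep(c("AL", "DR"), each = 3), 2)
    y <- rnorm(12, 100, 10)
    out <- tgContentInteraction(y, age, diet)
    expect_equal(rownames(out), c("age", "diet", "age:diet", "Residuals"))
    ## sums of squares add to the total
    expect_equal(sum(out$`Sum Sq`), sum((y - mean(y))^2), tolerance = 1e-9)
    ## a design with no old-DR samples has an empty cell
    expect_error(tgContentInteraction(y[1:6],
                                      c("young", "young", "young", "old",
                                        "old", "old"),
                                      c("AL", "DR", "AL", "AL", "AL", "AL")),
                 "cell")
})
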