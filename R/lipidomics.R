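## sample columns of a TG table = everything except the key columns
.tgSampleCols <- function(tab)
    setdiff(colnames(tab), c("species", "carbons", "double_bonds"))

#' Normalize TG species to percent of the total TG lipidome
#'
#' Each sample column is rescaled so species abundances sum to 100.
#' Odd-carbon species, if present, are retained and flagged with a
#' warning (the canonical chain-length grid uses even total acyl carbons
#' 38-60).
#'
#' @param tab data.frame with `carbons`, `double_bonds` and one abundance
#'   column per sample (plus optional `species`).
#' @return The table with sample columns as percentages.
#' @export
normalizeTG <- function(tab) {
    cols <- .tgSampleCols(tab)
    if (any(tab$carbons %% 2 == 1))
        warning(sprintf("%d odd-carbon species retained",
                        sum(tab$carbons %% 2 == 1)))
    for (s in cols) {
        tot <- sum(tab[[s]])
        if (!is.finite(tot) || tot <= 0)
            stop("sample '", s, "' has non-positive total abundance")
        tab[[s]] <- 100 * tab[[s]] / tot
    }
    tab
}

#' Aggregate relative abundances by chain length or saturation
#'
#' Sums per-sample relative abundances over species sharing the same
#' number of carbons (chain-length proxy) or double bonds (saturation
#' proxy). Columns of the result sum to 100 (mass conservation).
#'
#' @param tab normalized table from [normalizeTG()].
#' @param key `"carbons"` or `"double_bonds"`.
#' @return data.frame: the key column plus one percentage column per
#'   sample, ordered by category.
#' @export
aggregateBy <- function(tab, key = c("carbons", "double_bonds")) {
    key <- match.arg(key)
    cols <- .tgSampleCols(tab)
    agg <- rowsum(as.matrix(tab[cols]), tab[[key]])
    out <- data.frame(as.integer(rownames(agg)), agg, row.names = NULL,
                      check.names = FALSE)
    colnames(out)[1L] <- key
    out[order(out[[key]]), , drop = FALSE]
}

#' Per-category one-way ANOVA with Tukey HSD
#'
#' For every chain-length or saturation category, tests group differences
#' by one-way ANOVA across the four treatment groups and reports
#' Tukey-range pairwise p-values. Categories with a group below 2 samples
#' are skipped with a message.
#'
#' @param mat aggregated table from [aggregateBy()].
#' @param groups character/factor of group labels, one per sample column
#'   (in column order).
#' @return data.frame with one row per category: `anova_p`, `anova_F` and
#'   one `tukey_<A>.<B>` column per group pair.
#' @export
perCategoryTest <- function(mat, groups) {
    key <- colnames(mat)[1L]
    cols <- colnames(mat)[-1L]
    groups <- factor(groups)
    if (nlevels(groups) < 2L) stop("need at least two groups")
    if (any(table(groups) < 2L)) {
        message("group(s) with < 2 samples; all categories skipped: ",
                paste(names(which(table(groups) < 2L)), collapse = ", "))
        return(data.frame())
    }
    out <- NULL
    for (i in seq_len(nrow(mat))) {
        y <- as.numeric(mat[i, cols])
        if (var(y) < 1e-18) {
            ## degenerate category: no variation, no evidence of difference
            row <- data.frame(mat[i, key, drop = FALSE], anova_F = 0,
                              anova_p = 1, row.names = NULL)
            ## TukeyHSD labels pairs as "second-first"
            for (pr in utils::combn(levels(groups), 2, function(p)
                paste(p[2], p[1], sep = "."), simplify = TRUE))
                row[[paste0("tukey_", pr)]] <- 1
            out <- rbind(out, row)
            next
        }
        fit <- aov(y ~ groups)
        sm <- summary(fit)[[1L]]
        tk <- TukeyHSD(fit)$groups
        row <- data.frame(mat[i, key, drop = FALSE],
                          anova_F = sm$`F value`[1L],
                          anova_p = sm$`Pr(>F)`[1L], row.names = NULL)
        for (j in seq_len(nrow(tk)))
            row[[paste0("tukey_", gsub("-", ".", rownames(tk)[j]))]] <-
                tk[j, "p adj"]
        out <- rbind(out, row)
    }
    out
}

#' Paired signed-rank test on interval category means
#'
#' Averages the replicates of each condition per category, then compares
#' the two conditions over the categories of an interval (e.g. the left
#' tail 38-52 carbons vs the right tail 54-60, or 0-3 vs 4-12 double
#' bonds) with a Wilcoxon signed-rank test on the paired per-category
#' means. With k all-positive differences the exact one-sided p equals
#' `2^-k`.
#'
#' @param mat aggregated table from [aggregateBy()].
#' @param groups group label per sample column.
#' @param groupA,groupB the two conditions compared (difference is
#'   `A - B`).
#' @param interval numeric range `c(lo, hi)` of categories included
#'   (inclusive); must contain at least 2 categories.
#' @param alternative `"greater"` (A exceeds B across the interval,
#'   default), `"less"` or `"two.sided"`.
#' @return list with `p`, the `differences` of per-category means and the
#'   `categories` used.
#' @export
intervalTest <- function(mat, groups, groupA, groupB, interval,
                         alternative = c("greater", "less", "two.sided")) {
    alternative <- match.arg(alternative)
    key <- colnames(mat)[1L]
    cats <- mat[[key]]
    sel <- cats >= interval[1L] & cats <= interval[2L]
    if (sum(sel) < 2L) stop("interval contains fewer than 2 categories")
    cols <- colnames(mat)[-1L]
    groups <- as.character(groups)
    mA <- rowMeans(mat[sel, cols[groups == groupA], drop = FALSE])
    mB <- rowMeans(mat[sel, cols[groups == groupB], drop = FALSE])
    d <- mA - mB
    p <- if (all(d == 0)) 1 else
        suppressWarnings(wilcox.test(d, alternative = alternative,
                                     exact = TRUE)$p.value)
    list(p = p, differences = unname(d), categories = cats[sel])
}

#' Two-way ANOVA on total TG content
#'
#' Tests main effects of age and diet and their interaction on per-sample
#' total triglyceride content.
#'
#' @param totals numeric vector of per-sample totals.
#' @param age,diet factors (or character) of length `length(totals)`.
#' @return data.frame with rows `age`, `diet`, `age:diet`, `Residuals` and
#'   columns `Df`, `Sum Sq`, `Mean Sq`, `F value`, `Pr(>F)`.
#' @export
tgContentInteraction <- function(totals, age, diet) {
    age <- factor(age); diet <- factor(diet)
    if (any(table(age, diet) == 0L))
        stop("every age x diet cell needs at least one sample")
    fit <- aov(totals ~ age * diet)
    out <- as.data.frame(summary(fit)[[1L]])
    rownames(out) <- trimws(rownames(out))
    out
}
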