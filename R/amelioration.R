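#' Per-bin aging and diet methylation deltas
#'
#' For every bin computes, in percentage points, the aging change under
#' each diet and the between-diet difference at old age:
#' `d_age_AL = AL_old - AL_young`, `d_age_DR = DR_old - DR_young`,
#' `d_diet_old = DR_old - AL_old`. Full amelioration of an age effect
#' implies `d_diet_old = -d_age_AL` with `d_age_DR = 0`.
#'
#' @param bins A [BinSet-class] with all four group columns.
#' @param levelMethod quantitation, see [binLevels()].
#' @return data.frame with `bin_id`, coordinates and the three deltas;
#'   bins with a missing group level are dropped with a message.
#' @export
computeDeltas <- function(bins, levelMethod = "mean") {
    if (!all(.GROUPS %in% colnames(bins)))
        stop("bins must carry all four group levels")
    lv <- binLevels(bins, levelMethod)
    gr <- rowRanges(bins)
    out <- data.frame(
        bin_id = rowData(bins)$bin_id,
        chrom = as.character(seqnames(gr)), start = start(gr), end = end(gr),
        d_age_AL = lv[, "AL_old"] - lv[, "AL_young"],
        d_age_DR = lv[, "DR_old"] - lv[, "DR_young"],
        d_diet_old = lv[, "DR_old"] - lv[, "AL_old"], row.names = NULL)
    ok <- is.finite(out$d_age_AL) & is.finite(out$d_age_DR) &
        is.finite(out$d_diet_old)
    if (!all(ok))
        message(sprintf("dropped %d bin(s) with missing group levels",
                        sum(!ok)))
    out[ok, , drop = FALSE]
}

#' Ordinary least squares fit with Pearson correlation
#'
#' @param x,y numeric vectors (>= 3 finite pairs; `x` must vary).
#' @return list with `slope`, `intercept`, `r` and `residuals`.
#' @export
fitScatter <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("need at least 3 finite pairs")
    if (sd(x) == 0) stop("zero variance in x; fit undefined")
    fit <- lm(y ~ x)
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         r = cor(x, y), residuals = unname(residuals(fit)))
}

## degenerate-safe fit used inside permutations: a permuted delta vector
## with zero variance yields slope = r = 0 rather than an error
.fitSafe <- function(x, y) {
    if (length(x) < 3L || sd(x) == 0 || sd(y) == 0)
        return(list(slope = 0, intercept = mean(y), r = 0))
    fitScatter(x, y)[c("slope", "intercept", "r")]
}

#' Permutation nulls for the amelioration regression
#'
#' Shuffles the four group levels independently per bin under one of three
#' schemes, then recomputes the deltas and both regressions
#' (`d_diet_old` on `d_age_AL` and on `d_age_DR`):
#' * `all_labels`: a uniformly random permutation of the four labels per
#'   bin (a noise-only relationship);
#' * `across_age_within_diet`: independent per-bin coin-flip swaps of
#'   young/old inside each diet (removes age effects, keeps diet effects);
#' * `across_diet_within_age`: per-bin coin-flip swaps of AL/DR inside
#'   each age (removes diet effects, keeps age effects).
#'
#' @param bins A [BinSet-class] with all four groups.
#' @param scheme permutation scheme (see above).
#' @param nPerm number of permutations (default 100).
#' @param seed RNG seed.
#' @param levelMethod quantitation, see [binLevels()].
#' @return data.frame with one row per permutation: `scheme`, `perm`,
#'   `slope_AL`, `r_AL`, `slope_DR`, `r_DR`.
#' @export
permuteNull <- function(bins, scheme = c("all_labels",
                                         "across_age_within_diet",
                                         "across_diet_within_age"),
                        nPerm = 100L, seed = 1L, levelMethod = "mean") {
    scheme <- match.arg(scheme)
    stopifnot(nPerm >= 1L)
    lv <- binLevels(bins, levelMethod)[, .GROUPS, drop = FALSE]
    lv <- lv[apply(is.finite(lv), 1, all), , drop = FALSE]
    n <- nrow(lv)
    set.seed(seed)
    out <- vector("list", nPerm)
    for (p in seq_len(nPerm)) {
        perm <- lv
        if (scheme == "all_labels") {
            key <- matrix(runif(n * 4L), n, 4L)
            ord <- t(apply(key, 1L, order))
            for (j in 1:4) perm[, j] <- lv[cbind(seq_len(n), ord[, j])]
        } else if (scheme == "across_age_within_diet") {
            sAL <- runif(n) < 0.5; sDR <- runif(n) < 0.5
            perm[sAL, c("AL_young", "AL_old")] <- lv[sAL, c("AL_old", "AL_young")]
            perm[sDR, c("DR_young", "DR_old")] <- lv[sDR, c("DR_old", "DR_young")]
        } else {
            sY <- runif(n) < 0.5; sO <- runif(n) < 0.5
            perm[sY, c("AL_young", "DR_young")] <- lv[sY, c("DR_young", "AL_young")]
            perm[sO, c("AL_old", "DR_old")] <- lv[sO, c("DR_old", "AL_old")]
        }
        dAgeAL <- perm[, "AL_old"] - perm[, "AL_young"]
        dAgeDR <- perm[, "DR_old"] - perm[, "DR_young"]
        dDiet <- perm[, "DR_old"] - perm[, "AL_old"]
        fAL <- .fitSafe(dAgeAL, dDiet); fDR <- .fitSafe(dAgeDR, dDiet)
        out[[p]] <- data.frame(scheme = scheme, perm = p,
                               slope_AL = fAL$slope, r_AL = fAL$r,
                               slope_DR = fDR$slope, r_DR = fDR$r)
    }
    do.call(rbind, out)
}

#' Classify age-related DMRs as ameliorated by dietary restriction
#'
#' An age-related DMR is called ameliorated when its old-age diet
#' difference scatters from the DR aging fit by more than `2 * sigma`,
#' where `sigma` estimates the naturally random scatter as the standard
#' deviation of the residuals of the AL aging fit. The hyper/hypo split
#' follows the DMR's age direction under AL.
#'
#' @param ageDmrs data.frame from [callDMRs()] for the `age_AL` contrast
#'   (only rows with `dmr == TRUE` are classified).
#' @param deltas data.frame from [computeDeltas()].
#' @param fitDR list with `slope` and `intercept` (the DR aging fit).
#' @param sigma residual standard deviation of the AL aging fit.
#' @return data.frame of age-related DMRs with `residual_DR`, the
#'   `ameliorated` flag and `direction`.
#' @export
classifyAmeliorated <- function(ageDmrs, deltas, fitDR, sigma) {
    stopifnot(sigma >= 0)
    d <- dmrSet(ageDmrs)
    if (!nrow(d))
        return(data.frame(bin_id = character(0), residual_DR = numeric(0),
                          ameliorated = logical(0), direction = character(0)))
    j <- match(d$bin_id, deltas$bin_id)
    keep <- !is.na(j)
    d <- d[keep, , drop = FALSE]; j <- j[keep]
    resid <- deltas$d_diet_old[j] -
        (fitDR$intercept + fitDR$slope * deltas$d_age_DR[j])
    data.frame(bin_id = d$bin_id, chrom = d$chrom, start = d$start,
               end = d$end, delta_age = d$delta, residual_DR = resid,
               ameliorated = abs(resid) > 2 * sigma,
               direction = d$direction, row.names = NULL)
}

#' Full amelioration analysis
#'
#' Runs the complete procedure: per-bin deltas, the two regressions of the
#' old-age diet difference on the aging change under AL and under DR,
#' `sigma` from the AL-fit residuals (over all bins by default, or over
#' age-DMR bins only), classification of age-related DMRs beyond the
#' `2 * sigma` cutoff from the DR fit, and (optionally) the three
#' permutation-null distributions.
#'
#' @param bins A [BinSet-class] with all four groups.
#' @param ageDmrs data.frame from [callDMRs()] for the `age_AL` contrast.
#' @param nPerm permutations per scheme (0 skips permutations).
#' @param seed RNG seed for the permutations.
#' @param sigmaScope `"all"` (genome-wide residual scatter, default) or
#'   `"dmr"` (AL-fit residuals over age-DMR bins only).
#' @param levelMethod quantitation, see [binLevels()].
#' @return An [AmeliorationResult-class] object.
#' @export
ameliorationAnalysis <- function(bins, ageDmrs, nPerm = 100L, seed = 1L,
                                 sigmaScope = c("all", "dmr"),
                                 levelMethod = "mean") {
    sigmaScope <- match.arg(sigmaScope)
    deltas <- computeDeltas(bins, levelMethod)
    fitAL <- fitScatter(deltas$d_age_AL, deltas$d_diet_old)
    fitDR <- fitScatter(deltas$d_age_DR, deltas$d_diet_old)
    res <- fitAL$residuals
    if (sigmaScope == "dmr") {
        inDmr <- deltas$bin_id %in% dmrSet(ageDmrs)$bin_id
        if (sum(inDmr) < 3L) stop("too few age-DMR bins for sigmaScope='dmr'")
        res <- res[inDmr]
    }
    sigma <- sd(res)
    amel <- classifyAmeliorated(ageDmrs, deltas,
                                fitDR[c("slope", "intercept")], sigma)
    perms <- if (nPerm > 0L)
        do.call(rbind, lapply(c("all_labels", "across_age_within_diet",
                                "across_diet_within_age"),
                              function(s) permuteNull(bins, s, nPerm, seed,
                                                      levelMethod)))
    else data.frame()
    new("AmeliorationResult", deltas = deltas,
        fitAL = fitAL[c("slope", "intercept", "r")],
        fitDR = fitDR[c("slope", "intercept", "r")],
        sigma = sigma, cutoff = 2 * sigma, ameliorated = amel, perms = perms)
}

#' Accessors for amelioration results
#'
#' @param x An [AmeliorationResult-class] object.
#' @return `amelioratedDMRs()` returns the classified age-DMR data.frame
#'   (all rows, with the `ameliorated` flag); `ameliorationFits()` the two
#'   fits; `ameliorationSigma()` the `c(sigma, cutoff)` pair;
#'   `permutationNull()` the permutation data.frame.
#' @name amelioration-accessors
#' @export
amelioratedDMRs <- function(x) x@ameliorated

#' @rdname amelioration-accessors
#' @export
ameliorationFits <- function(x) list(AL = x@fitAL, DR = x@fitDR)

#' @rdname amelioration-accessors
#' @export
ameliorationSigma <- function(x) c(sigma = x@sigma, cutoff = x@cutoff)

#' @rdname amelioration-accessors
#' @export
permutationNull <- function(x) x@perms

#' @describeIn AmeliorationResult-class compact display
#' @param object An `AmeliorationResult` object.
#' @export
setMethod("show", "AmeliorationResult", function(object) {
    a <- object@ameliorated
    cat(sprintf("AmeliorationResult: %d bins; sigma = %.3f (cutoff %.3f)\n",
                nrow(object@deltas), object@sigma, object@cutoff))
    cat(sprintf("  fit AL: slope %.3f, r %.3f | fit DR: slope %.3f, r %.3f\n",
                object@fitAL$slope, object@fitAL$r,
                object@fitDR$slope, object@fitDR$r))
    cat(sprintf("  ameliorated DMRs: %d of %d age-related (%d hypo, %d hyper)\n",
                sum(a$ameliorated), nrow(a),
                sum(a$ameliorated & a$direction == "hypo"),
                sum(a$ameliorated & a$direction == "hyper")))
})
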