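test_that("per-bin deltas follow the sign conventions", {
    lv <- rbind(c(70, 80, 70, 70),   # age effect under AL, fully ameliorated
                c(60, 60, 60, 60),   # flat
                c(50, 70, 50, 70))   # equal aging in both diets
    colnames(lv) <- GROUPS
    d <- computeDeltas(binSetFrom(lv))
    expect_equal(d$d_age_AL, c(10, 0, 20))
    expect_equal(d$d_age_DR, c(0, 0, 20))
    expect_equal(d$d_diet_old, c(-10, 0, 0))
    ## full amelioration: d_diet_old = -d_age_AL
    expect_equal(d$d_diet_old[1], -d$d_age_AL[1])
})

test_that("fitScatter is ordinary least squares with Pearson r", {
    x <- c(1, 2, 3, 4)
    f <- fitScatter(x, -x)
    expect_equal(f$slope, -1)
    expect_equal(f$r, -1)
    expect_equal(f$intercept, 0)
    expect_error(fitScatter(rep(1, 5), rnorm(5)), "zero variance")
    expect_error(fitScatter(1:2, 1:2), "at least 3")
    ## independent x and y: negligible correlation at large n
    set.seed(1)
    f2 <- fitScatter(rnorm(1e4), rnorm(1e4))
    expect_lt(abs(f2$r), 0.05)
})

test_that("2-sigma classification matches hand computation", {
    ## age DMRs with known residuals from a given DR fit and sigma = 2
    ageDmrs <- data.frame(bin_id = c("b1", "b2", "b3"),
                          chrom = "chr1", start = c(1, 100, 200),
                          end = c(50, 150, 250), delta = c(20, 15, -12),
                          direction = c("hyper", "hyper", "hypo"),
                          dmr = TRUE)
    deltas <- data.frame(bin_id = c("b1", "b2", "b3"),
                         d_age_DR = c(0, 0, 0),
                         d_diet_old = c(-10, -3, 5))
    fit <- list(slope = 0, intercept = 0)
    got <- classifyAmeliorated(ageDmrs, deltas, fit, sigma = 2)
    ## residuals are -10, -3, 5; cutoff 4 flags bins 1 and 3
    expect_equal(got$residual_DR, c(-10, -3, 5))
    expect_equal(got$ameliorated, c(TRUE, FALSE, TRUE))
    expect_equal(got$direction, c("hyper", "hyper", "hypo"))
    ## sample standard deviation convention: sd(c(-2, 0, 2)) = 2
    expect_equal(sd(c(-2, 0, 2)), 2)
    ## empty DMR set
    none <- classifyAmeliorated(ageDmrs[0, ], deltas, fit, 2)
    expect_equal(nrow(none), 0L)
})

test_that("amelioration classification separates planted structure", {
    ## 400 noise bins + 20 strongly ameliorated + 20 plain age bins,
    ## constructed directly at the level scale
    set.seed(5)
    n <- 400
    lv <- levelMatrix(c(70, 70, 70, 70), n, noiseSd = 1, seed = 5)
    e <- runif(20, 15, 30)
    amel <- cbind(AL_young = 50, AL_old = 50 + e, DR_young = 50,
                  DR_old = 50 + 0.1 * e)
    plain <- cbind(AL_young = 50, AL_old = 50 + e, DR_young = 50,
                   DR_old = 50 + e)
    all <- rbind(lv, amel, plain)
    b <- binSetFrom(all, round(all * 45), round((100 - all) * 45))
    dm <- callDMRs(b, "age_AL")
    am <- ameliorationAnalysis(b, dm, nPerm = 0)
    flags <- amelioratedDMRs(am)
    amelIds <- sprintf("b%05d", n + 1:20)
    plainIds <- sprintf("b%05d", n + 21:40)
    got <- flags$bin_id[flags$ameliorated]
    expect_true(all(amelIds %in% got))
    expect_false(any(plainIds %in% got))
    ## the flagged set is unchanged by appending flat bins
    flat <- matrix(rep(80, 4 * 50), 50, dimnames = list(NULL, GROUPS))
    all2 <- rbind(all, flat)
    b2 <- binSetFrom(all2, round(all2 * 45), round((100 - all2) * 45))
    am2 <- ameliorationAnalysis(b2, callDMRs(b2, "age_AL"), nPerm = 0)
    f2 <- amelioratedDMRs(am2)
    expect_setequal(f2$bin_id[f2$ameliorated], got)
    ## ... and by shuffling bin order
    set.seed(9)
    perm <- sample(nrow(b))
    am3 <- ameliorationAnalysis(b[perm, ], callDMRs(b[perm, ], "age_AL"),
                                nPerm = 0)
    f3 <- amelioratedDMRs(am3)
    expect_setequal(f3$bin_id[f3$ameliorated], got)
    ## hyper/hypo split mirrors the age direction exactly
    expect_equal(flags$direction,
                 ifelse(flags$delta_age > 0, "hyper", "hypo"))
})

test_that("permutation schemes erase the targeted effects", {
    ## degenerate input: all four levels identical per bin
    lv <- levelMatrix(c(70, 70, 70, 70), 100, noiseSd = 0, seed = 1)
    lv <- lv + rnorm(100)  # bin-to-bin variation, none within bins
    b <- binSetFrom(lv)
    pm <- permuteNull(b, "all_labels", nPerm = 5, seed = 1)
    expect_equal(pm$slope_AL, rep(0, 5))
    expect_equal(pm$slope_DR, rep(0, 5))
    ## noise-only data: every scheme reproduces the analytic shared-term
    ## baseline (the aging and diet deltas share AL_old / DR_old, giving
    ## slopes of exactly -1/2 and +1/2 under label noise)
    lv2 <- levelMatrix(c(70, 70, 70, 70), 400, noiseSd = 2, seed = 3)
    b2 <- binSetFrom(lv2)
    for (s in c("all_labels", "across_age_within_diet",
                "across_diet_within_age")) {
        pm2 <- permuteNull(b2, s, nPerm = 30, seed = 2)
        expect_lt(abs(median(pm2$slope_AL) + 0.5), 0.1)
        expect_lt(abs(median(pm2$slope_DR) - 0.5), 0.1)
    }
    expect_error(permuteNull(b2, "bogus"), "arg")
    ## planted amelioration sits outside all three null envelopes
    set.seed(8)
    e <- runif(30, 15, 30)
    amel <- cbind(AL_young = 50, AL_old = 50 + e, DR_young = 50,
                  DR_old = 50 + 0.1 * e)
    lv3 <- rbind(levelMatrix(c(70, 70, 70, 70), 300, 1, seed = 6), amel)
    b3 <- binSetFrom(lv3)
    obs <- fitScatter(computeDeltas(b3)$d_age_DR,
                      computeDeltas(b3)$d_diet_old)
    for (s in c("all_labels", "across_age_within_diet",
                "across_diet_within_age")) {
        pm3 <- permuteNull(b3, s, nPerm = 50, seed = 4)
        expect_true(obs$slope < quantile(pm3$slope_DR, 0.025) |
                    obs$slope > quantile(pm3$slope_DR, 0.975))
    }
})

test_that("sigma tracks the noise floor as depth grows", {
    mkb <- function(noise) {
        lv <- levelMatrix(c(75, 75, 75, 75), 500, noiseSd = noise, seed = 4)
        binSetFrom(lv)
    }
    amLo <- ameliorationAnalysis(mkb(3), callDMRs(mkb(3), "age_AL"), nPerm = 0)
    amHi <- ameliorationAnalysis(mkb(0.3), callDMRs(mkb(0.3), "age_AL"),
                                 nPerm = 0)
    expect_lt(ameliorationSigma(amHi)["sigma"],
              ameliorationSigma(amLo)["sigma"] / 5)
})
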