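# Binomial release-probability estimation, trial planning, facilitation and
# epoch comparison.

test_that("the binomial SE formula holds across a grid and at the boundaries", {
    for (n in c(10L, 20L, 30L, 50L)) {
        for (k in unique(c(0L, 1L, n %/% 4, n %/% 2, n - 1L, n))) {
            est <- prEstimateFromCounts(k, n)
            p <- k / n
            expect_equal(standardError(est), sqrt(p * (1 - p) / n))
            # symmetry: SE(p) = SE(1 - p)
            expect_equal(standardError(est),
                standardError(prEstimateFromCounts(n - k, n)))
        }
    }
    expect_equal(standardError(prEstimateFromCounts(0L, 20L)), 0)
    expect_equal(standardError(prEstimateFromCounts(20L, 20L)), 0)
    # maximal at p = 0.5
    ses <- vapply(0:30, function(k) {
        standardError(prEstimateFromCounts(k, 30L))
    }, 0)
    expect_identical(which.max(ses) - 1L, 15L)
})

test_that("estimatePr counts pulse-1 successes only and itemizes exclusions", {
    est <- estimatePr(mkCalls(15, 30, k2 = 28))
    expect_equal(prHat(est), 0.5)
    expect_equal(nTrials(est), 30L)
    expect_equal(standardError(est), sqrt(0.25 / 30))

    zero <- estimatePr(mkCalls(0, 20))
    expect_equal(prHat(zero), 0)
    expect_equal(standardError(zero), 0)

    calls <- mkCalls(10, 20)
    calls$excluded[1:4] <- TRUE
    calls$success[1:4] <- NA
    calls$exclusion_reason[1:4] <- "contaminated"
    est2 <- estimatePr(calls)
    expect_equal(nTrials(est2), 16L)
    expect_equal(nSuccess(est2), 6L)
    expect_equal(est2@nExcluded, 4L)
    expect_identical(est2@exclusionReasons, c(contaminated = 4L))

    allOut <- mkCalls(0, 3)
    allOut$excluded <- TRUE
    allOut$success <- NA
    expect_error(estimatePr(allOut), class = "epscat_estimation_error")
})

test_that("confidence intervals agree with their reference implementations", {
    for (kn in list(c(15L, 30L), c(2L, 25L), c(0L, 20L), c(30L, 30L))) {
        k <- kn[1]; n <- kn[2]
        wilson <- prEstimateFromCounts(k, n, "wilson")
        ref <- suppressWarnings(
            prop.test(k, n, correct = FALSE)$conf.int)
        expect_equal(unname(confInt(wilson)), as.numeric(ref))
        cp <- prEstimateFromCounts(k, n, "clopper-pearson")
        expect_equal(unname(confInt(cp)),
            as.numeric(binom.test(k, n)$conf.int))
        wald <- prEstimateFromCounts(k, n, "wald")
        p <- k / n
        z <- qnorm(0.975)
        expect_equal(unname(confInt(wald)), c(
            max(0, p - z * sqrt(p * (1 - p) / n)),
            min(1, p + z * sqrt(p * (1 - p) / n))))
        expect_true(confInt(wilson)[1] <= p && p <= confInt(wilson)[2])
    }
})

test_that("the estimate is invariant to trial ordering", {
    calls <- mkCalls(11, 30)
    set.seed(1)
    shuffled <- calls[sample.int(nrow(calls)), ]
    a <- estimatePr(calls)
    b <- estimatePr(shuffled)
    expect_equal(prHat(a), prHat(b))
    expect_equal(confInt(a), confInt(b))
})

test_that("the trial planner inverts the SE formula", {
    expect_identical(requiredTrials(0.5, 0.1), 25L)
    expect_identical(requiredTrials(0.1, 0.1), 9L)
    expect_identical(requiredTrials(0.5, 1e6), 1L)
    for (p in seq(0.05, 0.95, by = 0.1)) {
        for (se in c(0.02, 0.05, 0.1, 0.2)) {
            n <- requiredTrials(p, se)
            expect_lte(sqrt(p * (1 - p) / n), se + 1e-12)
            if (n > 1L) expect_gt(sqrt(p * (1 - p) / (n - 1L)), se - 1e-12)
        }
    }
    expect_error(requiredTrials(0, 0.1), "pr_guess")
    expect_error(requiredTrials(0.5, 0), "target_se")
})

test_that("facilitation reports per-pulse proportions and their ratio", {
    fac <- facilitation(mkCalls(6, 20, k2 = 12))
    expect_equal(fac@p1Hat, 0.3)
    expect_equal(fac@p2Hat, 0.6)
    expect_equal(ppr(fac), 2)

    same <- facilitation(mkCalls(9, 20, k2 = 9))
    expect_equal(ppr(same), 1)

    none <- facilitation(mkCalls(0, 20, k2 = 10))
    expect_true(is.na(ppr(none)))

    expect_error(facilitation(mkCalls(5, 20)),
        class = "epscat_protocol_error")
})

test_that("epoch comparison reports the difference and a calibrated test", {
    a <- prEstimateFromCounts(6L, 30L)
    b <- prEstimateFromCounts(24L, 30L)
    cmp <- comparePr(a, b)
    expect_equal(cmp@deltaPr, 0.6)
    expect_equal(cmp@se, sqrt(a@se^2 + b@se^2))
    expect_equal(cmp@pValue, fisher.test(matrix(c(24, 6, 6, 24), 2,
        byrow = TRUE))$p.value)
    expect_identical(cmp@direction, "potentiation")
    expect_identical(comparePr(b, a)@direction, "depression")

    id <- comparePr(a, a)
    expect_equal(id@deltaPr, 0)
    expect_identical(id@direction, "no-change")

    z <- comparePr(a, b, method = "z")
    expect_equal(z@pValue, suppressWarnings(
        prop.test(c(24, 6), c(30, 30), correct = FALSE)$p.value))
})

test_that("the null comparison rejects at close to the nominal rate", {
    set.seed(1234)
    nRep <- 2000
    k1 <- rbinom(nRep, 30, 0.3)
    k2 <- rbinom(nRep, 30, 0.3)
    pvalZ <- vapply(seq_len(nRep), function(i) {
        comparePr(prEstimateFromCounts(k1[i], 30L),
            prEstimateFromCounts(k2[i], 30L), method = "z")@pValue
    }, 0)
    rateZ <- mean(pvalZ < 0.05, na.rm = TRUE)
    expect_lt(abs(rateZ - 0.05), 0.02)
    pvalF <- vapply(seq_len(nRep), function(i) {
        comparePr(prEstimateFromCounts(k1[i], 30L),
            prEstimateFromCounts(k2[i], 30L))@pValue
    }, 0)
    expect_lte(mean(pvalF < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / nRep))
})

test_that("the estimator recovers the generating proportion across replicates", {
    set.seed(777)
    nRep <- 500
    pr <- vapply(rbinom(nRep, 30, 0.35), function(k) {
        prHat(prEstimateFromCounts(k, 30L))
    }, 0)
    expect_lt(abs(mean(pr) - 0.35),
        3 * sqrt(0.35 * 0.65 / 30) / sqrt(nRep))
    expect_lt(abs(sd(pr) / sqrt(0.35 * 0.65 / 30) - 1), 0.15)
})
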