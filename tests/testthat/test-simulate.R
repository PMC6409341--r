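# Synthetic line-scan generator: ground-truth statistics, determinism,
# linearity of the noiseless model.

test_that("parameter validation names the violated invariant", {
    expect_error(SimParams(true_pr = 1.5), "true_pr")
    expect_error(SimParams(facilitation_factor = 0.5), "facilitation_factor")
    expect_error(SimParams(tau_rise_ms = 300), "tau_decay_ms")
    expect_error(SimParams(roi_geometry = list(
        n_pixels = 48L, spine = c(6L, 24L), dendrite = c(20L, 32L),
        background = c(36L, 46L)
    )), "disjoint")
    expect_error(SimParams(n_lines = 100), "scan too short")
    expect_error(simulateExperiment(SimParams(), 0), "n_trials")
})

test_that("degenerate probabilities give deterministic ground truth", {
    sure <- simulateExperiment(
        smallParams(true_pr = 1, amplitude_cv = 0, contamination_rate = 0,
            seed = 4), 25)
    expect_true(all(sure$truth$released_p1))
    expect_true(all(sure$truth$amplitude_p1 == 1))
    never <- simulateExperiment(
        smallParams(true_pr = 0, facilitation_factor = 1,
            contamination_rate = 0, seed = 4), 25)
    expect_false(any(never$truth$released_p1))
    expect_false(any(never$truth$released_p2))
})

test_that("release frequencies follow the binomial law at both pulses", {
    n <- 2000
    sim <- simulateExperiment(
        smallParams(true_pr = 0.5, facilitation_factor = 1, seed = 11), n)
    expect_lt(abs(mean(sim$truth$released_p1) - 0.5),
        3 * sqrt(0.25 / n))

    fac <- simulateExperiment(
        smallParams(true_pr = 0.3, facilitation_factor = 2, seed = 12), n)
    # marginal pulse-2 probability is min(1, 0.3 * 2) = 0.6
    expect_lt(abs(mean(fac$truth$released_p2) - 0.6),
        3 * sqrt(0.6 * 0.4 / n))
    expect_lt(abs(mean(fac$truth$released_p1) - 0.3),
        3 * sqrt(0.3 * 0.7 / n))
})

test_that("the same seed reproduces an experiment bit for bit", {
    p <- smallParams(true_pr = 0.4, contamination_rate = 0.1, seed = 99)
    a <- simulateExperiment(p, 8)
    b <- simulateExperiment(p, 8)
    expect_identical(a$truth, b$truth)
    for (i in seq_along(a$records)) {
        expect_identical(scanMatrix(a$records[[i]]),
            scanMatrix(b$records[[i]]))
    }
    expect_length(a$records, 8)
    expect_identical(nrow(a$truth), 8L)
    # trials are driven by distinct streams
    expect_false(identical(scanMatrix(a$records[[1]]),
        scanMatrix(a$records[[2]])))
})

test_that("noiseless expectation is the baseline in the null and scales linearly", {
    p <- smallParams(true_pr = 0, seed = 1)
    sigNull <- epscat:::.trialSignal(p, c(FALSE, FALSE), c(1, 1), FALSE, 1)
    lam <- epscat:::.trialExpectation(p, sigNull)
    spineRows <- epscat:::.span0(p@roiGeometry$spine)
    expect_true(all(lam[spineRows, ] ==
        p@backgroundLevel + p@baselinePhotonRate))

    sig1 <- epscat:::.trialSignal(p, c(TRUE, TRUE), c(0.4, 0.7), FALSE, 1)
    sig2 <- epscat:::.trialSignal(p, c(TRUE, TRUE), c(0.8, 1.4), FALSE, 1)
    expect_equal(sig2$spine, 2 * sig1$spine, tolerance = 1e-12)
    expect_equal(sig2$dendrite, 2 * sig1$dendrite, tolerance = 1e-12)
})

test_that("transient kernel peaks at 1 and is causal", {
    k <- epscatKernel(seq(-20, 400, by = 0.5), 10, 200)
    expect_equal(max(k), 1, tolerance = 1e-6)
    expect_true(all(k[seq(-20, 400, by = 0.5) < 0] == 0))
    expect_true(all(k >= 0 & k <= 1))
})

test_that("dendrite carries no release information without bleed or contamination", {
    sim <- simulateExperiment(
        smallParams(true_pr = 0.5, dendrite_bleed_fraction = 0,
            contamination_rate = 0, seed = 21), 300)
    dendMeans <- vapply(sim$records, function(r) {
        tr <- extractTrace(r, "dendrite")
        mean(dff(tr)[scanTimes(tr) >= 60 & scanTimes(tr) < 110])
    }, 0)
    rel <- sim$truth$released_p1
    expect_gt(t.test(dendMeans[rel], dendMeans[!rel])$p.value, 0.01)
})

test_that("photon counts bleach at the configured exponential rate", {
    p <- smallParams(true_pr = 0, bleach_tau_s = 0.2, seed = 31)
    sims <- simulateExperiment(p, 150)
    ratio <- mean(vapply(sims$records, function(r) {
        m <- scanMatrix(r)[epscat:::.span0(p@roiGeometry$spine), ]
        mean(m[, 111:120]) / mean(m[, 1:10])
    }, 0))
    tMid <- function(cols) mean((cols - 1) * 2) / 1000 # line period 2 ms
    expected <- exp(-(tMid(111:120) - tMid(1:10)) / 0.2)
    expect_lt(abs(ratio - expected), 0.02)
})
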