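# dF/F extraction: the normalization identity, its invariances, noise
# statistics and display smoothing.

test_that("dF/F reproduces the normalization identity exactly", {
    rec <- flatRecord(spineF = 2, bgF = 1)
    m <- scanMatrix(rec)
    m[1:3, 60] <- 3 # one line at F = 3, outside the baseline window
    rec2 <- LineScanRecord(m, 2, c(0, 3), c(3, 6), c(6, 8),
        stim_times_ms = 100, trial_id = "hand")
    tr <- extractTrace(rec2, "spine")
    expect_equal(fBaseline(tr), 2)
    expect_equal(fBackground(tr), 1)
    # (F - F_baseline) / (F_baseline - F_background) = (3 - 2) / (2 - 1)
    expect_equal(dff(tr)[60], 1)
    expect_equal(dff(tr)[10], 0)
})

test_that("a constant record yields an identically zero trace", {
    tr <- extractTrace(flatRecord(spineF = 2, bgF = 1), "spine")
    expect_true(all(dff(tr) == 0))
    expect_equal(fBaseline(tr) - fBackground(tr), 1)
    expect_equal(noiseSE(tr), 0)
})

test_that("dF/F is invariant to gain and common offset", {
    p <- smallParams(true_pr = 1, seed = 5)
    rec <- simulateTrial(p, 1)$record
    tr <- extractTrace(rec, "spine")
    gained <- LineScanRecord(7 * scanMatrix(rec), 2,
        rec@roiSpine, rec@roiDendrite, rec@roiBackground,
        stimTimes(rec), trial_id = "gained")
    expect_equal(dff(extractTrace(gained, "spine")), dff(tr),
        tolerance = 1e-12)
    shifted <- LineScanRecord(scanMatrix(rec) + 13, 2,
        rec@roiSpine, rec@roiDendrite, rec@roiBackground,
        stimTimes(rec), trial_id = "shifted")
    expect_equal(dff(extractTrace(shifted, "spine")), dff(tr),
        tolerance = 1e-12)
})

test_that("degenerate normalization and short baselines are rejected loudly", {
    dark <- flatRecord(spineF = 5, bgF = 5)
    expect_error(extractTrace(dark, "spine"),
        class = "epscat_degenerate_normalization")
    expect_error(extractTrace(dark, "spine"), "unanalyzable")
    short <- flatRecord(stim = 40) # only 40 ms of baseline
    expect_error(extractTrace(short, "spine"),
        class = "epscat_baseline_error")
})

test_that("noise statistics match a direct recomputation from the raw matrix", {
    rec <- simulateTrial(smallParams(true_pr = 0, seed = 17), 1)$record
    tr <- extractTrace(rec, "spine")
    m <- scanMatrix(rec)
    rawF <- colMeans(m[1:4, ]) # spine span [0, 4)
    fBg <- mean(m[11:12, ]) # background span [10, 12)
    fBase <- mean(rawF[1:30]) # baseline [0, 60) at 2 ms/line
    vals <- (rawF - fBase) / (fBase - fBg)
    noiseIdx <- 6:30 # noise window [10, 60)
    expect_equal(dff(tr), unname(vals), tolerance = 1e-12)
    expect_equal(noiseSE(tr), sd(vals[noiseIdx]) / sqrt(25),
        tolerance = 1e-12)
    expect_equal(tr@noiseSd, sd(vals[noiseIdx]), tolerance = 1e-12)
})

test_that("null simulator traces average to zero within noise", {
    sim <- simulateExperiment(smallParams(true_pr = 0, seed = 23), 60)
    stats <- vapply(sim$records, function(r) {
        tr <- extractTrace(r, "spine")
        idx <- scanTimes(tr) >= 60 & scanTimes(tr) < 110
        c(mean(dff(tr)[idx]), noiseSE(tr))
    }, c(0, 0))
    grand <- mean(stats[1, ])
    expect_lt(abs(grand), 3 * mean(stats[2, ]) / sqrt(ncol(stats)))
})

test_that("smoothing is display-only and behaves like a boxcar", {
    tr <- mkTrace(c(0, 0, 3, 0, 0))
    expect_identical(dff(smoothTrace(tr, width_ms = 2)), dff(tr))
    sm <- smoothTrace(tr, width_ms = 6)
    expect_equal(dff(sm)[3], 1) # centered 3-line average of [0, 3, 0]
    expect_true(sm@smoothed)
    const <- mkTrace(rep(0.4, 80))
    expect_equal(dff(smoothTrace(const, width_ms = 20)), rep(0.4, 80))
    expect_error(smoothTrace(tr, width_ms = 1), "line period")
    expect_error(callEvent(smoothTrace(mkTrace(rep(0, 100)), 6),
        stim_time_ms = 100), "smoothed")
})
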