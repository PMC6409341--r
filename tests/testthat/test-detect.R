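# Noise-scaled event calling: the 2.5x criterion, its boundary convention,
# contamination handling, and batch behavior.

test_that("null and boundary transients are called by the >= convention", {
    flat <- mkTrace(rep(0, 100), noiseSe = 0.01)
    expect_false(callEvent(flat, stim_time_ms = 100)$success)

    atBoundary <- mkTrace(
        replace(rep(0, 100), 51:75, 0.025), noiseSe = 0.01)
    callB <- callEvent(atBoundary, stim_time_ms = 100)
    expect_equal(callB$dff_transient, 0.025)
    expect_equal(callB$threshold, 0.025)
    expect_true(callB$success) # "at least" 2.5x is closed at the boundary

    justUnder <- mkTrace(
        replace(rep(0, 100), 51:75, 0.0249999), noiseSe = 0.01)
    expect_false(callEvent(justUnder, stim_time_ms = 100)$success)
})

test_that("degenerate noise, out-of-scan windows and NaNs error by class", {
    expect_error(
        callEvent(mkTrace(rep(0, 100), noiseSe = 0), stim_time_ms = 100),
        class = "epscat_degenerate_noise")
    expect_error(
        callEvent(mkTrace(rep(0, 100)), stim_time_ms = 180),
        class = "epscat_window_error")
    nan <- mkTrace(replace(rep(0, 100), 60, NaN))
    expect_error(callEvent(nan, stim_time_ms = 100),
        class = "epscat_nonfinite_error")
})

test_that("contamination screen follows the spine-versus-dendrite logic", {
    spineBig <- mkTrace(replace(rep(0, 100), 51:75, 0.5))
    dendFlat <- mkTrace(rep(0, 100), roi = "dendrite")
    cleanCall <- callEvent(spineBig, dendFlat, 100)
    expect_false(cleanCall$contaminated)
    expect_true(cleanCall$success)

    dendBig <- mkTrace(replace(rep(0, 100), 51:75, 0.5), roi = "dendrite")
    equalCall <- callEvent(spineBig, dendBig, 100,
        DetectionConfig(contamination_policy = "subtract_and_test"))
    expect_true(equalCall$contaminated)
    expect_false(equalCall$success) # equal amplitudes: excess test fails

    rejected <- callEvent(spineBig, dendBig, 100,
        DetectionConfig(contamination_policy = "reject_trial"))
    expect_true(rejected$contaminated)
    expect_true(rejected$excluded)
    expect_true(is.na(rejected$success))
    expect_identical(rejected$exclusion_reason, "contaminated")

    ignored <- callEvent(spineBig, dendBig, 100,
        DetectionConfig(contamination_policy = "off"))
    expect_true(ignored$success)

    ct <- contaminationTest(0.5, 0.5, 0.01, 0.01, DetectionConfig())
    expect_true(ct$contaminated)
    expect_false(ct$excess_significant)
    expect_equal(ct$excess_threshold, 2.5 * sqrt(2) * 0.01)
})

test_that("high-SNR calls track simulator ground truth at both pulses", {
    sim <- simulateExperiment(smallParams(true_pr = 0.5,
        facilitation_factor = 1.5, seed = 41), 60)
    calls <- callTrials(sim$records,
        DetectionConfig(p2_tail_correction = "prewindow"))
    p1 <- calls[calls$pulse == 1L, ]
    p2 <- calls[calls$pulse == 2L, ]
    # every true release event is detected (no misses at high SNR) ...
    expect_true(all(p1$success[sim$truth$released_p1]))
    expect_true(all(p2$success[sim$truth$released_p2]))
    # ... and disagreements are only the threshold's ~1% false positives on
    # no-release trials
    fp <- sum(p1$success & !sim$truth$released_p1) +
        sum(p2$success & !sim$truth$released_p2)
    expect_lte(fp, 3)
})

test_that("raising the threshold never creates successes", {
    sim <- simulateExperiment(smallParams(true_pr = 0.5,
        amplitude_dff = 0.08, seed = 43), 40)
    nSucc <- vapply(c(1, 2, 2.5, 3, 5, 8), function(mult) {
        calls <- callTrials(sim$records,
            DetectionConfig(threshold_multiple = mult,
                contamination_policy = "off"))
        sum(calls$success[calls$pulse == 1L])
    }, 0L)
    expect_true(all(diff(nSucc) <= 0))
})

test_that("batch calling is stateless over trials and robust to failures", {
    sim <- simulateExperiment(smallParams(true_pr = 0.5, seed = 47), 12)
    calls <- callTrials(sim$records)
    expect_identical(nrow(calls), 24L) # 12 trials x 2 pulses
    perm <- c(5, 1, 12, 7, 2, 3, 11, 4, 10, 8, 6, 9)
    permCalls <- callTrials(sim$records[perm])
    reord <- do.call(rbind, lapply(perm, function(i) {
        calls[calls$trial_id == sprintf("trial_%04d", i), ]
    }))
    rownames(reord) <- NULL
    expect_equal(permCalls, reord)

    expect_warning(empty <- callTrials(list()), "empty")
    expect_identical(nrow(empty), 0L)

    # a degenerate trial is excluded with its reason, not fatal
    bad <- flatRecord(spineF = 5, dendF = 5, bgF = 5, stim = 100)
    mixed <- c(sim$records[1:2], list(bad))
    expect_warning(calls2 <- callTrials(mixed), "unanalyzable")
    badRows <- calls2[calls2$trial_id == "hand", ]
    expect_true(all(badRows$excluded))
    expect_match(badRows$exclusion_reason[1], "F_baseline")
})
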