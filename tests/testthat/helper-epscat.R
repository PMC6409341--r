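# Shared fixtures, all built in code.

# Compact simulator geometry for fast unit tests: 12 pixels, 120 lines at
# 500 Hz (240 ms), stimulus at 60 ms so both 50 ms windows fit.
smallParams <- function(...) {
    SimParams(
        n_lines = 120,
        stim_onset_ms = 60,
        roi_geometry = list(
            n_pixels = 12L,
            spine = c(0L, 4L),
            dendrite = c(5L, 9L),
            background = c(10L, 12L)
        ),
        ...
    )
}

withSeed <- function(params, seed) {
    params@seed <- as.integer(seed)
    params
}

# Hand-built record: constant background, constant ROI levels, with optional
# per-line spine values. Spans: spine [0,3), dendrite [3,6), background [6,8).
flatRecord <- function(spineF = 50, dendF = 50, bgF = 5, nLines = 100,
                       periodMs = 2, stim = 100, id = "hand") {
    m <- matrix(bgF, nrow = 8, ncol = nLines)
    m[1:3, ] <- spineF
    m[4:6, ] <- dendF
    LineScanRecord(m, periodMs,
        roi_spine = c(0, 3), roi_dendrite = c(3, 6),
        roi_background = c(6, 8),
        stim_times_ms = stim, trial_id = id)
}

# Trace with fully controlled values and noise, for detector unit tests.
# 100 lines at 2 ms/line; noise window [50, 100), stimulus nominally 100 ms.
mkTrace <- function(values, noiseSe = 0.01, roi = "spine", id = "t") {
    new("Trace",
        values = values,
        timesMs = (seq_along(values) - 1) * 2,
        roiLabel = roi,
        fBaseline = 2, fBackground = 1,
        noiseSe = noiseSe, noiseSd = noiseSe * 5,
        noiseWindowMs = c(50, 100),
        trialId = id, smoothed = FALSE)
}

# Calls table with k successes at pulse 1 out of n (and optionally pulse 2).
mkCalls <- function(k1, n, k2 = NULL) {
    calls <- data.frame(
        trial_id = sprintf("t%04d", seq_len(n)),
        pulse = 1L,
        success = c(rep(TRUE, k1), rep(FALSE, n - k1)),
        excluded = FALSE,
        exclusion_reason = NA_character_,
        stringsAsFactors = FALSE
    )
    if (!is.null(k2)) {
        p2 <- calls
        p2$pulse <- 2L
        p2$success <- c(rep(TRUE, k2), rep(FALSE, n - k2))
        calls <- rbind(calls, p2)
    }
    calls
}
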