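#' Construct an event-detection configuration
#'
#' Defaults implement the standard optical quantal analysis criterion: a
#' pulse is a release success when the mean dF/F over the 50 ms window
#' starting at the stimulus is at least 2.5 times the baseline noise, where
#' noise is the standard error of the mean dF/F over the last 50 ms of
#' baseline. "At least" is closed at the boundary (>=).
#'
#' When a dendrite trace is available, trials whose dendrite transient is
#' itself significant (>= contamination_multiple times the dendrite noise)
#' are flagged as putative bAP/dendritic-spike contamination. Under the
#' default \code{subtract_and_test} policy such a trial still counts as a
#' success only if the spine transient exceeds the dendrite transient by at
#' least \code{contamination_multiple} times the pooled noise (root sum of
#' squared SEs) - the quantitative form of requiring the spine signal to
#' significantly exceed the dendrite signal. \code{reject_trial} instead
#' excludes flagged trials from both numerator and denominator; \code{off}
#' disables the screen.
#'
#' @param response_window_ms post-stimulus averaging window, ms.
#' @param threshold_multiple noise multiplier of the success criterion.
#' @param contamination_policy "subtract_and_test", "reject_trial" or "off".
#' @param contamination_multiple noise multiplier for the dendrite screen and
#'   the spine-minus-dendrite excess test.
#' @param noise_definition "se" (standard error of the windowed-mean
#'   comparison's natural scale; default) or "sd".
#' @param p2_tail_correction "none" (default) or "prewindow". With 70 ms
#'   between pulses and slow indicator decay, a pulse-1 transient is still
#'   decaying through the pulse-2 window; "prewindow" re-baselines each later
#'   pulse by subtracting the mean dF/F over the \code{prewindow_ms}
#'   immediately before its stimulus.
#' @param prewindow_ms length of that pre-stimulus window, ms.
#' @return a validated \linkS4class{DetectionConfig}.
#' @export
DetectionConfig <- function(response_window_ms = 50,
                            threshold_multiple = 2.5,
                            contamination_policy = c("subtract_and_test",
                                "reject_trial", "off"),
                            contamination_multiple = 2.5,
                            noise_definition = c("se", "sd"),
                            p2_tail_correction = c("none", "prewindow"),
                            prewindow_ms = 20) {
    obj <- try(new("DetectionConfig",
        responseWindowMs = response_window_ms,
        thresholdMultiple = threshold_multiple,
        contaminationPolicy = match.arg(contamination_policy),
        contaminationMultiple = contamination_multiple,
        noiseDefinition = match.arg(noise_definition),
        p2TailCorrection = match.arg(p2_tail_correction),
        prewindowMs = prewindow_ms
    ), silent = TRUE)
    if (inherits(obj, "try-error")) {
        .stop("epscat_config_error", "invalid DetectionConfig: %s",
            attr(obj, "condition")$message)
    }
    obj
}

.traceNoise <- function(trace, config) {
    if (config@noiseDefinition == "se") trace@noiseSe else trace@noiseSd
}

.windowMean <- function(trace, fromMs, toMs, what) {
    scanEnd <- max(trace@timesMs) + diff(trace@timesMs[1:2])
    if (toMs > scanEnd + 1e-9) {
        .stop("epscat_window_error",
            "trial '%s': %s window [%g, %g) ms extends past the end of the scan (%g ms)",
            trace@trialId, what, fromMs, toMs, scanEnd)
    }
    idx <- .windowIdx(trace@timesMs, fromMs, toMs)
    if (!length(idx)) {
        .stop("epscat_window_error",
            "trial '%s': %s window [%g, %g) ms contains no lines",
            trace@trialId, what, fromMs, toMs)
    }
    m <- mean(trace@values[idx])
    if (!is.finite(m)) {
        .stop("epscat_nonfinite_error",
            "trial '%s': non-finite dF/F inside the %s window", trace@trialId,
            what)
    }
    m
}

## Windowed transient statistic for one pulse, with optional re-baselining
## against the pre-stimulus tail of the preceding pulse.
.transientStat <- function(trace, stimMs, config, pulseIndex) {
    v <- .windowMean(trace, stimMs, stimMs + config@responseWindowMs,
        "response")
    if (pulseIndex > 1L && config@p2TailCorrection == "prewindow") {
        v <- v - .windowMean(trace, stimMs - config@prewindowMs, stimMs,
            "pre-stimulus")
    }
    v
}

#' Contamination screen and excess test
#'
#' A trial is flagged as putatively contaminated by a bAP or dendritic spike
#' when the dendrite transient is itself significant, i.e. at least
#' \code{contamination_multiple} times the dendrite noise. The excess test
#' then asks whether the spine transient significantly exceeds the dendrite
#' transient: \code{spine - dendrite >= contamination_multiple * pooled
#' noise}, with pooled noise the root sum of the squared per-trace noise
#' terms.
#'
#' @param spine_dff,dendrite_dff windowed transient statistics (mean dF/F
#'   over the response window) for the two ROIs.
#' @param spine_noise,dendrite_noise their baseline noise terms.
#' @param config a \linkS4class{DetectionConfig}.
#' @return list with logical \code{contaminated}, logical
#'   \code{excess_significant}, and numerics \code{excess} and
#'   \code{excess_threshold}.
#' @export
contaminationTest <- function(spine_dff, dendrite_dff, spine_noise,
                              dendrite_noise, config = DetectionConfig()) {
    pooled <- sqrt(spine_noise^2 + dendrite_noise^2)
    excess <- spine_dff - dendrite_dff
    list(
        contaminated = dendrite_dff >=
            config@contaminationMultiple * dendrite_noise,
        excess = excess,
        excess_threshold = config@contaminationMultiple * pooled,
        excess_significant = excess >= config@contaminationMultiple * pooled
    )
}

#' Call a release event for one pulse of one trial
#'
#' Computes the transient statistic (mean dF/F over the half-open response
#' window starting at the stimulus; the line containing the stimulus instant
#' is included), compares it with the noise-scaled threshold, and applies the
#' configured contamination policy using the dendrite trace.
#'
#' @param spine spine \linkS4class{Trace} (raw; smoothed traces are refused).
#' @param dendrite dendrite \linkS4class{Trace}, or NULL to skip the
#'   contamination screen.
#' @param stim_time_ms stimulus time, ms from scan start.
#' @param config a \linkS4class{DetectionConfig}.
#' @param pulse_index 1-based pulse number (used by the tail correction).
#' @return one-row data.frame: trial_id, pulse, dff_transient, noise_se,
#'   threshold, dendrite_dff_transient, dendrite_noise_se, contaminated,
#'   success, excluded, exclusion_reason.
#' @examples
#' sim <- simulateTrial(SimParams(true_pr = 1, seed = 2))
#' sp <- extractTrace(sim$record, "spine")
#' de <- extractTrace(sim$record, "dendrite")
#' callEvent(sp, de, stim_time_ms = stimTimes(sim$record)[1])
#' @export
callEvent <- function(spine, dendrite = NULL, stim_time_ms,
                      config = DetectionConfig(), pulse_index = 1L) {
    stopifnot(is(spine, "Trace"))
    if (spine@smoothed || (!is.null(dendrite) && dendrite@smoothed)) {
        .stop("epscat_config_error",
            "detection requires raw traces; got a smoothed trace for trial '%s'",
            spine@trialId)
    }
    noise <- .traceNoise(spine, config)
    if (!is.finite(noise) || noise <= 0) {
        .stop("epscat_degenerate_noise",
            "trial '%s': baseline noise is %.3g; cannot scale the detection threshold",
            spine@trialId, noise)
    }
    dffT <- .transientStat(spine, stim_time_ms, config, pulse_index)
    threshold <- config@thresholdMultiple * noise
    base <- dffT >= threshold

    dendDff <- NA_real_
    dendNoise <- NA_real_
    contaminated <- FALSE
    success <- base
    excluded <- FALSE
    reason <- NA_character_

    if (!is.null(dendrite) && config@contaminationPolicy != "off") {
        stopifnot(is(dendrite, "Trace"))
        dendNoise <- .traceNoise(dendrite, config)
        dendDff <- .transientStat(dendrite, stim_time_ms, config, pulse_index)
        ct <- contaminationTest(dffT, dendDff, noise, dendNoise, config)
        contaminated <- ct$contaminated
        if (contaminated) {
            if (config@contaminationPolicy == "reject_trial") {
                success <- NA
                excluded <- TRUE
                reason <- "contaminated"
            } else { # subtract_and_test
                success <- base && ct$excess_significant
            }
        }
    } else if (!is.null(dendrite)) {
        dendNoise <- .traceNoise(dendrite, config)
        dendDff <- .transientStat(dendrite, stim_time_ms, config, pulse_index)
    }

    data.frame(
        trial_id = spine@trialId,
        pulse = as.integer(pulse_index),
        dff_transient = dffT,
        noise_se = noise,
        threshold = threshold,
        dendrite_dff_transient = dendDff,
        dendrite_noise_se = dendNoise,
        contaminated = contaminated,
        success = success,
        excluded = excluded,
        exclusion_reason = reason,
        stringsAsFactors = FALSE
    )
}

.errorCall <- function(trialId, pulse, msg) {
    data.frame(
        trial_id = trialId, pulse = as.integer(pulse),
        dff_transient = NA_real_, noise_se = NA_real_, threshold = NA_real_,
        dendrite_dff_transient = NA_real_, dendrite_noise_se = NA_real_,
        contaminated = NA, success = NA, excluded = TRUE,
        exclusion_reason = msg, stringsAsFactors = FALSE
    )
}

#' Call release events for a batch of trials
#'
#' Runs trace extraction and per-pulse event calling over a list of records.
#' Trials that fail (degenerate normalization, windowing problems, non-finite
#' values) are returned as excluded rows carrying the error message and a
#' warning names the trial; a failing trial never aborts the batch.
#'
#' @param records list of \linkS4class{LineScanRecord} with homogeneous
#'   ROI/timing metadata.
#' @param config a \linkS4class{DetectionConfig}.
#' @param noise_window_ms,background_per_line,detrend_baseline forwarded to
#'   [extractTrace()].
#' @return data.frame with one row per trial per pulse (see [callEvent()]).
#' @export
callTrials <- function(records, config = DetectionConfig(),
                       noise_window_ms = 50, background_per_line = FALSE,
                       detrend_baseline = FALSE) {
    if (!length(records)) {
        warning("callTrials: empty record list; returning no calls")
        return(.errorCall("none", 1L, "no records")[0, ])
    }
    rows <- lapply(records, function(rec) {
        stim <- stimTimes(rec)
        tr <- tryCatch(
            list(
                spine = extractTrace(rec, "spine",
                    noise_window_ms = noise_window_ms,
                    background_per_line = background_per_line,
                    detrend_baseline = detrend_baseline),
                dendrite = extractTrace(rec, "dendrite",
                    noise_window_ms = noise_window_ms,
                    background_per_line = background_per_line,
                    detrend_baseline = detrend_baseline)
            ),
            error = function(e) e
        )
        if (inherits(tr, "error")) {
            warning(sprintf("trial '%s' excluded: %s", trialId(rec),
                conditionMessage(tr)), call. = FALSE)
            return(do.call(rbind, lapply(seq_along(stim), function(p) {
                .errorCall(trialId(rec), p, conditionMessage(tr))
            })))
        }
        do.call(rbind, lapply(seq_along(stim), function(p) {
            tryCatch(
                callEvent(tr$spine, tr$dendrite, stim[p], config,
                    pulse_index = p),
                error = function(e) {
                    warning(sprintf("trial '%s' pulse %d excluded: %s",
                        trialId(rec), p, conditionMessage(e)), call. = FALSE)
                    .errorCall(trialId(rec), p, conditionMessage(e))
                }
            )
        }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
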