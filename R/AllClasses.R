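#' @import methods
NULL

## Central S4 classes. All pixel/line coordinates are 0-based half-open spans,
## all times are milliseconds from the start of the scan, line i is sampled at
## t = i / line_rate (so t = 0 is the first line). Analysis windows are
## half-open [start, end).

#' Parameters of the synthetic line-scan generator
#'
#' @slot truePr probability of uniquantal release at pulse 1, in [0, 1].
#' @slot facilitationFactor multiplier (>= 1) applied to the marginal release
#'   probability at pulse 2; the product is capped at 1.
#' @slot isiMs inter-stimulus interval in ms (paired-pulse protocol).
#' @slot lineRateHz lines scanned per second.
#' @slot nLines number of lines per trial.
#' @slot stimOnsetMs time of pulse 1 from the start of the scan, ms.
#' @slot nPulses 1 (single pulse) or 2 (paired pulse).
#' @slot amplitudeDff mean peak dF/F of a uniquantal spine transient.
#' @slot amplitudeCv coefficient of variation of event amplitude (lognormal).
#' @slot tauRiseMs,tauDecayMs waveform time constants of the
#'   difference-of-exponentials transient kernel, ms.
#' @slot dendriteBleedFraction fraction of the spine signal appearing in the
#'   dendrite ROI through diffusion.
#' @slot contaminationRate per-trial probability of a global (bAP or dendritic
#'   spike) transient of equal amplitude in spine and dendrite.
#' @slot baselinePhotonRate expected photon count per pixel per line inside
#'   fluorescent structures at baseline.
#' @slot backgroundLevel additive photon offset present in every pixel.
#' @slot bleachTauS exponential bleaching time constant in seconds
#'   (Inf disables bleaching).
#' @slot roiGeometry list with elements \code{n_pixels} and 0-based half-open
#'   integer spans \code{spine}, \code{dendrite}, \code{background}.
#' @slot seed integer seed from which all per-trial streams are derived.
#' @exportClass SimParams
setClass("SimParams",
    representation(
        truePr = "numeric",
        facilitationFactor = "numeric",
        isiMs = "numeric",
        lineRateHz = "numeric",
        nLines = "integer",
        stimOnsetMs = "numeric",
        nPulses = "integer",
        amplitudeDff = "numeric",
        amplitudeCv = "numeric",
        tauRiseMs = "numeric",
        tauDecayMs = "numeric",
        dendriteBleedFraction = "numeric",
        contaminationRate = "numeric",
        baselinePhotonRate = "numeric",
        backgroundLevel = "numeric",
        bleachTauS = "numeric",
        roiGeometry = "list",
        seed = "integer"
    )
)

.validSpan <- function(span, nPixels, label) {
    if (!is.numeric(span) || length(span) != 2L || any(!is.finite(span))) {
        return(sprintf("roi_geometry$%s must be two finite numbers", label))
    }
    if (span[1] < 0 || span[2] > nPixels || span[1] >= span[2]) {
        return(sprintf(
            "roi_geometry$%s span [%d, %d) invalid for %d pixels",
            label, as.integer(span[1]), as.integer(span[2]),
            as.integer(nPixels)
        ))
    }
    NULL
}

.spansDisjoint <- function(a, b) a[2] <= b[1] || b[2] <= a[1]

setValidity("SimParams", function(object) {
    msgs <- character()
    if (object@truePr < 0 || object@truePr > 1) {
        msgs <- c(msgs, "true_pr must lie in [0, 1]")
    }
    if (object@facilitationFactor < 1) {
        msgs <- c(msgs, "facilitation_factor must be >= 1")
    }
    pos <- c(
        isi_ms = object@isiMs, line_rate_hz = object@lineRateHz,
        tau_rise_ms = object@tauRiseMs, tau_decay_ms = object@tauDecayMs,
        amplitude_dff = object@amplitudeDff,
        baseline_photon_rate = object@baselinePhotonRate,
        bleach_tau_s = object@bleachTauS
    )
    bad <- names(pos)[!is.finite(pos) & names(pos) != "bleach_tau_s" | pos <= 0]
    if (length(bad)) {
        msgs <- c(msgs, sprintf("%s must be > 0", paste(bad, collapse = ", ")))
    }
    if (object@tauDecayMs <= object@tauRiseMs) {
        msgs <- c(msgs, "tau_decay_ms must exceed tau_rise_ms")
    }
    if (object@amplitudeCv < 0) {
        msgs <- c(msgs, "amplitude_cv must be >= 0")
    }
    if (object@dendriteBleedFraction < 0 || object@dendriteBleedFraction > 1) {
        msgs <- c(msgs, "dendrite_bleed_fraction must lie in [0, 1]")
    }
    if (object@contaminationRate < 0 || object@contaminationRate > 1) {
        msgs <- c(msgs, "contamination_rate must lie in [0, 1]")
    }
    if (object@backgroundLevel < 0) {
        msgs <- c(msgs, "background_level must be >= 0")
    }
    if (!object@nPulses %in% c(1L, 2L)) {
        msgs <- c(msgs, "n_pulses must be 1 or 2")
    }
    geom <- object@roiGeometry
    need <- c("n_pixels", "spine", "dendrite", "background")
    if (!all(need %in% names(geom))) {
        msgs <- c(msgs, sprintf(
            "roi_geometry must contain %s", paste(need, collapse = ", ")
        ))
    } else {
        for (lab in c("spine", "dendrite", "background")) {
            m <- .validSpan(geom[[lab]], geom$n_pixels, lab)
            if (!is.null(m)) msgs <- c(msgs, m)
        }
        if (!length(msgs)) {
            pairs <- utils::combn(c("spine", "dendrite", "background"), 2)
            for (j in seq_len(ncol(pairs))) {
                if (!.spansDisjoint(geom[[pairs[1, j]]], geom[[pairs[2, j]]])) {
                    msgs <- c(msgs, sprintf(
                        "ROI spans %s and %s must be disjoint",
                        pairs[1, j], pairs[2, j]
                    ))
                }
            }
        }
    }
    scanMs <- object@nLines * 1000 / object@lineRateHz
    lastWin <- object@stimOnsetMs +
        (if (object@nPulses == 2L) object@isiMs else 0) + 50
    if (scanMs < lastWin) {
        msgs <- c(msgs, sprintf(
            "scan too short: %g ms of imaging cannot contain the %g ms analysis windows (stim_onset_ms + isi_ms + 50)",
            scanMs, lastWin
        ))
    }
    if (object@stimOnsetMs < 50) {
        msgs <- c(msgs, "stim_onset_ms must be >= 50 (the noise window needs 50 ms of baseline)")
    }
    if (length(msgs)) msgs else TRUE
})

#' One trial's line-scan record
#'
#' Raw fluorescence of a single imaging trial: a spatial-pixel-by-line photon
#' count matrix plus the timing and ROI metadata needed to analyse it.
#'
#' @slot matrix numeric matrix, rows = spatial pixels, columns = lines.
#' @slot linePeriodMs milliseconds per line.
#' @slot roiSpine,roiDendrite,roiBackground 0-based half-open pixel spans.
#' @slot stimTimesMs ordered stimulus times (1 or 2), ms from scan start.
#' @slot baselineWindowMs half-open window used for F_baseline, ms.
#' @slot trialId identifier carried through all downstream tables.
#' @exportClass LineScanRecord
setClass("LineScanRecord",
    representation(
        matrix = "matrix",
        linePeriodMs = "numeric",
        roiSpine = "numeric",
        roiDendrite = "numeric",
        roiBackground = "numeric",
        stimTimesMs = "numeric",
        baselineWindowMs = "numeric",
        trialId = "character"
    )
)

setValidity("LineScanRecord", function(object) {
    msgs <- character()
    m <- object@matrix
    if (!is.numeric(m) || any(!is.finite(m))) {
        msgs <- c(msgs, "matrix must be finite numeric")
    } else if (any(m < 0)) {
        msgs <- c(msgs, "matrix must be non-negative")
    }
    np <- nrow(m)
    for (lab in c("roiSpine", "roiDendrite", "roiBackground")) {
        v <- .validSpan(slot(object, lab), np, sub("roi", "", tolower(lab)))
        if (!is.null(v)) msgs <- c(msgs, v)
    }
    if (!length(msgs)) {
        if (!.spansDisjoint(object@roiSpine, object@roiDendrite) ||
            !.spansDisjoint(object@roiSpine, object@roiBackground) ||
            !.spansDisjoint(object@roiDendrite, object@roiBackground)) {
            msgs <- c(msgs, "ROI spans must be pairwise disjoint")
        }
    }
    st <- object@stimTimesMs
    if (!length(st) %in% c(1L, 2L) || is.unsorted(st, strictly = TRUE)) {
        msgs <- c(msgs, "stim_times_ms must be 1 or 2 strictly increasing times")
    }
    if (object@linePeriodMs <= 0) {
        msgs <- c(msgs, "line_period_ms must be > 0")
    }
    bw <- object@baselineWindowMs
    if (length(bw) != 2L || bw[1] < 0 || bw[2] <= bw[1]) {
        msgs <- c(msgs, "baseline_window_ms must be an increasing pair of times")
    } else if (length(st) && bw[2] > st[1]) {
        msgs <- c(msgs, "baseline window must end at or before the first stimulus")
    }
    if (length(msgs)) msgs else TRUE
})

#' A dF/F time series for one ROI
#'
#' @slot values dF/F per line (dimensionless).
#' @slot timesMs per-line timestamps, ms from scan start.
#' @slot roiLabel "spine" or "dendrite".
#' @slot fBaseline mean raw fluorescence over the baseline window.
#' @slot fBackground mean raw fluorescence over the background ROI.
#' @slot noiseSe standard error of the mean of the dF/F samples in the noise
#'   window (the last 50 ms of baseline by default).
#' @slot noiseSd sample standard deviation over the same window (alternative
#'   noise definition).
#' @slot noiseWindowMs the half-open window the noise statistics came from.
#' @slot trialId identifier of the source record.
#' @slot smoothed TRUE if produced by \code{smoothTrace} (display only; the
#'   detector refuses smoothed traces).
#' @exportClass Trace
setClass("Trace",
    representation(
        values = "numeric",
        timesMs = "numeric",
        roiLabel = "character",
        fBaseline = "numeric",
        fBackground = "numeric",
        noiseSe = "numeric",
        noiseSd = "numeric",
        noiseWindowMs = "numeric",
        trialId = "character",
        smoothed = "logical"
    )
)

setValidity("Trace", function(object) {
    msgs <- character()
    if (length(object@values) != length(object@timesMs)) {
        msgs <- c(msgs, "values and times_ms must have equal length")
    }
    if (!object@roiLabel %in% c("spine", "dendrite")) {
        msgs <- c(msgs, "roi_label must be 'spine' or 'dendrite'")
    }
    if (length(object@noiseSe) && (is.na(object@noiseSe) ||
        object@noiseSe < 0)) {
        msgs <- c(msgs, "noise_se must be >= 0")
    }
    if (object@fBaseline <= object@fBackground) {
        msgs <- c(msgs, "f_baseline must exceed f_background")
    }
    if (length(msgs)) msgs else TRUE
})

#' Event-detection configuration
#'
#' @slot responseWindowMs length of the post-stimulus averaging window, ms.
#' @slot thresholdMultiple noise multiplier for the success criterion; a pulse
#'   succeeds when its windowed dF/F is at least this many times the baseline
#'   noise.
#' @slot contaminationPolicy "subtract_and_test" (default; a trial with a
#'   significant dendrite transient succeeds only if the spine transient
#'   significantly exceeds the dendrite transient), "reject_trial" (such
#'   trials are excluded from numerator and denominator) or "off".
#' @slot contaminationMultiple noise multiplier for the dendrite-significance
#'   screen and the spine-minus-dendrite excess test.
#' @slot noiseDefinition "se" (standard error of the mean over the noise
#'   window; default) or "sd" (sample standard deviation).
#' @slot p2TailCorrection "none" (default) or "prewindow": re-baseline later
#'   pulses by subtracting the mean dF/F over the window immediately before
#'   the stimulus, removing the decay tail of the preceding pulse.
#' @slot prewindowMs length of that pre-stimulus window, ms.
#' @exportClass DetectionConfig
setClass("DetectionConfig",
    representation(
        responseWindowMs = "numeric",
        thresholdMultiple = "numeric",
        contaminationPolicy = "character",
        contaminationMultiple = "numeric",
        noiseDefinition = "character",
        p2TailCorrection = "character",
        prewindowMs = "numeric"
    )
)

setValidity("DetectionConfig", function(object) {
    msgs <- character()
    if (object@responseWindowMs <= 0) {
        msgs <- c(msgs, "response_window_ms must be > 0")
    }
    if (object@thresholdMultiple <= 0 || object@contaminationMultiple <= 0) {
        msgs <- c(msgs, "threshold multiples must be > 0")
    }
    if (!object@contaminationPolicy %in%
        c("off", "reject_trial", "subtract_and_test")) {
        msgs <- c(msgs,
            "contamination_policy must be off, reject_trial or subtract_and_test")
    }
    if (!object@noiseDefinition %in% c("se", "sd")) {
        msgs <- c(msgs, "noise_definition must be 'se' or 'sd'")
    }
    if (!object@p2TailCorrection %in% c("none", "prewindow")) {
        msgs <- c(msgs, "p2_tail_correction must be 'none' or 'prewindow'")
    }
    if (object@prewindowMs <= 0) {
        msgs <- c(msgs, "prewindow_ms must be > 0")
    }
    if (length(msgs)) msgs else TRUE
})

#' Release-probability estimate for one synapse and epoch
#'
#' @slot nTrials analyzable pulse-1 trials after exclusions.
#' @slot nSuccess successful release events at pulse 1.
#' @slot prHat point estimate n_success / n_trials.
#' @slot se binomial standard error sqrt(prHat (1 - prHat) / nTrials).
#' @slot ciLow,ciHigh confidence bounds at \code{confLevel}.
#' @slot ciMethod "wilson", "wald" or "clopper-pearson".
#' @slot confLevel confidence level of the interval.
#' @slot nRaw trials before exclusion.
#' @slot nExcluded excluded trials.
#' @slot exclusionReasons named integer vector tabulating exclusion reasons.
#' @exportClass PrEstimate
setClass("PrEstimate",
    representation(
        nTrials = "integer",
        nSuccess = "integer",
        prHat = "numeric",
        se = "numeric",
        ciLow = "numeric",
        ciHigh = "numeric",
        ciMethod = "character",
        confLevel = "numeric",
        nRaw = "integer",
        nExcluded = "integer",
        exclusionReasons = "integer"
    )
)

setValidity("PrEstimate", function(object) {
    msgs <- character()
    if (object@nSuccess < 0 || object@nSuccess > object@nTrials) {
        msgs <- c(msgs, "n_success must lie in [0, n_trials]")
    }
    if (object@prHat < 0 || object@prHat > 1) {
        msgs <- c(msgs, "pr_hat must lie in [0, 1]")
    }
    seRef <- sqrt(object@prHat * (1 - object@prHat) / object@nTrials)
    if (abs(object@se - seRef) > 1e-12) {
        msgs <- c(msgs, "se must equal sqrt(pr_hat (1 - pr_hat) / n_trials)")
    }
    if (object@ciLow > object@prHat || object@ciHigh < object@prHat) {
        msgs <- c(msgs, "confidence interval must contain pr_hat")
    }
    if (length(msgs)) msgs else TRUE
})

#' Paired-pulse facilitation summary
#'
#' @slot p1Hat,p2Hat success proportions at pulses 1 and 2.
#' @slot ppr paired-pulse ratio p2Hat / p1Hat (NA when p1Hat is 0).
#' @slot n1,n2 analyzable trial counts per pulse.
#' @exportClass FacilitationResult
setClass("FacilitationResult",
    representation(
        p1Hat = "numeric",
        p2Hat = "numeric",
        ppr = "numeric",
        n1 = "integer",
        n2 = "integer"
    )
)

setValidity("FacilitationResult", function(object) {
    ok <- function(p) is.na(p) || (p >= 0 && p <= 1)
    if (!ok(object@p1Hat) || !ok(object@p2Hat)) {
        "pulse success proportions must lie in [0, 1]"
    } else TRUE
})

#' Pre/post comparison of two release-probability estimates
#'
#' @slot deltaPr after minus before point estimates.
#' @slot se root-sum-square of the two binomial SEs.
#' @slot pValue two-proportion test p-value.
#' @slot method "fisher" (exact on the 2x2 success table) or "z"
#'   (normal-approximation two-proportion test).
#' @slot alpha significance level used for the direction label.
#' @slot direction "potentiation", "depression" or "no-change".
#' @exportClass PrComparison
setClass("PrComparison",
    representation(
        deltaPr = "numeric",
        se = "numeric",
        pValue = "numeric",
        method = "character",
        alpha = "numeric",
        direction = "character"
    )
)
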