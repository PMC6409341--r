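#' Extract a dF/F trace from a line-scan record
#'
#' Computes, per line, the mean raw fluorescence over the ROI's pixels, then
#' normalizes it as
#' \deqn{\Delta F/F = (F - F_{baseline}) / (F_{baseline} - F_{background})}
#' where F_baseline is the mean raw ROI fluorescence over the baseline window
#' (scan start up to the first stimulus by default) and F_background is the
#' mean fluorescence of the background ROI over the whole scan. The trace's
#' noise level is taken from the last \code{noise_window_ms} of the baseline
#' window: both the standard error of the mean (the default noise definition
#' used by the detector) and the sample standard deviation are stored.
#'
#' The ratio is invariant to any positive multiplicative gain applied to the
#' raw matrix and to any additive offset common to all pixels, so detector
#' decisions do not depend on acquisition gain.
#'
#' @param record a \linkS4class{LineScanRecord}.
#' @param roi "spine" or "dendrite".
#' @param noise_window_ms length of the end-of-baseline noise window, ms;
#'   the baseline must be at least this long.
#' @param background_per_line if TRUE, subtract the per-line background mean
#'   (recentered to its scan mean) from the ROI fluorescence before
#'   normalizing, which removes slow background drift; default FALSE uses the
#'   scan-wide scalar mean only.
#' @param detrend_baseline if TRUE, divide the raw ROI fluorescence by an
#'   exponential bleaching trend fitted to the baseline window before
#'   normalizing; off by default.
#' @return a \linkS4class{Trace}.
#' @examples
#' m <- matrix(5, nrow = 8, ncol = 40)
#' m[1:3, ] <- 50 # spine rows
#' rec <- LineScanRecord(m, 2, c(0, 3), c(4, 6), c(6, 8), stim_times_ms = 60)
#' tr <- extractTrace(rec, "spine")
#' all(dff(tr) == 0) # constant record: no transient
#' @export
extractTrace <- function(record, roi = c("spine", "dendrite"),
                         noise_window_ms = 50,
                         background_per_line = FALSE,
                         detrend_baseline = FALSE) {
    stopifnot(is(record, "LineScanRecord"))
    roi <- match.arg(roi)
    span <- if (roi == "spine") record@roiSpine else record@roiDendrite
    m <- record@matrix
    timesMs <- scanTimes(record)

    rawF <- colMeans(m[.span0(span), , drop = FALSE])
    bgPerLine <- colMeans(m[.span0(record@roiBackground), , drop = FALSE])
    fBackground <- mean(bgPerLine)
    if (background_per_line) {
        rawF <- rawF - (bgPerLine - fBackground)
    }

    bw <- record@baselineWindowMs
    if (bw[2] - bw[1] < noise_window_ms) {
        .stop("epscat_baseline_error",
            "trial '%s': baseline window [%g, %g) ms is shorter than the %g ms noise window",
            record@trialId, bw[1], bw[2], noise_window_ms)
    }
    baseIdx <- .windowIdx(timesMs, bw[1], bw[2])
    if (!length(baseIdx)) {
        .stop("epscat_baseline_error",
            "trial '%s': baseline window contains no lines", record@trialId)
    }

    if (detrend_baseline) {
        fit <- stats::lm(log(pmax(rawF[baseIdx], .Machine$double.eps)) ~
            timesMs[baseIdx])
        trend <- exp(stats::coef(fit)[2] * (timesMs - timesMs[baseIdx][1]))
        rawF <- rawF / trend
    }

    fBaseline <- mean(rawF[baseIdx])
    if (fBaseline <= fBackground) {
        .stop("epscat_degenerate_normalization",
            "trial '%s' (%s): F_baseline (%.4g) does not exceed F_background (%.4g); trial is unanalyzable",
            record@trialId, roi, fBaseline, fBackground)
    }

    values <- (rawF - fBaseline) / (fBaseline - fBackground)
    noiseIdx <- .windowIdx(timesMs, bw[2] - noise_window_ms, bw[2])
    noiseSd <- stats::sd(values[noiseIdx])
    new("Trace",
        values = values,
        timesMs = timesMs,
        roiLabel = roi,
        fBaseline = fBaseline,
        fBackground = fBackground,
        noiseSe = noiseSd / sqrt(length(noiseIdx)),
        noiseSd = noiseSd,
        noiseWindowMs = c(bw[2] - noise_window_ms, bw[2]),
        trialId = record@trialId,
        smoothed = FALSE
    )
}

#' Smooth a trace for display
#'
#' Boxcar (moving-average) smoothing for figures. Smoothed traces are marked
#' as such and are refused by the detector: event calls are always made on
#' the raw dF/F.
#'
#' @param trace a \linkS4class{Trace}.
#' @param width_ms boxcar width in ms; rounded to an odd number of lines.
#'   A width of one line period returns the trace unchanged.
#' @param method only "boxcar".
#' @return a smoothed \linkS4class{Trace} with \code{smoothed = TRUE}.
#' @export
smoothTrace <- function(trace, width_ms, method = "boxcar") {
    stopifnot(is(trace, "Trace"))
    method <- match.arg(method)
    period <- if (length(trace@timesMs) > 1) {
        diff(trace@timesMs[1:2])
    } else {
        width_ms
    }
    if (width_ms < period) {
        .stop("epscat_config_error",
            "smoothing width (%g ms) must be at least one line period (%g ms)",
            width_ms, period)
    }
    w <- max(1L, round(width_ms / period))
    if (w %% 2 == 0) w <- w + 1L
    v <- trace@values
    if (w > 1L) {
        half <- (w - 1L) %/% 2L
        n <- length(v)
        cs <- cumsum(c(0, v))
        lo <- pmax(seq_len(n) - half, 1L)
        hi <- pmin(seq_len(n) + half, n)
        v <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    out <- trace
    out@values <- v
    out@smoothed <- TRUE
    out
}

#' @rdname accessors
setMethod("dff", "Trace", function(x) x@values)

#' @rdname accessors
setMethod("scanTimes", "Trace", function(x) x@timesMs)

#' @rdname accessors
setMethod("noiseSE", "Trace", function(x) x@noiseSe)

#' @rdname accessors
setMethod("fBaseline", "Trace", function(x) x@fBaseline)

#' @rdname accessors
setMethod("fBackground", "Trace", function(x) x@fBackground)

#' @rdname accessors
setMethod("roiLabel", "Trace", function(x) x@roiLabel)

#' @rdname accessors
setMethod("trialId", "Trace", function(x) x@trialId)

setMethod("show", "Trace", function(object) {
    cat(sprintf(
        "Trace '%s' (%s%s): %d lines, F_baseline %.4g, F_background %.4g\n",
        object@trialId, object@roiLabel,
        if (object@smoothed) ", smoothed" else "",
        length(object@values), object@fBaseline, object@fBackground))
    cat(sprintf("  noise over [%g, %g) ms: SE %.4g, SD %.4g\n",
        object@noiseWindowMs[1], object@noiseWindowMs[2],
        object@noiseSe, object@noiseSd))
})

#' Tidy trace table
#'
#' Long-format export of one or more traces (columns trial_id, roi, time_ms,
#' dff), ready for CSV.
#'
#' @param traces a \linkS4class{Trace} or list of them.
#' @return data.frame.
#' @export
tracesToDataFrame <- function(traces) {
    if (is(traces, "Trace")) traces <- list(traces)
    do.call(rbind, lapply(traces, function(tr) {
        data.frame(
            trial_id = tr@trialId,
            roi = tr@roiLabel,
            time_ms = tr@timesMs,
            dff = tr@values,
            stringsAsFactors = FALSE
        )
    }))
}
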