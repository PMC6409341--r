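#' Construct a line-scan record
#'
#' Wraps one trial's raw fluorescence matrix (rows = spatial pixels along the
#' scanned line, columns = successive lines) with the timing and ROI metadata
#' the analysis needs. Pixel spans are 0-based and half-open; times are ms
#' from the start of the scan, with line i sampled at i * line_period_ms.
#'
#' @param matrix numeric pixel-by-line matrix of non-negative intensities.
#' @param line_period_ms milliseconds per line.
#' @param roi_spine,roi_dendrite,roi_background 0-based half-open pixel spans
#'   \code{c(start, end)}.
#' @param stim_times_ms 1 or 2 strictly increasing stimulus times, ms.
#' @param baseline_window_ms half-open window for F_baseline; defaults to
#'   scan start up to the first stimulus.
#' @param trial_id identifier carried into every downstream table.
#' @return a validated \linkS4class{LineScanRecord}.
#' @export
LineScanRecord <- function(matrix, line_period_ms,
                           roi_spine, roi_dendrite, roi_background,
                           stim_times_ms,
                           baseline_window_ms = c(0, stim_times_ms[1]),
                           trial_id = "trial") {
    obj <- try(new("LineScanRecord",
        matrix = matrix,
        linePeriodMs = line_period_ms,
        roiSpine = as.numeric(roi_spine),
        roiDendrite = as.numeric(roi_dendrite),
        roiBackground = as.numeric(roi_background),
        stimTimesMs = as.numeric(stim_times_ms),
        baselineWindowMs = as.numeric(baseline_window_ms),
        trialId = trial_id
    ), silent = TRUE)
    if (inherits(obj, "try-error")) {
        .stop("epscat_config_error", "invalid LineScanRecord '%s': %s",
            trial_id, attr(obj, "condition")$message)
    }
    obj
}

#' @rdname accessors
setMethod("scanMatrix", "LineScanRecord", function(x) x@matrix)

#' @rdname accessors
setMethod("stimTimes", "LineScanRecord", function(x) x@stimTimesMs)

#' @rdname accessors
setMethod("trialId", "LineScanRecord", function(x) x@trialId)

#' @rdname accessors
setMethod("scanTimes", "LineScanRecord", function(x) {
    (seq_len(ncol(x@matrix)) - 1) * x@linePeriodMs
})

setMethod("show", "LineScanRecord", function(object) {
    cat(sprintf(
        "LineScanRecord '%s': %d pixels x %d lines (%g ms/line, %g ms total)\n",
        object@trialId, nrow(object@matrix), ncol(object@matrix),
        object@linePeriodMs, ncol(object@matrix) * object@linePeriodMs))
    cat(sprintf("  stimuli at %s ms; baseline [%g, %g) ms\n",
        paste(object@stimTimesMs, collapse = ", "),
        object@baselineWindowMs[1], object@baselineWindowMs[2]))
    cat(sprintf("  ROIs (0-based, half-open): spine [%g,%g) dendrite [%g,%g) background [%g,%g)\n",
        object@roiSpine[1], object@roiSpine[2],
        object@roiDendrite[1], object@roiDendrite[2],
        object@roiBackground[1], object@roiBackground[2]))
})
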