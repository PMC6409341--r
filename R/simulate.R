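#' Normalized transient kernel
#'
#' Difference-of-exponentials waveform
#' \code{exp(-t/tau_decay) - exp(-t/tau_rise)}, rescaled so its peak is 1 and
#' zero for t < 0. Scaled by a peak dF/F amplitude it is the shape of every
#' simulated spine transient.
#'
#' @param t_ms time from event onset, ms (vectorized).
#' @param tau_rise_ms,tau_decay_ms time constants, ms (decay > rise).
#' @return numeric vector of kernel values in [0, 1].
#' @examples
#' k <- epscatKernel(0:400, 10, 200)
#' max(k) # 1 at the peak line
#' @export
epscatKernel <- function(t_ms, tau_rise_ms, tau_decay_ms) {
    if (tau_decay_ms <= tau_rise_ms) {
        .stop("epscat_config_error", "tau_decay_ms must exceed tau_rise_ms")
    }
    tPeak <- log(tau_decay_ms / tau_rise_ms) /
        (1 / tau_rise_ms - 1 / tau_decay_ms)
    peak <- exp(-tPeak / tau_decay_ms) - exp(-tPeak / tau_rise_ms)
    k <- exp(-t_ms / tau_decay_ms) - exp(-t_ms / tau_rise_ms)
    k[t_ms < 0] <- 0
    k / peak
}

## Fractional-signal time courses (dF/F units) injected into each ROI for one
## trial, given the realized release outcomes and amplitudes.
.trialSignal <- function(params, released, amps, contaminated, ampCont) {
    tMs <- (seq_len(params@nLines) - 1) * 1000 / params@lineRateHz
    stim <- .stimTimesFromParams(params)
    spine <- numeric(params@nLines)
    synaptic <- numeric(params@nLines)
    for (p in seq_along(stim)) {
        if (isTRUE(released[p])) {
            synaptic <- synaptic + amps[p] *
                epscatKernel(tMs - stim[p], params@tauRiseMs, params@tauDecayMs)
        }
    }
    global <- if (isTRUE(contaminated)) {
        ampCont * epscatKernel(tMs - stim[1], params@tauRiseMs,
            params@tauDecayMs)
    } else {
        numeric(params@nLines)
    }
    list(
        spine = synaptic + global,
        dendrite = params@dendriteBleedFraction * synaptic + global,
        times_ms = tMs
    )
}

.stimTimesFromParams <- function(params) {
    if (params@nPulses == 2L) {
        c(params@stimOnsetMs, params@stimOnsetMs + params@isiMs)
    } else {
        params@stimOnsetMs
    }
}

## Noiseless Poisson-mean matrix (pixels x lines) for one trial.
.trialExpectation <- function(params, signal) {
    geom <- params@roiGeometry
    nPix <- as.integer(geom$n_pixels)
    bleach <- exp(-(signal$times_ms / 1000) / params@bleachTauS)
    lam <- matrix(rep(params@backgroundLevel * bleach, each = nPix),
        nrow = nPix)
    rate <- params@baselinePhotonRate
    lam[.span0(geom$spine), ] <- rep(
        (params@backgroundLevel + rate * (1 + signal$spine)) * bleach,
        each = length(.span0(geom$spine)))
    lam[.span0(geom$dendrite), ] <- rep(
        (params@backgroundLevel + rate * (1 + signal$dendrite)) * bleach,
        each = length(.span0(geom$dendrite)))
    lam
}

.lognormAmp <- function(n, mean, cv) {
    if (cv == 0) return(rep(mean, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(mean / sqrt(1 + cv^2)), sdlog = sdlog)
}

.trialSeed <- function(seed, trialIndex) {
    as.integer((as.numeric(seed) + 1000003 * as.numeric(trialIndex)) %%
        2147483647)
}

#' Simulate one line-scan trial
#'
#' Draws the trial's ground truth (release at each pulse, event amplitudes,
#' contamination) from the generative model, injects the corresponding
#' transients into the spine and dendrite ROIs, and samples every pixel from
#' a Poisson law around the bleach-scaled noiseless expectation. Release at
#' pulse 1 occurs with probability \code{true_pr}; at pulse 2 with the
#' facilitated probability \code{min(1, true_pr * facilitation_factor)},
#' independently of the pulse-1 outcome. A contamination event (probability
#' \code{contamination_rate}) adds an equal-amplitude transient to both ROIs
#' at the time of pulse 1, emulating a bAP or dendritic spike triggered by
#' the stimulus.
#'
#' @param params a \linkS4class{SimParams} object.
#' @param trial_index positive integer; together with \code{params@seed} it
#'   fixes the trial's random stream, so trials are reproducible and
#'   independent.
#' @return list with elements \code{record} (a
#'   \linkS4class{LineScanRecord}) and \code{truth} (a one-row data.frame:
#'   trial_id, released_p1, released_p2, amplitude_p1, amplitude_p2,
#'   contaminated, amplitude_contamination, noise_seed).
#' @seealso [simulateExperiment()] for whole experiments.
#' @export
simulateTrial <- function(params, trial_index = 1L) {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    seed <- .trialSeed(params@seed, trial_index)
    set.seed(seed)

    p2 <- min(1, params@truePr * params@facilitationFactor)
    released <- c(
        stats::runif(1) < params@truePr,
        if (params@nPulses == 2L) stats::runif(1) < p2 else NA
    )
    contaminated <- stats::runif(1) < params@contaminationRate
    amps <- .lognormAmp(2, params@amplitudeDff, params@amplitudeCv)
    ampCont <- .lognormAmp(1, params@amplitudeDff, params@amplitudeCv)

    signal <- .trialSignal(params, released, amps, contaminated, ampCont)
    lam <- .trialExpectation(params, signal)
    counts <- matrix(as.double(stats::rpois(length(lam), lam)),
        nrow = nrow(lam))

    id <- sprintf("trial_%04d", trial_index)
    geom <- params@roiGeometry
    record <- LineScanRecord(
        matrix = counts,
        line_period_ms = 1000 / params@lineRateHz,
        roi_spine = geom$spine,
        roi_dendrite = geom$dendrite,
        roi_background = geom$background,
        stim_times_ms = .stimTimesFromParams(params),
        baseline_window_ms = c(0, params@stimOnsetMs),
        trial_id = id
    )
    truth <- data.frame(
        trial_id = id,
        released_p1 = released[1],
        released_p2 = released[2],
        amplitude_p1 = if (isTRUE(released[1])) amps[1] else NA_real_,
        amplitude_p2 = if (isTRUE(released[2])) amps[2] else NA_real_,
        contaminated = contaminated,
        amplitude_contamination = if (contaminated) ampCont else NA_real_,
        noise_seed = seed,
        stringsAsFactors = FALSE
    )
    list(record = record, truth = truth)
}

#' Simulate a whole imaging experiment
#'
#' Generates \code{n_trials} independent line-scan trials with a shared
#' parameter set and a ground-truth ledger recording exactly what was
#' injected into each trial. Rerunning with the same \code{params} (same
#' seed) reproduces the records bit for bit.
#'
#' @param params a \linkS4class{SimParams} object.
#' @param n_trials number of trials (an estimate of p_r typically uses
#'   20-30).
#' @param out_dir optional directory; when given, the records are written as
#'   a multi-page TIFF (\code{linescans.tif}), the ground truth as
#'   \code{ground_truth.csv} and the parameters (seed included) as
#'   \code{sim_params.json}.
#' @return list with \code{records} (list of \linkS4class{LineScanRecord}),
#'   \code{truth} (data.frame, one row per trial) and \code{params}.
#' @examples
#' sim <- simulateExperiment(SimParams(true_pr = 1, amplitude_cv = 0, seed = 7),
#'     n_trials = 3)
#' sim$truth$released_p1 # all TRUE at true_pr = 1
#' @export
simulateExperiment <- function(params, n_trials, out_dir = NULL) {
    if (n_trials < 1) {
        .stop("epscat_config_error", "n_trials must be >= 1")
    }
    trials <- lapply(seq_len(n_trials), function(i) simulateTrial(params, i))
    records <- lapply(trials, `[[`, "record")
    truth <- do.call(rbind, lapply(trials, `[[`, "truth"))
    rownames(truth) <- NULL
    if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        writeLineScans(records, file.path(out_dir, "linescans.tif"))
        utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
        jsonlite::write_json(simParamsToList(params),
            file.path(out_dir, "sim_params.json"),
            auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    list(records = records, truth = truth, params = params)
}

#' @rdname simulateExperiment
#' @param x for \code{simParamsToList}, a \linkS4class{SimParams} object.
#' @export
simParamsToList <- function(x) {
    list(
        true_pr = x@truePr,
        facilitation_factor = x@facilitationFactor,
        isi_ms = x@isiMs,
        line_rate_hz = x@lineRateHz,
        n_lines = x@nLines,
        stim_onset_ms = x@stimOnsetMs,
        n_pulses = x@nPulses,
        amplitude_dff = x@amplitudeDff,
        amplitude_cv = x@amplitudeCv,
        tau_rise_ms = x@tauRiseMs,
        tau_decay_ms = x@tauDecayMs,
        dendrite_bleed_fraction = x@dendriteBleedFraction,
        contamination_rate = x@contaminationRate,
        baseline_photon_rate = x@baselinePhotonRate,
        background_level = x@backgroundLevel,
        bleach_tau_s = if (is.finite(x@bleachTauS)) x@bleachTauS else "Inf",
        roi_geometry = x@roiGeometry,
        seed = x@seed
    )
}
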