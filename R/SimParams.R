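#' Construct simulator parameters
#'
#' Parameters of the synthetic line-scan generator. The defaults encode the
#' standard acquisition protocol for optical quantal analysis at hippocampal
#' spines: 200 lines at 500 Hz (400 ms of imaging), paired-pulse stimulation
#' 70 ms apart delivered 100 ms into the scan, and 50 ms analysis windows.
#' Waveform kinetics (tau_rise 10 ms, tau_decay 200 ms) and the unit event
#' amplitude (peak dF/F 1.0, CV 0.2) are conventions typical of a
#' high-affinity indicator such as OGB-1, not measured constants; adjust them
#' to your preparation.
#'
#' @param true_pr release probability at pulse 1.
#' @param facilitation_factor multiplier (>= 1) on the marginal pulse-2
#'   release probability, capped so that the product never exceeds 1.
#' @param isi_ms inter-stimulus interval, ms.
#' @param line_rate_hz lines per second.
#' @param n_lines lines per trial.
#' @param stim_onset_ms time of pulse 1 from scan start, ms.
#' @param n_pulses 1 or 2.
#' @param amplitude_dff mean peak dF/F of a uniquantal event.
#' @param amplitude_cv coefficient of variation of event amplitudes
#'   (lognormal; 0 gives identical amplitudes).
#' @param tau_rise_ms,tau_decay_ms transient kernel time constants, ms.
#' @param dendrite_bleed_fraction fraction of the spine signal appearing in
#'   the dendrite ROI through diffusion.
#' @param contamination_rate per-trial probability of a global bAP or
#'   dendritic-spike transient (equal amplitude in spine and dendrite).
#' @param baseline_photon_rate expected photons per pixel per line in
#'   fluorescent structures.
#' @param background_level additive photon offset in every pixel.
#' @param bleach_tau_s bleaching time constant, seconds (Inf = none).
#' @param roi_geometry list with \code{n_pixels} and 0-based half-open spans
#'   \code{spine}, \code{dendrite}, \code{background}.
#' @param seed integer; every random draw in a simulated experiment derives
#'   deterministically from it.
#' @return a validated \linkS4class{SimParams} object.
#' @examples
#' p <- SimParams(true_pr = 0.5, seed = 1)
#' p
#' @export
SimParams <- function(true_pr = 0.5,
                      facilitation_factor = 1.5,
                      isi_ms = 70,
                      line_rate_hz = 500,
                      n_lines = 200,
                      stim_onset_ms = 100,
                      n_pulses = 2,
                      amplitude_dff = 1.0,
                      amplitude_cv = 0.2,
                      tau_rise_ms = 10,
                      tau_decay_ms = 200,
                      dendrite_bleed_fraction = 0.1,
                      contamination_rate = 0,
                      baseline_photon_rate = 50,
                      background_level = 5,
                      bleach_tau_s = Inf,
                      roi_geometry = list(
                          n_pixels = 48L,
                          spine = c(6L, 16L),
                          dendrite = c(20L, 32L),
                          background = c(36L, 46L)
                      ),
                      seed = 1L) {
    obj <- try(new("SimParams",
        truePr = true_pr,
        facilitationFactor = facilitation_factor,
        isiMs = isi_ms,
        lineRateHz = line_rate_hz,
        nLines = as.integer(n_lines),
        stimOnsetMs = stim_onset_ms,
        nPulses = as.integer(n_pulses),
        amplitudeDff = amplitude_dff,
        amplitudeCv = amplitude_cv,
        tauRiseMs = tau_rise_ms,
        tauDecayMs = tau_decay_ms,
        dendriteBleedFraction = dendrite_bleed_fraction,
        contaminationRate = contamination_rate,
        baselinePhotonRate = baseline_photon_rate,
        backgroundLevel = background_level,
        bleachTauS = bleach_tau_s,
        roiGeometry = roi_geometry,
        seed = as.integer(seed)
    ), silent = TRUE)
    if (inherits(obj, "try-error")) {
        .stop("epscat_config_error", "invalid SimParams: %s",
            attr(obj, "condition")$message)
    }
    obj
}

setMethod("show", "SimParams", function(object) {
    cat("SimParams\n")
    cat(sprintf("  true_pr %.3g, facilitation x%.3g, %d pulse(s), ISI %g ms\n",
        object@truePr, object@facilitationFactor, object@nPulses,
        object@isiMs))
    cat(sprintf("  %d lines at %g Hz (%g ms), stimulus at %g ms\n",
        object@nLines, object@lineRateHz,
        object@nLines * 1000 / object@lineRateHz, object@stimOnsetMs))
    cat(sprintf("  amplitude dF/F %.3g (CV %.3g), tau %g/%g ms, bleed %.3g\n",
        object@amplitudeDff, object@amplitudeCv, object@tauRiseMs,
        object@tauDecayMs, object@dendriteBleedFraction))
    cat(sprintf("  contamination rate %.3g, photons %g + %g bg, bleach tau %g s, seed %d\n",
        object@contaminationRate, object@baselinePhotonRate,
        object@backgroundLevel, object@bleachTauS, object@seed))
})
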