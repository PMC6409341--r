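## File formats. TIFF: grayscale multi-page, one page per trial, rows =
## spatial pixels, columns = lines, stored as 16-bit unsigned. Acquisition
## metadata is never read from TIFF tags: the sidecar configuration is
## authoritative, which sidesteps vendor-tag dialects. Delimited input: one
## comma-separated matrix per trial in a directory, lexicographic order =
## trial order.

.isTiffPath <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

#' Write line-scan records
#'
#' Writes a list of records either as one multi-page 16-bit grayscale TIFF
#' (page order = trial order) or, when \code{path} is a directory, as one
#' comma-delimited matrix per trial (\code{trial_0001.csv}, ...). Intensities
#' must fit in 16 bits; both formats round-trip integer photon counts
#' exactly.
#'
#' @param records list of \linkS4class{LineScanRecord}.
#' @param path output file (.tif/.tiff) or directory.
#' @return invisibly, the path written.
#' @export
writeLineScans <- function(records, path) {
    if (is(records, "LineScanRecord")) records <- list(records)
    mats <- lapply(records, scanMatrix)
    if (.isTiffPath(path)) {
        if (any(vapply(mats, max, 0) > 65535)) {
            .stop("epscat_io_error",
                "intensities exceed 65535 and cannot be stored as 16-bit TIFF")
        }
        tiff::writeTIFF(lapply(mats, function(m) m / 65535), path,
            bits.per.sample = 16L)
    } else {
        dir.create(path, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_along(mats)) {
            utils::write.table(mats[[i]],
                file.path(path, sprintf("trial_%04d.csv", i)),
                sep = ",", row.names = FALSE, col.names = FALSE)
        }
    }
    invisible(path)
}

#' Read line-scan records
#'
#' Reads a multi-page TIFF (page = trial) or a directory of delimited
#' matrices and attaches the timing/ROI metadata from the experiment
#' configuration, which is authoritative for all acquisition parameters.
#' Every record is validated on construction; dimension or ROI mismatches
#' are reported with the trial's identity.
#'
#' @param path a .tif/.tiff file or a directory of .csv/.tsv/.txt matrices.
#' @param config an experiment configuration list (see
#'   [defaultExperimentConfig()]), resolved internally.
#' @return list of \linkS4class{LineScanRecord}.
#' @export
readLineScans <- function(path, config = list()) {
    cfg <- resolveConfig(config)
    if (!file.exists(path)) {
        .stop("epscat_io_error", "input '%s' does not exist", path)
    }
    if (.isTiffPath(path)) {
        pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
        if (is.matrix(pages)) pages <- list(pages)
        mats <- pages
        ids <- sprintf("trial_%04d", seq_along(mats))
    } else if (dir.exists(path)) {
        files <- sort(list.files(path, pattern = "\\.(csv|tsv|txt)$",
            full.names = TRUE))
        if (!length(files)) {
            .stop("epscat_io_error",
                "directory '%s' contains no delimited matrices", path)
        }
        mats <- lapply(files, function(f) {
            as.matrix(utils::read.table(f, sep = ",", header = FALSE))
        })
        ids <- tools::file_path_sans_ext(basename(files))
    } else {
        .stop("epscat_io_error",
            "input '%s' is neither a TIFF file nor a directory", path)
    }
    mapply(function(m, id) .recordFromMatrix(m, cfg, id),
        mats, ids, SIMPLIFY = FALSE)
}

.recordFromMatrix <- function(m, cfg, trial_id) {
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    acq <- cfg$acquisition
    roi <- cfg$roi
    if (nrow(m) != roi$n_pixels) {
        .stop("epscat_config_error",
            "trial '%s': matrix has %d pixels but roi$n_pixels is %d",
            trial_id, nrow(m), roi$n_pixels)
    }
    if (ncol(m) != acq$n_lines) {
        .stop("epscat_config_error",
            "trial '%s': matrix has %d lines but acquisition$n_lines is %d",
            trial_id, ncol(m), acq$n_lines)
    }
    stim <- acq$stim_onset_ms
    if (acq$n_pulses == 2L) stim <- c(stim, stim + acq$isi_ms)
    LineScanRecord(
        matrix = m,
        line_period_ms = 1000 / acq$line_rate_hz,
        roi_spine = roi$spine,
        roi_dendrite = roi$dendrite,
        roi_background = roi$background,
        stim_times_ms = stim,
        trial_id = trial_id
    )
}

#' Default experiment configuration
#'
#' The shipped defaults are the standard acquisition and analysis settings
#' for optical quantal analysis: 500 Hz line rate, 200 lines, paired pulses
#' 70 ms apart starting 100 ms into the scan, 50 ms response and noise
#' windows, and a 2.5x noise threshold. The \code{simulation} block holds
#' the generator defaults of [SimParams()].
#'
#' @return nested named list with blocks \code{acquisition}, \code{roi},
#'   \code{analysis}, \code{simulation}, plus \code{seed} and
#'   \code{version}.
#' @export
defaultExperimentConfig <- function() {
    list(
        acquisition = list(
            line_rate_hz = 500,
            n_lines = 200L,
            stim_onset_ms = 100,
            isi_ms = 70,
            n_pulses = 2L
        ),
        roi = list(
            n_pixels = 48L,
            spine = c(6L, 16L),
            dendrite = c(20L, 32L),
            background = c(36L, 46L)
        ),
        analysis = list(
            noise_window_ms = 50,
            noise_definition = "se",
            response_window_ms = 50,
            threshold_multiple = 2.5,
            contamination_policy = "subtract_and_test",
            contamination_multiple = 2.5,
            p2_tail_correction = "none",
            prewindow_ms = 20,
            background_per_line = FALSE,
            detrend_baseline = FALSE,
            ci_method = "wilson",
            conf_level = 0.95,
            comparison_test = "fisher",
            alpha = 0.05
        ),
        simulation = list(
            true_pr = 0.5,
            facilitation_factor = 1.5,
            amplitude_dff = 1.0,
            amplitude_cv = 0.2,
            tau_rise_ms = 10,
            tau_decay_ms = 200,
            dendrite_bleed_fraction = 0.1,
            contamination_rate = 0,
            baseline_photon_rate = 50,
            background_level = 5,
            bleach_tau_s = Inf,
            n_trials = 30L
        ),
        seed = 1L,
        version = as.character(utils::packageVersion("epscat"))
    )
}

.mergeConfig <- function(defaults, user, path = "") {
    for (key in names(user)) {
        full <- if (nzchar(path)) paste0(path, "$", key) else key
        if (!key %in% names(defaults)) {
            .stop("epscat_config_error",
                "unknown configuration key '%s'", full)
        }
        if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
            if (!is.list(user[[key]])) {
                .stop("epscat_config_error",
                    "configuration block '%s' must be a mapping", full)
            }
            defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]],
                full)
        } else {
            defaults[[key]] <- user[[key]]
        }
    }
    defaults
}

#' Resolve an experiment configuration
#'
#' Deep-merges a (possibly partial) user configuration into
#' [defaultExperimentConfig()], coerces types, validates the schema (unknown
#' keys are errors) and returns the fully resolved configuration that every
#' report embeds.
#'
#' @param config partial configuration list, or a path handled by
#'   [readExperimentConfig()].
#' @return resolved configuration list.
#' @export
resolveConfig <- function(config = list()) {
    if (is.character(config)) config <- readExperimentConfig(config)
    if (isTRUE(attr(config, "epscat_resolved"))) return(config)
    cfg <- .mergeConfig(defaultExperimentConfig(), config)
    bt <- cfg$simulation$bleach_tau_s
    if (is.null(bt) || (is.character(bt) && toupper(bt) %in%
        c("INF", ".INF"))) {
        cfg$simulation$bleach_tau_s <- Inf
    }
    cfg$acquisition$n_lines <- as.integer(cfg$acquisition$n_lines)
    cfg$acquisition$n_pulses <- as.integer(cfg$acquisition$n_pulses)
    cfg$roi <- lapply(cfg$roi, function(x) as.integer(x))
    cfg$simulation$n_trials <- as.integer(cfg$simulation$n_trials)
    cfg$seed <- as.integer(cfg$seed)
    ## construct the derived objects once so invariants are checked here
    invisible(simParamsFromConfig(cfg))
    invisible(detectionConfigFromConfig(cfg))
    structure(cfg, epscat_resolved = TRUE)
}

#' Read or write an experiment configuration file
#'
#' YAML (.yaml/.yml) or JSON (.json), chosen by extension.
#'
#' @param path configuration file path.
#' @return for the reader, the configuration list (not yet resolved).
#' @export
readExperimentConfig <- function(path) {
    if (!file.exists(path)) {
        .stop("epscat_io_error", "configuration file '%s' does not exist",
            path)
    }
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
        yaml::read_yaml(path)
    } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
        .stop("epscat_io_error",
            "configuration '%s' must be .yaml, .yml or .json", path)
    }
}

#' @rdname readExperimentConfig
#' @param config configuration list to write.
#' @export
writeExperimentConfig <- function(config, path) {
    cfg <- .jsonSafeConfig(config)
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
        yaml::write_yaml(cfg, path)
    } else {
        jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
            digits = NA)
    }
    invisible(path)
}

## JSON has no Inf; serialize it as the string "Inf" (the resolver maps it
## back).
.jsonSafeConfig <- function(x) {
    attr(x, "epscat_resolved") <- NULL
    if (is.list(x$simulation) && is.numeric(x$simulation$bleach_tau_s) &&
        !is.finite(x$simulation$bleach_tau_s)) {
        x$simulation$bleach_tau_s <- "Inf"
    }
    x
}

#' Build pipeline objects from a configuration
#'
#' @param cfg a (resolved or partial) experiment configuration.
#' @return \code{simParamsFromConfig}: a \linkS4class{SimParams};
#'   \code{detectionConfigFromConfig}: a \linkS4class{DetectionConfig}.
#' @export
simParamsFromConfig <- function(cfg) {
    if (!isTRUE(attr(cfg, "epscat_resolved"))) {
        cfg <- .mergeConfig(defaultExperimentConfig(), cfg)
    }
    s <- cfg$simulation
    a <- cfg$acquisition
    SimParams(
        true_pr = s$true_pr,
        facilitation_factor = s$facilitation_factor,
        isi_ms = a$isi_ms,
        line_rate_hz = a$line_rate_hz,
        n_lines = a$n_lines,
        stim_onset_ms = a$stim_onset_ms,
        n_pulses = a$n_pulses,
        amplitude_dff = s$amplitude_dff,
        amplitude_cv = s$amplitude_cv,
        tau_rise_ms = s$tau_rise_ms,
        tau_decay_ms = s$tau_decay_ms,
        dendrite_bleed_fraction = s$dendrite_bleed_fraction,
        contamination_rate = s$contamination_rate,
        baseline_photon_rate = s$baseline_photon_rate,
        background_level = s$background_level,
        bleach_tau_s = if (is.numeric(s$bleach_tau_s)) s$bleach_tau_s else Inf,
        roi_geometry = list(
            n_pixels = cfg$roi$n_pixels,
            spine = cfg$roi$spine,
            dendrite = cfg$roi$dendrite,
            background = cfg$roi$background
        ),
        seed = cfg$seed
    )
}

#' @rdname simParamsFromConfig
#' @export
detectionConfigFromConfig <- function(cfg) {
    if (!isTRUE(attr(cfg, "epscat_resolved"))) {
        cfg <- .mergeConfig(defaultExperimentConfig(), cfg)
    }
    a <- cfg$analysis
    DetectionConfig(
        response_window_ms = a$response_window_ms,
        threshold_multiple = a$threshold_multiple,
        contamination_policy = a$contamination_policy,
        contamination_multiple = a$contamination_multiple,
        noise_definition = a$noise_definition,
        p2_tail_correction = a$p2_tail_correction,
        prewindow_ms = a$prewindow_ms
    )
}
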