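#' Estimate release probability from event calls
#'
#' p_r is the proportion of analyzable imaging trials whose pulse-1 call is a
#' success; pulse-2 calls never enter the estimate (paired-pulse convention).
#' Uncertainty follows the binomial law:
#' \deqn{SE = \sqrt{\hat p (1 - \hat p) / N_{trials}}}
#' with N_trials the number of analyzable trials after exclusions (excluded
#' trials are itemized so the denominator is auditable). The confidence
#' interval defaults to Wilson score (well behaved at the 0/1 boundaries);
#' Wald (the SE formula's literal companion) and Clopper-Pearson are
#' available.
#'
#' @param calls data.frame of event calls from [callTrials()] or
#'   [callEvent()].
#' @param ci_method "wilson", "wald" or "clopper-pearson".
#' @param conf_level confidence level.
#' @return a \linkS4class{PrEstimate}.
#' @examples
#' calls <- data.frame(trial_id = sprintf("t%02d", 1:30), pulse = 1L,
#'     success = rep(c(TRUE, FALSE), 15), excluded = FALSE)
#' estimatePr(calls) # 15/30: pr_hat 0.5, SE sqrt(0.25/30)
#' @export
estimatePr <- function(calls, ci_method = c("wilson", "wald",
                           "clopper-pearson"),
                       conf_level = 0.95) {
    ci_method <- match.arg(ci_method)
    p1 <- calls[calls$pulse == 1L, , drop = FALSE]
    if (!nrow(p1)) {
        .stop("epscat_estimation_error", "no pulse-1 calls to estimate from")
    }
    keep <- !p1$excluded & !is.na(p1$success)
    n <- sum(keep)
    if (n == 0L) {
        .stop("epscat_estimation_error",
            "no analyzable pulse-1 trials (all %d excluded)", nrow(p1))
    }
    k <- sum(p1$success[keep])
    reasons <- p1$exclusion_reason[!keep]
    reasons <- table(ifelse(is.na(reasons), "unspecified", reasons))
    prEstimateFromCounts(k, n,
        ci_method = ci_method, conf_level = conf_level,
        n_raw = nrow(p1),
        exclusion_reasons = stats::setNames(as.integer(reasons),
            names(reasons)))
}

#' Build a release-probability estimate from raw counts
#'
#' Same arithmetic as [estimatePr()] when the per-trial calls are not at
#' hand (e.g. when reloading a report): pr_hat = n_success / n_trials and
#' SE = sqrt(pr_hat (1 - pr_hat) / n_trials).
#'
#' @param n_success,n_trials success and analyzable-trial counts.
#' @param n_raw raw trial count before exclusions.
#' @param exclusion_reasons named integer vector tabulating exclusions.
#' @inheritParams estimatePr
#' @return a \linkS4class{PrEstimate}.
#' @export
prEstimateFromCounts <- function(n_success, n_trials,
                                 ci_method = c("wilson", "wald",
                                     "clopper-pearson"),
                                 conf_level = 0.95,
                                 n_raw = n_trials,
                                 exclusion_reasons = integer()) {
    ci_method <- match.arg(ci_method)
    if (n_trials < 1) {
        .stop("epscat_estimation_error", "n_trials must be >= 1")
    }
    prHat <- n_success / n_trials
    ci <- .binomCI(as.integer(n_success), as.integer(n_trials), ci_method,
        conf_level)
    new("PrEstimate",
        nTrials = as.integer(n_trials),
        nSuccess = as.integer(n_success),
        prHat = prHat,
        se = sqrt(prHat * (1 - prHat) / n_trials),
        ciLow = ci[1],
        ciHigh = ci[2],
        ciMethod = ci_method,
        confLevel = conf_level,
        nRaw = as.integer(n_raw),
        nExcluded = as.integer(n_raw - n_trials),
        exclusionReasons = exclusion_reasons
    )
}

.binomCI <- function(k, n, method, conf) {
    switch(method,
        ## prop.test emits a chi-square small-count warning that does not
        ## apply to its score interval, which is closed-form Wilson
        wilson = suppressWarnings(
            stats::prop.test(k, n, conf.level = conf,
                correct = FALSE)$conf.int),
        wald = {
            p <- k / n
            z <- stats::qnorm(1 - (1 - conf) / 2)
            se <- sqrt(p * (1 - p) / n)
            c(max(0, p - z * se), min(1, p + z * se))
        },
        `clopper-pearson` = stats::binom.test(k, n,
            conf.level = conf)$conf.int
    )
}

#' Plan the number of imaging trials
#'
#' Smallest integer N such that the binomial standard error
#' sqrt(p (1 - p) / N) does not exceed the target. At p = 0.5 and a target
#' SE of 0.1 this gives 25 trials; tolerating SE in the 0.09-0.11 range
#' around p = 0.5 reproduces the usual 20-30 trial guidance (more trials
#' near p = 0.5 where the SE is maximal, fewer at extreme p).
#'
#' @param pr_guess anticipated release probability, strictly inside (0, 1).
#' @param target_se tolerated standard error (> 0).
#' @return integer number of trials (at least 1).
#' @examples
#' requiredTrials(0.5, 0.1) # 25
#' @export
requiredTrials <- function(pr_guess, target_se) {
    if (pr_guess <= 0 || pr_guess >= 1) {
        .stop("epscat_config_error",
            "pr_guess must lie strictly inside (0, 1)")
    }
    if (target_se <= 0) {
        .stop("epscat_config_error", "target_se must be > 0")
    }
    max(1L, .ceilingTol(pr_guess * (1 - pr_guess) / target_se^2))
}

#' Paired-pulse facilitation
#'
#' Success proportions at each pulse and their ratio PPR = p2 / p1. The
#' estimate of p_r itself is never affected by pulse-2 outcomes; this
#' summary quantifies short-term facilitation only.
#'
#' @param calls data.frame of event calls covering both pulses.
#' @return a \linkS4class{FacilitationResult}; \code{ppr} is NA when p1 = 0.
#' @export
facilitation <- function(calls) {
    if (max(calls$pulse, na.rm = TRUE) < 2L) {
        .stop("epscat_protocol_error",
            "facilitation requires a paired-pulse protocol (no pulse-2 calls found)")
    }
    prop <- function(p) {
        rows <- calls[calls$pulse == p, , drop = FALSE]
        keep <- !rows$excluded & !is.na(rows$success)
        c(n = sum(keep), p = if (sum(keep)) mean(rows$success[keep]) else NA)
    }
    s1 <- prop(1L)
    s2 <- prop(2L)
    pprVal <- if (!is.na(s1["p"]) && s1["p"] > 0) {
        unname(s2["p"] / s1["p"])
    } else {
        NA_real_
    }
    new("FacilitationResult",
        p1Hat = unname(s1["p"]), p2Hat = unname(s2["p"]),
        ppr = pprVal, n1 = as.integer(s1["n"]), n2 = as.integer(s2["n"]))
}

#' Compare release probability across epochs
#'
#' Pre/post-plasticity comparison of two estimates: the change
#' delta = after - before, its root-sum-square SE, and a two-proportion test
#' (Fisher's exact on the 2x2 success table by default; "z" gives the
#' normal-approximation test, which is calibrated closer to the nominal
#' level at these trial counts but approximate). The direction label is
#' "potentiation"/"depression" when significant at \code{alpha}, otherwise
#' "no-change".
#'
#' @param before,after \linkS4class{PrEstimate} objects.
#' @param method "fisher" or "z".
#' @param alpha significance level for the direction label.
#' @return a \linkS4class{PrComparison}.
#' @export
comparePr <- function(before, after, method = c("fisher", "z"),
                      alpha = 0.05) {
    stopifnot(is(before, "PrEstimate"), is(after, "PrEstimate"))
    method <- match.arg(method)
    tab <- matrix(c(
        after@nSuccess, after@nTrials - after@nSuccess,
        before@nSuccess, before@nTrials - before@nSuccess
    ), nrow = 2, byrow = TRUE)
    pval <- if (method == "fisher") {
        stats::fisher.test(tab)$p.value
    } else {
        suppressWarnings(stats::prop.test(
            c(after@nSuccess, before@nSuccess),
            c(after@nTrials, before@nTrials),
            correct = FALSE)$p.value)
    }
    delta <- after@prHat - before@prHat
    direction <- if (is.na(pval) || pval >= alpha) {
        "no-change"
    } else if (delta > 0) {
        "potentiation"
    } else {
        "depression"
    }
    new("PrComparison",
        deltaPr = delta,
        se = sqrt(before@se^2 + after@se^2),
        pValue = pval,
        method = method,
        alpha = alpha,
        direction = direction
    )
}

#' @rdname accessors
setMethod("prHat", "PrEstimate", function(x) x@prHat)

#' @rdname accessors
setMethod("standardError", "PrEstimate", function(x) x@se)

#' @rdname accessors
setMethod("confInt", "PrEstimate", function(x) {
    c(low = x@ciLow, high = x@ciHigh)
})

#' @rdname accessors
setMethod("nTrials", "PrEstimate", function(x) x@nTrials)

#' @rdname accessors
setMethod("nSuccess", "PrEstimate", function(x) x@nSuccess)

#' @rdname accessors
setMethod("ppr", "FacilitationResult", function(x) x@ppr)

setMethod("show", "PrEstimate", function(object) {
    cat(sprintf(
        "PrEstimate: p_r = %.3f (%d/%d trials), SE = %.4f\n",
        object@prHat, object@nSuccess, object@nTrials, object@se))
    cat(sprintf("  %g%% CI [%.3f, %.3f] (%s)\n",
        100 * object@confLevel, object@ciLow, object@ciHigh,
        object@ciMethod))
    if (object@nExcluded > 0) {
        cat(sprintf("  %d of %d raw trials excluded: %s\n",
            object@nExcluded, object@nRaw,
            paste(sprintf("%s (%d)", names(object@exclusionReasons),
                object@exclusionReasons), collapse = ", ")))
    } else {
        cat(sprintf("  no exclusions (%d raw trials)\n", object@nRaw))
    }
})

setMethod("show", "FacilitationResult", function(object) {
    cat(sprintf(
        "FacilitationResult: P1 %.3f (n=%d), P2 %.3f (n=%d), PPR %s\n",
        object@p1Hat, object@n1, object@p2Hat, object@n2,
        if (is.na(object@ppr)) "undefined (p1 = 0)" else
            sprintf("%.3f", object@ppr)))
})

setMethod("show", "PrComparison", function(object) {
    cat(sprintf(
        "PrComparison: delta p_r = %+.3f (SE %.4f), p = %.4g (%s test) -> %s at alpha = %g\n",
        object@deltaPr, object@se, object@pValue, object@method,
        object@direction, object@alpha))
})

#' Serialize an estimate for reports
#'
#' @param x a \linkS4class{PrEstimate}.
#' @return plain list mirroring the object's slots (counts, estimate, SE,
#'   CI, method names, exclusions), ready for JSON.
#' @export
prEstimateToList <- function(x) {
    list(
        n_trials = x@nTrials,
        n_success = x@nSuccess,
        pr_hat = x@prHat,
        se = x@se,
        ci_low = x@ciLow,
        ci_high = x@ciHigh,
        ci_method = x@ciMethod,
        conf_level = x@confLevel,
        n_raw = x@nRaw,
        n_excluded = x@nExcluded,
        exclusion_reasons = as.list(x@exclusionReasons)
    )
}
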