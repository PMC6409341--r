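## Internal helpers: classed conditions and window arithmetic.

.stop <- function(class, fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
        class = c(class, "epscat_error")))
}

## indices of lines whose timestamp falls in the half-open window [from, to)
.windowIdx <- function(timesMs, fromMs, toMs) {
    which(timesMs >= fromMs & timesMs < toMs)
}

.span0 <- function(span) {
    ## 0-based half-open span -> 1-based R row indices
    seq.int(span[1] + 1L, span[2])
}

## smallest-integer guard against floating-point ceilings (24.999999999 -> 25)
.ceilingTol <- function(x, tol = 1e-9) as.integer(ceiling(x - tol))
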