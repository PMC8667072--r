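# internal helpers

# lexicographic (C-locale byte) sort, independent of the session locale
.lexSort <- function(x) sort(x, method = "radix")

.lexOrder <- function(...) order(..., method = "radix")

# per-permutation RNG seed derived from one base seed so that each draw is
# reproducible in isolation (e.g. under parallel execution); kept < 2^31
.permSeed <- function(base, i) {
    (abs(as.numeric(base)) * 48271 + as.numeric(i) * 7919) %% 2147483629
}

# fixed 10-significant-digit formatting for all exported floating output
.fmtNum <- function(x) {
    out <- formatC(x, digits = 10, format = "g")
    out[is.na(x)] <- "NA"
    out
}

.assertScalar <- function(x, what, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
        stop(what, " must be a single number in [", lower, ", ", upper, "]",
             call. = FALSE)
    invisible(x)
}
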