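# Internal helpers.

# Half-up rounding (0.005 -> 0.01), the convention of the screen-QC report
# tables; base round() is half-to-even. The 1e-9 relative nudge guards
# against binary representation of values sitting exactly on .xx5.
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + abs(x) * 1e-12 + 1e-12) / p
}

# log2(count + pseudocount) on an assay matrix
logCounts <- function(m, pseudocount = 1) log2(m + pseudocount)

`%||%` <- function(a, b) if (is.null(a)) b else a
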