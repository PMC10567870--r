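`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-up rounding (round(0.125, 2) in base R is banker's); validation tables
# print percentages rounded half-up to two decimals.
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

clamp01 <- function(x, lower = 0, upper = 100) pmin(pmax(x, lower), upper)
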