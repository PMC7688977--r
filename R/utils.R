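# Internal helpers shared across modules.

# Round to one decimal, halves away from zero (base round() is half-to-even,
# which would make 2.45 years round down).
round1 <- function(x) floor(x * 10 + 0.5) / 10

# Follow-up times are multiples of 0.1 year; compare them as integer
# "deci-years" so floating-point representation never splits a tie.
deci <- function(t) as.integer(round(t * 10))

years_between <- function(from, to) as.numeric(to - from) / 365.25

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
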