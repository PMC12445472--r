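# Shared numeric helpers.

# round-half-up to integer; R's round() is banker's rounding which would send
# 0.5 to 0 — gray-level bins need the conventional rule.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}
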