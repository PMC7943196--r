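# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

#' @importFrom withr with_seed
NULL

# Derive a stream of child seeds from one master seed, staying within the
# 32-bit integer range R requires for set.seed().
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x)
}

# Reverse complement for plain character vectors (Biostrings handles the
# XStringSet case; this avoids round-tripping single strings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
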