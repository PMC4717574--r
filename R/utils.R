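# internal helpers

# derive a reproducible child seed; stays inside 32-bit integer range
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003) * 2039 + k) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# standardize a vector; a constant vector maps to zeros
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

makeQCReport <- function(step, counts, kept) {
  new("QCReport", step = step, counts = counts, kept = as.character(kept))
}

qcCountsRow <- function(filter, n_input, n_excluded) {
  data.frame(filter = filter, n_input = n_input, n_excluded = n_excluded,
             n_retained = n_input - n_excluded, stringsAsFactors = FALSE)
}
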