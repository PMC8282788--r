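# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log C(n, k) via log-gamma; n, k vectorised
log_choose <- function(n, k) {
  lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
}

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == trunc(x)
}

# gene identifier canonicalization: trim whitespace, fold case
normalize_gene_ids <- function(ids, normalize = TRUE) {
  ids <- as.character(ids)
  if (normalize) toupper(trimws(ids)) else ids
}
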