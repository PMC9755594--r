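# Internal helpers shared across the pipeline.

# Locale-independent (C collation) sort so written files are byte-stable.
ct_sort <- function(x) sort(x, method = "radix")

ct_order <- function(...) order(..., method = "radix")

# Append a line to a character log vector, optionally echoing via message().
ct_log <- function(log, ..., echo = FALSE) {
  line <- paste0(...)
  if (echo) message(line)
  c(log, line)
}

ct_stop <- function(..., class = "cerna_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

# Canonical triplet key used when comparing accepted axes to planted truth.
triplet_key <- function(mrna_a, mirna, mrna_b) {
  lo <- pmin(mrna_a, mrna_b)
  hi <- pmax(mrna_a, mrna_b)
  paste(lo, mirna, hi, sep = "|")
}
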