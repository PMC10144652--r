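## Internal error helpers: every user-facing failure is classed so the CLI
## can map validation problems to exit code 2 and runtime data problems to 3.

abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("pmmcd_validation_error", "pmmcd_error")))
}

abort_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("pmmcd_data_error", "pmmcd_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## max |a - b| / max(1, |b|) over all elements
rel_dev <- function(a, b) {
  max(abs(a - b) / pmax(1, abs(b)))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## deterministic md5 of a character scalar (via tools::md5sum on a temp file)
md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeChar(x, tf, eos = NULL)
  unname(tools::md5sum(tf))
}

## fixed-notation number formatting for reproducible text output
fmt_num <- function(x, digits = 10) {
  formatC(x, format = "g", digits = digits)
}
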