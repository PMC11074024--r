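#' @importFrom stats setNames
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish validation, format,
# retrieval and not-found failures programmatically.
ts_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "trialscape_error")))
}

ts_validation_error <- function(msg) ts_abort(msg, "trialscape_validation_error")
ts_format_error     <- function(msg) ts_abort(msg, "trialscape_format_error")
ts_not_found_error  <- function(msg) ts_abort(msg, "trialscape_not_found_error")
ts_retrieval_error  <- function(msg) ts_abort(msg, "trialscape_retrieval_error")
ts_shape_error      <- function(msg) ts_abort(msg, "trialscape_shape_error")
ts_parse_error      <- function(msg) ts_abort(msg, "trialscape_parse_error")

is_blank <- function(x) {
  is.na(x) | !nzchar(trimws(x))
}

#' @noRd
nct_pattern <- "^NCT\\d{8}$"

# Polynomial rolling hash over UTF-8 bytes, exact in double arithmetic.
# Used for provenance log lines and checksum-style determinism tests.
content_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967291
  sprintf("%010.0f", h)
}
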