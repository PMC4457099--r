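#' @keywords internal
"_PACKAGE"

# Split a ';'-separated field into a character vector; "" -> character(0).
split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

join_field <- function(x) paste(x, collapse = ";")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

CALL_LEVELS <- c("methylated", "unmethylated", "failed")

check_calls <- function(x, what) {
  bad <- setdiff(unique(x), CALL_LEVELS)
  if (length(bad) > 0)
    stopf("invalid %s call value(s): %s", what, paste(bad, collapse = ", "))
  invisible(x)
}
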