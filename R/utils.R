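`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log a message to stderr
#'
#' All diagnostics go to stderr so that result tables written to stdout stay
#' machine-readable.
#'
#' @param ... message parts, pasted together.
#' @param level log level tag (`"INFO"`, `"WARN"`, `"ERROR"`).
#' @return invisibly, the formatted message.
#' @keywords internal
uvma_log <- function(..., level = "INFO") {
  msg <- sprintf("[uvma %s] %s", level, paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

# Complement of a vector of single bases.
comp_bases <- function(b) unname(DNA_COMPLEMENT[b])

stopf <- function(...) stop(sprintf(...), call. = FALSE)
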