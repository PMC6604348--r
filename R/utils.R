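#' @keywords internal
"_PACKAGE"

#' Stage logging
#'
#' Writes a timestamped message to stderr (and to a log file when
#' `options(pollsort.logfile = path)` is set). Silenced with
#' `options(pollsort.verbose = FALSE)`.
#'
#' @param ... pieces pasted into one message.
#' @keywords internal
ps_log <- function(...) {
  msg <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ", ...)
  logfile <- getOption("pollsort.logfile", NULL)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  if (isTRUE(getOption("pollsort.verbose", TRUE))) message(msg)
  invisible(NULL)
}

# Population standard deviation of each row of a matrix.
row_pop_sd <- function(x) {
  mu <- rowMeans(x)
  sqrt(rowMeans((x - mu)^2))
}

# choose(n, 2) that tolerates large counts without integer overflow
n_pairs2 <- function(n) n * (n - 1) / 2
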