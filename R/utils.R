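## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message (no call in output)
#' @noRd
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Warn with a formatted message
#' @noRd
warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

#' Seed the RNG for a stochastic stage
#'
#' Every stochastic entry point seeds itself from an explicit argument, so a
#' fixed configuration seed reproduces outputs byte-for-byte.
#' @noRd
local_seed <- function(seed) {
  set.seed(as.integer(seed) %% 2147483647L)
  invisible(seed)
}

#' Derive a stream-specific child seed from a master seed
#'
#' Keeps independent generator stages decoupled so that, e.g., regenerating
#' coverage does not perturb the expression draw. Result stays below 2^31.
#' @noRd
child_seed <- function(seed, stream) {
  offsets <- c(genome = 11L, coverage = 23L, expression = 37L, sam = 53L,
               de = 67L, pipeline = 79L)
  off <- offsets[[stream]] %||% 97L
  (as.integer(seed) * 101L + off) %% 2147483587L
}

#' Write a data.frame as a UTF-8, LF, tab-separated file
#' @noRd
write_tsv <- function(df, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
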