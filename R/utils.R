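#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# full-precision number formatting for text round-trips
format_full <- function(x) {
  if (is.integer(x)) return(format(x, scientific = FALSE, trim = TRUE))
  trimws(formatC(x, digits = 17, format = "g"))
}

# parse leading "# key value..." comment lines into a named list of strings
parse_header_meta <- function(lines) {
  hdr <- lines[grepl("^#", lines)]
  out <- list()
  for (h in hdr) {
    h <- sub("^#\\s*", "", h)
    key <- sub("\\s.*$", "", h)
    val <- sub("^\\S+\\s*", "", h)
    out[[key]] <- val
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-member seed stream: the master seed and a member counter
# combine linearly; kept below 2^31 - 1
member_seed <- function(seed, member) {
  as.integer((as.numeric(seed) + 1009 * as.numeric(member)) %% 2147483647)
}

stop_bad_rows <- function(what, rows) {
  stop(what, " at row(s) ", paste(utils::head(rows, 10), collapse = ", "),
       if (length(rows) > 10) " ...", call. = FALSE)
}
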