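#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dfr map_int map_dbl pmap
NULL

GAP_RAW <- as.raw(45L) # "-"
BASES <- c("A", "C", "G", "T")

# mark 1-based inclusive integer ranges in a logical vector of length n
mark_ranges <- function(n, start, end) {
  if (length(start) == 0L) return(logical(n))
  start <- pmax(1L, start)
  end <- pmin(n, end)
  ok <- start <= end
  start <- start[ok]; end <- end[ok]
  d <- tabulate(start, nbins = n + 1L) - tabulate(end + 1L, nbins = n + 1L)
  cumsum(d[seq_len(n)]) > 0L
}

# split a string into single characters
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# deterministic TSV writer (no quoting surprises, fixed na encoding)
write_tsv_strict <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

# derive a child RNG seed from a master seed, kept inside 32-bit range
child_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% .Machine$integer.max
}

is_gap_raw <- function(txt) charToRaw(txt) == GAP_RAW
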