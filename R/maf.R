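#' Pairwise alignment block tibbles
#'
#' Pairwise alignments are carried as a tibble with one row per block and
#' columns `ref_name`, `ref_start` (0-based), `ref_size`, `ref_strand`,
#' `ref_src_size`, `ref_text`, and the corresponding `qry_*` columns. The two
#' gapped texts of a block have equal length, each text's ungapped length
#' equals its `*_size`, and no column is a gap in both rows.
#'
#' @param blocks A tibble in the above layout.
#' @return The validated tibble (invisibly the same object).
#' @export
validate_pair_blocks <- function(blocks) {
  need <- c(
    "ref_name", "ref_start", "ref_size", "ref_strand", "ref_src_size", "ref_text",
    "qry_name", "qry_start", "qry_size", "qry_strand", "qry_src_size", "qry_text"
  )
  missing <- setdiff(need, names(blocks))
  if (length(missing)) {
    abort(paste0("alignment block tibble lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (i in seq_len(nrow(blocks))) {
    rt <- blocks$ref_text[i]; qt <- blocks$qry_text[i]
    if (nchar(rt) != nchar(qt)) {
      abort(sprintf("block %d: row texts differ in length", i))
    }
    rg <- is_gap_raw(rt); qg <- is_gap_raw(qt)
    if (sum(!rg) != blocks$ref_size[i] || sum(!qg) != blocks$qry_size[i]) {
      abort(sprintf("block %d: ungapped length does not match declared size", i))
    }
    if (any(rg & qg)) {
      abort(sprintf("block %d: column gapped in both rows", i))
    }
  }
  blocks
}

#' Read a two-row MAF file into a block tibble
#'
#' Parses Multiple Alignment Format. Only blocks with exactly two `s` rows
#' are kept; blocks with any other row count are skipped with a warning.
#' MAF start coordinates are already 0-based and are retained as such;
#' minus-strand rows keep MAF semantics (start counted on the reverse
#' strand).
#'
#' @param path Path to a MAF file.
#' @return A pairwise alignment block tibble (see [validate_pair_blocks()]).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  is_a <- startsWith(lines, "a")
  is_s <- startsWith(lines, "s")
  a_idx <- which(is_a)
  if (!length(a_idx)) {
    return(validate_pair_blocks(tibble(
      ref_name = character(), ref_start = integer(), ref_size = integer(),
      ref_strand = character(), ref_src_size = integer(), ref_text = character(),
      qry_name = character(), qry_start = integer(), qry_size = integer(),
      qry_strand = character(), qry_src_size = integer(), qry_text = character()
    )))
  }
  bounds <- c(a_idx, length(lines) + 1L)
  parse_s <- function(ln, lineno) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) != 7L) {
      abort(sprintf("malformed MAF 's' line at line %d", lineno),
            class = "nimtools_parse_error")
    }
    list(name = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
         strand = f[5], src_size = as.integer(f[6]), text = f[7])
  }
  rows <- vector("list", length(a_idx))
  skipped <- 0L
  for (b in seq_along(a_idx)) {
    span <- seq.int(a_idx[b] + 1L, bounds[b + 1L] - 1L)
    span <- span[span <= length(lines)]
    s_lines <- span[is_s[span]]
    if (length(s_lines) != 2L) {
      skipped <- skipped + 1L
      next
    }
    r <- parse_s(lines[s_lines[1]], s_lines[1])
    q <- parse_s(lines[s_lines[2]], s_lines[2])
    rows[[b]] <- tibble(
      ref_name = r$name, ref_start = r$start, ref_size = r$size,
      ref_strand = r$strand, ref_src_size = r$src_size, ref_text = r$text,
      qry_name = q$name, qry_start = q$start, qry_size = q$size,
      qry_strand = q$strand, qry_src_size = q$src_size, qry_text = q$text
    )
  }
  if (skipped > 0L) {
    warn(sprintf("skipped %d MAF block(s) without exactly two 's' rows", skipped))
  }
  validate_pair_blocks(bind_rows(rows))
}

#' Write a block tibble as MAF
#'
#' @param blocks A pairwise alignment block tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  validate_pair_blocks(blocks)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (i in seq_len(nrow(blocks))) {
    writeLines("a", con)
    writeLines(sprintf(
      "s %s %d %d %s %d %s",
      c(blocks$ref_name[i], blocks$qry_name[i]),
      c(blocks$ref_start[i], blocks$qry_start[i]),
      c(blocks$ref_size[i], blocks$qry_size[i]),
      c(blocks$ref_strand[i], blocks$qry_strand[i]),
      c(blocks$ref_src_size[i], blocks$qry_src_size[i]),
      c(blocks$ref_text[i], blocks$qry_text[i])
    ), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read or coerce a genome into a named character vector
#'
#' Accepts a FASTA path, a `Biostrings::DNAStringSet`, or an already-named
#' character vector of sequences.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    x <- Biostrings::readDNAStringSet(genome)
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(toupper(genome))
  }
  abort("genome must be a FASTA path, DNAStringSet, or named character vector")
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
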