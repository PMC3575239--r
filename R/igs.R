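#' G+C binner over fixed genome windows
#'
#' Computes the G+C fraction of non-overlapping windows along each reference
#' sequence (N bases are excluded from numerator and denominator) and splits
#' the windows into `n_bins` equally populated bins by ordering windows on
#' GC and cutting the cumulative weight into equal parts. With
#' `weights = NULL` the weight is the window's non-N length; supplying
#' per-window aligned-base counts (see [aligned_bases_by_window()]) makes
#' the bins equally populated in aligned bases, the convention used for the
#' neutral indel model.
#'
#' Sequences whose name matches `exclude_pattern` (sex chromosomes and
#' unplaced scaffolds, whose indel dynamics differ from autosomes) and
#' all-N windows get bin `NA` and are thereby excluded downstream.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param window_size Window length in bases (default 10 kb).
#' @param n_bins Number of GC bins (default 20).
#' @param weights Optional tibble `(seqname, window, weight)` of per-window
#'   aligned bases; windows absent from it get weight 0 but keep a bin.
#' @param exclude_pattern Regex of sequence names excluded from binning.
#' @return A `gc_binner`: list with the window table and an `assign(seqname,
#'   pos)` vectorised lookup (0-based positions).
#' @export
gc_binner <- function(genome, window_size = 10000, n_bins = 20,
                      weights = NULL,
                      exclude_pattern = "chrZ|chrW|chrUn|random") {
  stopifnot(n_bins >= 1, window_size >= 1)
  seqs <- read_genome(genome)
  win <- map_dfr(names(seqs), function(nm) {
    r <- charToRaw(seqs[[nm]])
    L <- length(r)
    gc <- cumsum(r == as.raw(71L) | r == as.raw(67L))   # G, C
    acgt <- cumsum(r == as.raw(65L) | r == as.raw(67L) |
                     r == as.raw(71L) | r == as.raw(84L))
    starts <- seq.int(0L, L - 1L, by = window_size)
    ends <- pmin(starts + window_size, L)
    gc_n <- gc[ends] - c(0L, gc[starts[-1]])
    acgt_n <- acgt[ends] - c(0L, acgt[starts[-1]])
    tibble(
      seqname = nm,
      window = seq_along(starts) - 1L,
      start = starts, end = ends,
      gc = ifelse(acgt_n > 0L, gc_n / acgt_n, NA_real_),
      non_n = acgt_n
    )
  })
  win$excluded <- grepl(exclude_pattern, win$seqname)
  if (!is.null(weights)) {
    win <- win |>
      left_join(weights, by = c("seqname", "window")) |>
      mutate(weight = dplyr::coalesce(.data$weight, 0))
  } else {
    win$weight <- as.double(win$non_n)
  }
  usable <- !win$excluded & !is.na(win$gc)
  win$gc_bin <- NA_integer_
  if (any(usable)) {
    u <- win[usable, ]
    ord <- order(u$gc, u$seqname, u$window)
    cw <- cumsum(u$weight[ord])
    total <- cw[length(cw)]
    if (total <= 0) {
      bin <- rep(1L, length(ord))
    } else {
      mid <- cw - u$weight[ord] / 2
      bin <- pmin(n_bins, 1L + as.integer(floor(mid / total * n_bins)))
    }
    win$gc_bin[usable][ord] <- bin
  }
  key <- paste0(win$seqname, ":", win$window)
  bin_by_key <- win$gc_bin
  names(bin_by_key) <- key
  assign_fn <- function(seqname, pos) {
    k <- paste0(seqname, ":", as.integer(pos %/% window_size))
    unname(bin_by_key[k])
  }
  structure(
    list(windows = win, window_size = window_size, n_bins = n_bins,
         exclude_pattern = exclude_pattern, assign = assign_fn),
    class = "gc_binner"
  )
}

#' @export
print.gc_binner <- function(x, ...) {
  cat(sprintf("<gc_binner> %d windows of %d bp in %d bins\n",
              nrow(x$windows), x$window_size, x$n_bins))
  invisible(x)
}

# per-block column bookkeeping shared by extract_igs and aligned-base counts
block_columns <- function(ref_text, qry_text) {
  rg <- is_gap_raw(ref_text)
  qg <- is_gap_raw(qry_text)
  list(ref_gap = rg, qry_gap = qg, gap = rg | qg, ref_cum = cumsum(!rg))
}

#' Extract inter-gap segments from alignment blocks
#'
#' An inter-gap segment (IGS) is a maximal run of alignment columns in which
#' neither row is gapped; a run of one or more consecutive gap columns —
#' regardless of which row carries the gap — is a single delimiter. Segments
#' abutting a block edge are flagged `boundary_truncated` (their length is
#' censored by the block boundary, not by an indel).
#'
#' @param blocks Pairwise alignment block tibble.
#' @param binner Optional [gc_binner()]; if supplied, each segment gets the
#'   GC bin of the reference window containing its midpoint.
#' @return Tibble with `seqname`, `ref_start`, `ref_end` (0-based half-open
#'   reference interval), `length`, `boundary_truncated`, `gc_bin`.
#' @export
extract_igs <- function(blocks, binner = NULL) {
  segs <- map_dfr(seq_len(nrow(blocks)), function(i) {
    bc <- block_columns(blocks$ref_text[i], blocks$qry_text[i])
    if (!length(bc$gap)) return(NULL)
    r <- rle(bc$gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seg <- which(!r$values)
    if (!length(seg)) return(NULL)
    first_run <- seg == 1L
    last_run <- seg == length(r$values)
    s <- starts[seg]; e <- ends[seg]
    ref0 <- blocks$ref_start[i] + bc$ref_cum[s] - 1L
    tibble(
      seqname = blocks$ref_name[i],
      ref_start = ref0,
      ref_end = blocks$ref_start[i] + bc$ref_cum[e],
      length = r$lengths[seg],
      boundary_truncated = first_run | last_run
    )
  })
  if (is.null(segs) || !nrow(segs)) {
    segs <- tibble(seqname = character(), ref_start = integer(),
                   ref_end = integer(), length = integer(),
                   boundary_truncated = logical())
  }
  segs$gc_bin <- if (!is.null(binner) && nrow(segs)) {
    mid <- segs$ref_start + segs$length %/% 2L
    binner$assign(segs$seqname, mid)
  } else if (!is.null(binner)) integer(0) else rep(NA_integer_, nrow(segs))
  segs
}

#' Aligned bases per reference window
#'
#' Counts, for each fixed-size reference window, the alignment columns where
#' neither row is gapped. Used to weight GC bins so that each bin holds an
#' equal share of aligned sequence.
#'
#' @param blocks Pairwise alignment block tibble.
#' @param window_size Window length in bases.
#' @return Tibble `(seqname, window, weight)`.
#' @export
aligned_bases_by_window <- function(blocks, window_size = 10000) {
  map_dfr(seq_len(nrow(blocks)), function(i) {
    bc <- block_columns(blocks$ref_text[i], blocks$qry_text[i])
    aligned <- !bc$gap
    if (!any(aligned)) return(NULL)
    refpos <- blocks$ref_start[i] + bc$ref_cum[aligned] - 1L
    tibble(seqname = blocks$ref_name[i],
           window = as.integer(refpos %/% window_size)) |>
      count(.data$seqname, .data$window, name = "weight")
  }) |>
    group_by(.data$seqname, .data$window) |>
    summarise(weight = sum(.data$weight), .groups = "drop") |>
    mutate(weight = as.double(.data$weight))
}

#' Build an inter-gap segment length histogram
#'
#' Counts segments by GC bin and exact length. Boundary-truncated segments
#' are excluded by default: their observed length is right-censored at the
#' block edge and would bias the geometric fit.
#'
#' @param segments Output of [extract_igs()].
#' @param exclude_truncated Drop boundary-truncated segments (default TRUE).
#' @return An `igs_histogram` tibble `(gc_bin, length, count)` with
#'   attributes `aligned_bases` (per-bin tibble, from *all* segments) and
#'   `n_segments`.
#' @export
build_histogram <- function(segments, exclude_truncated = TRUE) {
  aligned <- segments |>
    group_by(gc_bin = .data$gc_bin) |>
    summarise(aligned_bases = sum(as.double(.data$length)), .groups = "drop")
  keep <- segments
  if (exclude_truncated && nrow(keep)) {
    keep <- keep[!keep$boundary_truncated, ]
  }
  h <- keep |>
    count(gc_bin = .data$gc_bin, length = .data$length, name = "count") |>
    arrange(.data$gc_bin, .data$length)
  structure(h, aligned_bases = aligned, n_segments = nrow(keep),
            class = c("igs_histogram", class(h)))
}

#' Write an IGS histogram as TSV
#'
#' @param histogram An [build_histogram()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_igs_tsv <- function(histogram, path) {
  write_tsv_strict(as_tibble(histogram), path)
}
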