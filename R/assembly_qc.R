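#' Coverage-based genome size estimate
#'
#' Under the simplifying assumption that all genomic regions are equally
#' represented among reads, the true genome size is the total sequenced
#' bases divided by the modal per-base depth of coverage on assembled
#' contigs.
#'
#' @param total_sequenced_bases Total bases of sequence data.
#' @param modal_coverage Modal (peak) fold-coverage; must be positive.
#' @return Estimated genome size in bases.
#' @export
genome_size_from_coverage <- function(total_sequenced_bases, modal_coverage) {
  if (!is.numeric(modal_coverage) || modal_coverage <= 0) {
    abort("modal_coverage must be > 0", class = "nimtools_domain_error")
  }
  stopifnot(total_sequenced_bases >= 0)
  total_sequenced_bases / modal_coverage
}

#' Modal coverage of an integer per-base coverage track
#'
#' The mode of the integer coverage histogram; ties resolve to the smallest
#' depth. Zero-coverage positions are ignored (they are absent from contigs).
#'
#' @param coverage Integer vector of per-base depths.
#' @return The modal depth (integer).
#' @export
modal_coverage <- function(coverage) {
  cov <- coverage[coverage > 0]
  stopifnot(length(cov) > 0)
  tab <- tabulate(cov)
  which.max(tab)
}

#' Euchromatic completeness from outgroup triangulation
#'
#' Sequence aligned between two outgroups but absent from the target
#' assembly is, with rare lineage-specific-deletion exceptions, sequence the
#' assembly failed to capture. Completeness is then
#' `span / (span + absent)`.
#'
#' @param assembly_euchromatic_span Assembly span, bases.
#' @param outgroup_pair_aligned_absent Outgroup-pair-aligned sequence absent
#'   from the target assembly, bases.
#' @return Completeness fraction in `[0, 1]`.
#' @export
euchromatic_completeness <- function(assembly_euchromatic_span,
                                     outgroup_pair_aligned_absent) {
  stopifnot(assembly_euchromatic_span >= 0, outgroup_pair_aligned_absent >= 0)
  assembly_euchromatic_span /
    (assembly_euchromatic_span + outgroup_pair_aligned_absent)
}

#' Percentage of an assembly covered by an alignment
#'
#' @param aligned_bases Bases of the assembly that aligned.
#' @param assembly_span Assembly span, bases.
#' @return Integer percent.
#' @export
aligned_fraction <- function(aligned_bases, assembly_span) {
  stopifnot(aligned_bases >= 0, assembly_span > 0)
  as.integer(round(100 * aligned_bases / assembly_span))
}

#' Gene-set completeness from 1:1 ortholog counts
#'
#' Ratio of simple 1:1 ortholog sets found for the target species to those
#' found for a well-annotated reference species against the same outgroup.
#'
#' @param n_orthologs_target_pair 1:1 ortholog count, outgroup vs target.
#' @param n_orthologs_reference_pair 1:1 ortholog count, outgroup vs
#'   reference.
#' @return Integer percent.
#' @export
geneset_completeness <- function(n_orthologs_target_pair,
                                 n_orthologs_reference_pair) {
  stopifnot(n_orthologs_target_pair >= 0, n_orthologs_reference_pair > 0)
  as.integer(round(100 * n_orthologs_target_pair / n_orthologs_reference_pair))
}

#' Splice-site audit record
#'
#' @param n_changed Splice-dinucleotide nucleotides differing in the target.
#' @param n_sites_nt Audited (aligned) splice-dinucleotide nucleotides.
#' @param n_skipped_noncanonical Reference introns skipped as non-GT..AG.
#' @param n_unaligned Splice nucleotides excluded as unaligned.
#' @return A `splice_audit` list with `rate = n_changed / n_sites_nt` and a
#'   `percent` formatted to two significant figures.
#' @export
splice_audit <- function(n_changed, n_sites_nt,
                         n_skipped_noncanonical = 0L, n_unaligned = 0L) {
  stopifnot(n_sites_nt >= 1, n_changed >= 0, n_changed <= n_sites_nt)
  rate <- n_changed / n_sites_nt
  structure(list(
    n_sites_nt = as.integer(n_sites_nt),
    n_changed = as.integer(n_changed),
    rate = rate,
    percent = signif(100 * rate, 2),
    n_skipped_noncanonical = as.integer(n_skipped_noncanonical),
    n_unaligned = as.integer(n_unaligned)
  ), class = "splice_audit")
}

#' @export
print.splice_audit <- function(x, ...) {
  cat(sprintf("<splice_audit> %d of %d splice nucleotides changed (%.2g%%)\n",
              x$n_changed, x$n_sites_nt, x$percent))
  invisible(x)
}

# read a GFF3 path (via rtracklayer) or accept a tibble with the columns
# seqid, type, start, end, strand, and Parent/ID as available
read_gene_models <- function(gff3) {
  if (is.character(gff3) && length(gff3) == 1L) {
    g <- rtracklayer::import(gff3)
    df <- as.data.frame(g)
    tibble(
      seqid = as.character(df$seqnames), type = as.character(df$type),
      start = df$start, end = df$end, strand = as.character(df$strand),
      parent = vapply(as.list(df$Parent %||% rep(NA_character_, nrow(df))),
                      function(p) if (length(p)) as.character(p)[1] else NA_character_,
                      character(1))
    )
  } else {
    as_tibble(gff3)
  }
}

# introns between consecutive exons of each parent, 1-based inclusive coords
derive_introns <- function(models) {
  ex <- models[models$type == "exon", ]
  ex |>
    group_by(.data$seqid, .data$strand, .data$parent) |>
    arrange(.data$start, .by_group = TRUE) |>
    reframe(
      intron_start = .data$end[-dplyr::n()] + 1L,
      intron_end = .data$start[-1L] - 1L
    ) |>
    filter(.data$intron_end >= .data$intron_start)
}

# map reference positions (1-based) to target bases through pair blocks;
# returns NA where unaligned or gapped in the target
map_ref_to_target <- function(blocks, seqid, pos) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(blocks))) {
    if (blocks$ref_name[i] != seqid) next
    bc <- block_columns(blocks$ref_text[i], blocks$qry_text[i])
    # reference position (1-based) of each column that carries a ref base
    ref_cols <- which(!bc$ref_gap)
    refpos <- blocks$ref_start[i] + bc$ref_cum[ref_cols] # 1-based
    hit <- match(pos, refpos)
    found <- which(!is.na(hit))
    if (!length(found)) next
    qchars <- str_chars(blocks$qry_text[i])
    out[found] <- qchars[ref_cols[hit[found]]]
  }
  out[!is.na(out) & out == "-"] <- NA_character_
  out
}

#' Audit splice-dinucleotide substitutions in an aligned target assembly
#'
#' For every canonical GT..AG intron of the reference annotation, the four
#' splice-dinucleotide nucleotides (donor GT, acceptor AG, read on the gene
#' strand) are looked up in the aligned target genome. Nucleotides that are
#' unaligned or gapped are excluded from the denominator; apparent
#' substitutions at these highly conserved positions estimate the target
#' assembly's nucleotide error rate. Non-canonical reference introns are
#' skipped with a warning and counted.
#'
#' @param gff3 GFF3 path or a gene-model tibble with exon rows
#'   (`seqid`, `type`, `start`, `end`, `strand`, `parent`).
#' @param ref_genome Reference genome (FASTA path, `DNAStringSet`, or named
#'   character vector).
#' @param target_blocks Pairwise block tibble aligning the reference
#'   (`ref_*` rows) to the target assembly (`qry_*` rows).
#' @return A [splice_audit()].
#' @export
splice_site_substitution_rate <- function(gff3, ref_genome, target_blocks) {
  models <- read_gene_models(gff3)
  seqs <- read_genome(ref_genome)
  introns <- derive_introns(models)
  if (!nrow(introns)) abort("no introns derivable from the annotation")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_skip <- 0L
  audit_pos <- list()
  for (i in seq_len(nrow(introns))) {
    sq <- seqs[[introns$seqid[i]]]
    s <- introns$intron_start[i]; e <- introns$intron_end[i]
    if (is.null(sq) || e > nchar(sq) || e - s + 1L < 4L) { n_skip <- n_skip + 1L; next }
    left <- substr(sq, s, s + 1L)
    right <- substr(sq, e - 1L, e)
    canonical <- if (introns$strand[i] == "-") {
      left == "CT" && right == "AC" # reverse-complement of GT..AG
    } else {
      left == "GT" && right == "AG"
    }
    if (!canonical) { n_skip <- n_skip + 1L; next }
    audit_pos[[length(audit_pos) + 1L]] <-
      tibble(seqid = introns$seqid[i], pos = c(s, s + 1L, e - 1L, e))
  }
  if (n_skip > 0L) {
    warn(sprintf("skipped %d non-canonical or unusable intron(s)", n_skip))
  }
  ap <- bind_rows(audit_pos)
  if (is.null(ap) || !nrow(ap)) abort("no canonical introns to audit")
  n_changed <- 0L; n_audited <- 0L; n_unaligned <- 0L
  for (sq in unique(ap$seqid)) {
    pos <- ap$pos[ap$seqid == sq]
    refb <- toupper(substring(seqs[[sq]], pos, pos))
    tgtb <- map_ref_to_target(target_blocks, sq, pos)
    tgtb <- toupper(tgtb)
    ok <- !is.na(tgtb)
    n_unaligned <- n_unaligned + sum(!ok)
    n_audited <- n_audited + sum(ok)
    n_changed <- n_changed + sum(refb[ok] != tgtb[ok])
  }
  splice_audit(n_changed, n_audited,
               n_skipped_noncanonical = n_skip, n_unaligned = n_unaligned)
}

#' Upper-bound indel error rate from a three-way alignment
#'
#' In an alignment of outgroup, target, and a close sister genome, a gap-run
#' event where the target's gap state differs from *both* other rows is, if
#' one conservatively assumes no target-lineage indels occurred, an assembly
#' indel error. An event is a maximal run of gap-containing columns with a
#' constant row gap pattern. The rate is events per kb of columns in which
#' the outgroup row is ungapped.
#'
#' @param blocks3 Tibble with gapped, equal-length `outgroup`, `target`,
#'   `sister` texts (one row per alignment block). Rows whose texts differ
#'   in length are skipped with a warning.
#' @return List: `events`, `aligned_kb`, `per_kb`.
#' @export
indel_error_upper_bound <- function(blocks3) {
  need <- c("outgroup", "target", "sister")
  if (!all(need %in% names(blocks3))) {
    abort("blocks3 needs columns outgroup, target, sister")
  }
  events <- 0L
  aligned <- 0
  skipped <- 0L
  for (i in seq_len(nrow(blocks3))) {
    go <- is_gap_raw(blocks3$outgroup[i])
    gt <- is_gap_raw(blocks3$target[i])
    gs <- is_gap_raw(blocks3$sister[i])
    if (length(go) != length(gt) || length(go) != length(gs)) {
      skipped <- skipped + 1L
      next
    }
    aligned <- aligned + sum(!go)
    pattern <- go + 2L * gt + 4L * gs
    r <- rle(pattern)
    # target differs from both others: target-only gap (2) or
    # target-only base against gaps in both others (5)
    events <- events + sum(r$values %in% c(2L, 5L))
  }
  if (skipped > 0L) {
    warn(sprintf("skipped %d block(s) with unequal row lengths", skipped))
  }
  if (aligned == 0) abort("no aligned outgroup bases in input")
  list(events = events, aligned_kb = aligned / 1000,
       per_kb = events / (aligned / 1000))
}
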