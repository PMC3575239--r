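#' Write a minimal gene-model tibble as GFF3
#'
#' @param models Tibble with `seqid`, `type`, `start`, `end` (1-based
#'   inclusive), `strand`, `id`, `parent` (NA for top-level features).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  attrs <- ifelse(
    is.na(models$parent),
    paste0("ID=", models$id),
    paste0("ID=", models$id, ";Parent=", models$parent)
  )
  lines <- paste(models$seqid, "nimtools", models$type, models$start,
                 models$end, ".", models$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Generate a three-genome spliced-gene fixture with planted assembly errors
#'
#' Builds one reference chromosome of toy genes whose introns carry
#' canonical GT..AG splice dinucleotides, then derives a colinear target
#' genome carrying exactly the planted splice-dinucleotide substitutions and
#' target-only indel events (placed in intergenic spacers), and an identical
#' sister genome. The exact three-way alignment follows from the plant
#' bookkeeping. This is the input shape expected by
#' [splice_site_substitution_rate()] (reference vs target pair blocks) and
#' [indel_error_upper_bound()] (outgroup/target/sister rows).
#'
#' @param n_genes Number of genes.
#' @param introns_per_gene Introns per gene.
#' @param exon_length,intron_length Exon/intron lengths, bases
#'   (`intron_length >= 4`).
#' @param intergenic_length Spacer length before, between and after genes.
#' @param n_splice_errors Planted substitutions at splice-dinucleotide
#'   nucleotides of the target.
#' @param n_indel_errors Planted target-only indel events (in spacers).
#' @param indel_length Length of each planted indel, bases.
#' @param seed Integer seed; regeneration is bit-identical.
#' @return A list:
#' \describe{
#'   \item{genomes}{named character vector `reference`, `target`, `sister`.}
#'   \item{models}{gene-model tibble (gene/mRNA/exon rows) for
#'     [write_gff3()].}
#'   \item{blocks3}{one-row tibble with gapped `outgroup`, `target`,
#'     `sister` texts.}
#'   \item{pair_blocks}{reference-vs-target pairwise block tibble.}
#'   \item{truth}{list: `splice_errors` tibble `(pos, ref_base, target_base)`,
#'     `indel_events` tibble `(type, ref_pos, len)`, `n_splice_nt`,
#'     `ref_length`.}
#' }
#' @export
make_spliced_gene_fixture <- function(n_genes = 10, introns_per_gene = 5,
                                      exon_length = 120, intron_length = 90,
                                      intergenic_length = 200,
                                      n_splice_errors = 0,
                                      n_indel_errors = 0,
                                      indel_length = 3,
                                      seed = 1L) {
  stopifnot(intron_length >= 4, exon_length >= 1, n_genes >= 1,
            introns_per_gene >= 1)
  set.seed(seed)
  seqid <- "chr1"
  ref <- character(0)
  models <- list()
  introns <- list()
  spacers <- list()
  cursor <- 0L # 0-based end of built sequence
  add_spacer <- function() {
    spacers[[length(spacers) + 1L]] <<- c(cursor + 1L, cursor + intergenic_length)
    ref[[length(ref) + 1L]] <<-
      paste(sample(BASES, intergenic_length, replace = TRUE), collapse = "")
    cursor <<- cursor + intergenic_length
  }
  for (g in seq_len(n_genes)) {
    add_spacer()
    gene_start <- cursor + 1L
    gid <- sprintf("gene%03d", g)
    mid <- sprintf("mRNA%03d", g)
    for (e in seq_len(introns_per_gene + 1L)) {
      ex_start <- cursor + 1L
      ref[[length(ref) + 1L]] <-
        paste(sample(BASES, exon_length, replace = TRUE), collapse = "")
      cursor <- cursor + exon_length
      models[[length(models) + 1L]] <- tibble(
        seqid = seqid, type = "exon", start = ex_start, end = cursor,
        strand = "+", id = sprintf("%s.exon%d", mid, e), parent = mid
      )
      if (e <= introns_per_gene) {
        in_start <- cursor + 1L
        body <- paste(sample(BASES, intron_length - 4L, replace = TRUE),
                      collapse = "")
        ref[[length(ref) + 1L]] <- paste0("GT", body, "AG")
        cursor <- cursor + intron_length
        introns[[length(introns) + 1L]] <- c(in_start, cursor)
      }
    }
    models[[length(models) + 1L]] <- tibble(
      seqid = seqid, type = "mRNA", start = gene_start, end = cursor,
      strand = "+", id = mid, parent = gid
    )
    models[[length(models) + 1L]] <- tibble(
      seqid = seqid, type = "gene", start = gene_start, end = cursor,
      strand = "+", id = gid, parent = NA_character_
    )
  }
  add_spacer()
  ref_seq <- paste(unlist(ref), collapse = "")
  L <- nchar(ref_seq)
  intron_tbl <- do.call(rbind, introns)
  splice_nt <- as.vector(t(cbind(intron_tbl[, 1], intron_tbl[, 1] + 1L,
                                 intron_tbl[, 2] - 1L, intron_tbl[, 2])))
  if (n_splice_errors > length(splice_nt)) {
    abort("planted splice errors exceed available splice-site nucleotides",
          class = "nimtools_fixture_error")
  }
  ref_chars <- str_chars(ref_seq)
  tgt_chars <- ref_chars
  sp_err <- if (n_splice_errors > 0) {
    at <- sort(sample(splice_nt, n_splice_errors))
    shift <- sample.int(3L, n_splice_errors, replace = TRUE)
    newb <- BASES[((match(ref_chars[at], BASES) - 1L + shift) %% 4L) + 1L]
    tgt_chars[at] <- newb
    tibble(pos = at, ref_base = ref_chars[at], target_base = newb)
  } else tibble(pos = integer(), ref_base = character(),
                target_base = character())
  # planted target-only indels live inside spacers, well separated
  ind <- tibble(type = character(), ref_pos = integer(), len = integer())
  del_mask <- logical(L)
  ins_pos <- integer(0); ins_len <- integer(0)
  if (n_indel_errors > 0) {
    spacer_tbl <- do.call(rbind, spacers)
    # candidate anchors: spacer interiors, away from edges and each other
    cand <- unlist(apply(spacer_tbl, 1L, function(sp) {
      lo <- sp[1] + 2L; hi <- sp[2] - indel_length - 2L
      if (hi < lo) integer(0) else
        seq.int(lo, hi, by = indel_length + 4L)
    }))
    if (length(cand) < n_indel_errors) {
      abort("not enough spacer room for planted indels",
            class = "nimtools_fixture_error")
    }
    at <- sort(sample(cand, n_indel_errors))
    is_del <- rep_len(c(TRUE, FALSE), n_indel_errors)
    for (k in seq_len(n_indel_errors)) {
      if (is_del[k]) {
        del_mask[at[k]:(at[k] + indel_length - 1L)] <- TRUE
      } else {
        ins_pos <- c(ins_pos, at[k])
        ins_len <- c(ins_len, indel_length)
      }
    }
    ind <- tibble(type = ifelse(is_del, "deletion", "insertion"),
                  ref_pos = at, len = indel_length)
  }
  nIns <- sum(ins_len)
  ins_chars <- if (nIns) sample(BASES, nIns, replace = TRUE) else character(0)
  key <- c(as.double(seq_len(L)),
           if (nIns) rep(ins_pos, ins_len) - 0.5 else double(0))
  o <- order(key)
  out_row <- c(ref_chars, rep("-", nIns))[o]
  sis_row <- c(ref_chars, rep("-", nIns))[o]
  tgt_gapped <- tgt_chars
  tgt_gapped[del_mask] <- "-"
  tgt_row <- c(tgt_gapped, ins_chars)[o]
  out_txt <- paste(out_row, collapse = "")
  tgt_txt <- paste(tgt_row, collapse = "")
  sis_txt <- paste(sis_row, collapse = "")
  tgt_seq <- gsub("-", "", tgt_txt, fixed = TRUE)
  pair_blocks <- tibble(
    ref_name = seqid, ref_start = 0L, ref_size = L, ref_strand = "+",
    ref_src_size = L, ref_text = out_txt,
    qry_name = "target_chr1", qry_start = 0L, qry_size = nchar(tgt_seq),
    qry_strand = "+", qry_src_size = nchar(tgt_seq), qry_text = tgt_txt
  )
  list(
    genomes = c(reference = ref_seq, target = tgt_seq, sister = ref_seq),
    models = bind_rows(models),
    blocks3 = tibble(outgroup = out_txt, target = tgt_txt, sister = sis_txt),
    pair_blocks = validate_pair_blocks(pair_blocks),
    truth = list(
      splice_errors = sp_err,
      indel_events = ind,
      n_splice_nt = length(splice_nt),
      ref_length = L
    )
  )
}
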