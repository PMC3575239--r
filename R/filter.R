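#' Per-codon filter mask with an ordered rule ledger
#'
#' Tracks, for every codon column of an alignment, whether it is kept or
#' which rule first removed it. A removed codon is never resurrected, and
#' the ledger (one entry per rule application, with the codons newly
#' removed) replays to the final mask.
#'
#' @param n_codons Number of codon columns.
#' @return A `filter_mask` tibble `(codon, removed, rule)` with an empty
#'   `ledger` attribute.
#' @export
filter_mask <- function(n_codons) {
  m <- tibble(codon = seq_len(n_codons), removed = FALSE,
              rule = NA_character_)
  structure(m, ledger = tibble(step = integer(), rule = character(),
                               n_removed = integer(), removed = list()),
            class = c("filter_mask", class(m)))
}

# record newly removed codons under a rule; already-removed codons stay
# attributed to their first rule
mask_remove <- function(mask, codons, rule) {
  new <- setdiff(codons, mask$codon[mask$removed])
  mask$removed[mask$codon %in% new] <- TRUE
  mask$rule[mask$codon %in% new] <- rule
  led <- attr(mask, "ledger")
  led <- bind_rows(led, tibble(step = nrow(led) + 1L, rule = rule,
                               n_removed = length(new),
                               removed = list(sort(as.integer(new)))))
  structure(mask, ledger = led, class = class(mask))
}

#' Replay a filter ledger onto a fresh mask
#'
#' @param mask A `filter_mask` whose ledger to replay.
#' @param n_codons Number of codons of the target mask.
#' @return A `filter_mask` equal to `mask` (same removed set and rules).
#' @export
replay_ledger <- function(mask, n_codons = nrow(mask)) {
  out <- filter_mask(n_codons)
  led <- attr(mask, "ledger")
  for (i in seq_len(nrow(led))) {
    out <- mask_remove(out, led$removed[[i]], led$rule[i])
  }
  out
}

#' Remove codons containing a low-quality base
#'
#' A codon column is removed when any species with quality data carries a
#' base with phred score less than or equal to `threshold` in that codon
#' (the boundary is inclusive: a phred-30 base is removed at the default
#' threshold of 30, which corresponds to a 0.1% base-call error rate).
#'
#' @param aln A [codon_alignment()].
#' @param mask Optional existing mask to extend.
#' @param threshold Inclusive phred cutoff (default 30).
#' @return Updated `filter_mask`.
#' @export
mask_low_quality_codons <- function(aln, mask = NULL, threshold = 30) {
  if (is.null(mask)) mask <- filter_mask(aln$n_codons)
  if (is.null(aln$qualities)) return(mask_remove(mask, integer(0), "quality"))
  bad_nt <- colSums(aln$qualities <= threshold, na.rm = TRUE) > 0
  bad_codon <- which(colSums(matrix(bad_nt, nrow = 3L)) > 0)
  mask_remove(mask, bad_codon, "quality")
}

#' Remove codon columns containing a gap in any species
#'
#' @param aln A [codon_alignment()].
#' @param mask Optional existing mask to extend.
#' @return Updated `filter_mask`.
#' @export
remove_gap_columns <- function(aln, mask = NULL) {
  if (is.null(mask)) mask <- filter_mask(aln$n_codons)
  gap_nt <- colSums(aln$bases == "-") > 0
  bad_codon <- which(colSums(matrix(gap_nt, nrow = 3L)) > 0)
  mask_remove(mask, bad_codon, "gap")
}

# mismatch indicator between two gapped rows, NA-safe: positions where
# either base is a gap or N do not count as substitutions
pair_mismatch <- function(a, b) {
  ok <- a != "-" & b != "-" & a != "N" & b != "N"
  ok & a != b
}

#' Remove columns in substitution-dense windows between a species pair
#'
#' Windows of `window_nt` nucleotides are slid (step 1) along the
#' concatenated nucleotides of the codons still kept by `mask`; every
#' nucleotide covered by any window containing strictly more than
#' `max_subs` substitutions between the two named species is removed
#' (a window with exactly `max_subs` is kept). A codon is removed when any
#' of its three nucleotides is removed. Such substitution runs typically
#' reflect alignment or sequencing error rather than real divergence.
#'
#' @param aln A [codon_alignment()].
#' @param species_pair Length-2 character vector naming the pair.
#' @param mask Optional existing mask; the windows run over kept codons.
#' @param window_nt Window length in nucleotides (default 15).
#' @param max_subs Maximum tolerated substitutions per window (default 5).
#' @param mode `"sliding"` (step 1, default) or `"tiled"` (non-overlapping).
#' @return Updated `filter_mask`.
#' @export
window_substitution_filter <- function(aln, species_pair, mask = NULL,
                                       window_nt = 15, max_subs = 5,
                                       mode = c("sliding", "tiled")) {
  mode <- match.arg(mode)
  if (is.null(mask)) mask <- filter_mask(aln$n_codons)
  if (!all(species_pair %in% aln$species)) {
    abort("both species of species_pair must be present in the alignment")
  }
  kept <- mask$codon[!mask$removed]
  if (!length(kept)) return(mask_remove(mask, integer(0), "window"))
  cols <- codon_nt_cols(kept)
  a <- aln$bases[species_pair[1], cols]
  b <- aln$bases[species_pair[2], cols]
  mm <- as.integer(pair_mismatch(a, b))
  M <- length(mm)
  flagged <- logical(M)
  if (M >= window_nt) {
    cs <- cumsum(c(0L, mm))
    if (mode == "sliding") {
      starts <- seq_len(M - window_nt + 1L)
    } else {
      starts <- seq.int(1L, M - window_nt + 1L, by = window_nt)
    }
    wsum <- cs[starts + window_nt] - cs[starts]
    bad <- starts[wsum > max_subs]
    if (length(bad)) flagged <- mark_ranges(M, bad, bad + window_nt - 1L)
  }
  bad_kept_codon <- unique((which(flagged) - 1L) %/% 3L + 1L)
  mask_remove(mask, kept[bad_kept_codon], "window")
}

#' Remove codons flanking previously filtered sequence
#'
#' Every kept codon lying within `flank_codons` codon positions (in original
#' alignment coordinates) of any already-removed codon is removed, in a
#' single pass: codons removed by this rule do not seed further flanks.
#' Codons adjacent to filtered sequence are otherwise enriched for spurious
#' positively selected sites.
#'
#' @param mask A `filter_mask` with prior removals.
#' @param flank_codons Flank width in codons (default 7).
#' @return Updated `filter_mask`.
#' @export
flank_removal <- function(mask, flank_codons = 7) {
  removed <- mask$codon[mask$removed]
  if (!length(removed)) return(mask_remove(mask, integer(0), "flank"))
  n <- nrow(mask)
  dil <- mark_ranges(n, removed - flank_codons, removed + flank_codons)
  mask_remove(mask, which(dil), "flank")
}

#' Keep-or-discard decision for a filtered gene
#'
#' A gene is discarded when its remaining codons number fewer than
#' `min_frac` of the predicted codon count, or fewer than `min_codons`
#' (boundaries: exactly `min_codons` remaining, or exactly `min_frac` of
#' predicted, is kept).
#'
#' @param aln A [codon_alignment()].
#' @param mask A `filter_mask`.
#' @param min_codons Minimum remaining codons (default 100).
#' @param min_frac Minimum remaining fraction of predicted codons
#'   (default 0.10).
#' @return List: `keep` (logical), `reason` (`NA` if kept), `remaining`.
#' @export
discard_gene <- function(aln, mask, min_codons = 100, min_frac = 0.10) {
  remaining <- sum(!mask$removed)
  frac_fail <- remaining < min_frac * aln$predicted_codon_count
  len_fail <- remaining < min_codons
  reason <- if (frac_fail && len_fail) "fraction_and_length" else
    if (frac_fail) "fraction" else if (len_fail) "length" else NA_character_
  list(keep = !(frac_fail || len_fail), reason = reason,
       remaining = remaining)
}

#' Run the full codon-alignment filtering cascade
#'
#' Applies, in order: an externally produced column mask if supplied (e.g.
#' SEG/GBLOCKS/GUIDANCE output, read from file — never computed here), gap
#' removal, quality masking, the paired substitution-window filter, flank
#' removal, and the keep/discard decision. Every stage only shrinks the
#' kept set, and the per-rule ledger replays to the final mask.
#'
#' @param aln A [codon_alignment()].
#' @param species_pair Pair for the window filter; `NULL` skips that stage.
#' @param external_mask Optional integer vector of codon columns removed by
#'   external tools.
#' @param phred_min Inclusive phred threshold (default 30).
#' @param window_nt,max_subs,window_mode Window filter settings.
#' @param flank_codons Flank width (default 7).
#' @param min_codons,min_frac Discard-rule settings.
#' @return A `filter_result` list: `alignment` (kept codons), `mask`,
#'   `report` (per-rule removals tibble), `keep`, `reason`, `remaining`.
#' @export
run_filter_cascade <- function(aln, species_pair = c("target", "sister"),
                               external_mask = NULL,
                               phred_min = 30, window_nt = 15, max_subs = 5,
                               window_mode = "sliding", flank_codons = 7,
                               min_codons = 100, min_frac = 0.10) {
  mask <- filter_mask(aln$n_codons)
  if (!is.null(external_mask)) {
    if (any(external_mask < 1L | external_mask > aln$n_codons)) {
      abort("external_mask codons out of range")
    }
    mask <- mask_remove(mask, external_mask, "external")
  }
  mask <- remove_gap_columns(aln, mask)
  mask <- mask_low_quality_codons(aln, mask, threshold = phred_min)
  if (!is.null(species_pair)) {
    mask <- window_substitution_filter(aln, species_pair, mask,
                                       window_nt = window_nt,
                                       max_subs = max_subs,
                                       mode = window_mode)
  }
  mask <- flank_removal(mask, flank_codons = flank_codons)
  decision <- discard_gene(aln, mask, min_codons = min_codons,
                           min_frac = min_frac)
  led <- attr(mask, "ledger")
  report <- led |>
    select("step", "rule", "n_removed") |>
    mutate(remaining = aln$n_codons - cumsum(.data$n_removed))
  structure(list(
    alignment = apply_mask(aln, mask),
    mask = mask,
    report = report,
    keep = decision$keep,
    reason = decision$reason,
    remaining = decision$remaining
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %d codons remain; %s\n",
              x$remaining,
              if (x$keep) "gene kept" else paste0("discarded (", x$reason, ")")))
  print(x$report)
  invisible(x)
}
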