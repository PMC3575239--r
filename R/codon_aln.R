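#' Codon alignment container
#'
#' A species-by-nucleotide character matrix constrained to whole codons
#' (columns come in triplets), with optional per-base phred qualities and
#' the gene's predicted codon count (the denominator of the discard rule).
#' Gaps are '-' characters; a gap always spans a whole codon in practice
#' but the container does not enforce it.
#'
#' @param bases Character matrix, species x nucleotides (single characters).
#' @param qualities Optional integer matrix of phred scores, same shape;
#'   `NA` where no quality is available (e.g. gaps, or species without
#'   quality data).
#' @param species Character vector of row names.
#' @param predicted_codon_count The gene's predicted codon number.
#' @return A `codon_alignment` object.
#' @export
codon_alignment <- function(bases, qualities = NULL, species = rownames(bases),
                            predicted_codon_count = ncol(bases) %/% 3L) {
  stopifnot(is.matrix(bases), ncol(bases) %% 3L == 0L)
  if (is.null(species)) species <- paste0("sp", seq_len(nrow(bases)))
  if (!is.null(qualities)) {
    stopifnot(is.matrix(qualities), all(dim(qualities) == dim(bases)))
  }
  rownames(bases) <- species
  structure(list(
    bases = bases,
    qualities = qualities,
    species = species,
    n_codons = ncol(bases) %/% 3L,
    predicted_codon_count = as.integer(predicted_codon_count)
  ), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d species x %d codons (predicted %d)\n",
              length(x$species), x$n_codons, x$predicted_codon_count))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.codon_alignment <- function(x, ...) {
  tibble(
    species = rep(x$species, each = ncol(x$bases)),
    nt = rep(seq_len(ncol(x$bases)), times = length(x$species)),
    codon = rep((seq_len(ncol(x$bases)) - 1L) %/% 3L + 1L,
                times = length(x$species)),
    base = as.vector(t(x$bases)),
    quality = if (is.null(x$qualities)) NA_integer_ else as.vector(t(x$qualities))
  )
}

# nucleotide column indices of a codon index vector
codon_nt_cols <- function(codons) {
  as.vector(vapply(codons, function(cdn) (cdn - 1L) * 3L + 1:3, integer(3)))
}

#' Subset a codon alignment to the codons kept by a mask
#'
#' @param aln A [codon_alignment()].
#' @param mask A [filter_mask()].
#' @return A new `codon_alignment` containing only kept codons;
#'   `predicted_codon_count` is carried over unchanged.
#' @export
apply_mask <- function(aln, mask) {
  keep <- mask$codon[!mask$removed]
  cols <- if (length(keep)) codon_nt_cols(keep) else integer(0)
  codon_alignment(
    aln$bases[, cols, drop = FALSE],
    if (is.null(aln$qualities)) NULL else aln$qualities[, cols, drop = FALSE],
    species = aln$species,
    predicted_codon_count = aln$predicted_codon_count
  )
}

#' Generate a codon-alignment fixture with planted defects
#'
#' All species start from one shared random codon sequence (so the
#' background mismatch count is zero) with uniform base quality. Defects are
#' planted at recorded positions: low-quality bases (phred drawn from 0 to
#' the masking threshold), whole-codon gaps in one species, and substitution
#' bursts (clustered mismatches between the first two species within a short
#' nucleotide span). The returned alignment carries a `planted` attribute, a
#' machine-readable ledger against which filter outputs can be asserted
#' exactly.
#'
#' @param n_species Number of species (first two form the comparison pair).
#' @param n_codons Codons per species.
#' @param n_low_quality Codons receiving one low-quality base.
#' @param n_gap_codons Codons gapped (whole codon) in one random species.
#' @param n_bursts Substitution bursts planted between species 1 and 2.
#' @param burst_subs Substitutions per burst.
#' @param burst_span_nt Nucleotide span of each burst.
#' @param base_quality Background phred score (default 40).
#' @param predicted_codon_count Predicted codon number (default `n_codons`).
#' @param seed Integer seed; regeneration is bit-identical.
#' @return A `codon_alignment` with attribute `planted`: list of tibbles
#'   `low_quality (species, codon, nt)`, `gaps (species, codon)`,
#'   `bursts (start_nt, end_nt, n_subs)`.
#' @export
make_codon_fixture <- function(n_species = 4, n_codons = 200,
                               n_low_quality = 0, n_gap_codons = 0,
                               n_bursts = 0, burst_subs = 6,
                               burst_span_nt = 15, base_quality = 40,
                               predicted_codon_count = n_codons,
                               seed = 1L) {
  stopifnot(n_codons >= 1, n_species >= 2, burst_subs <= burst_span_nt)
  set.seed(seed)
  n_nt <- 3L * n_codons
  template <- sample(BASES, n_nt, replace = TRUE)
  bases <- matrix(rep(template, each = n_species), nrow = n_species)
  qual <- matrix(as.integer(base_quality), n_species, n_nt)
  species <- c("target", "sister",
               if (n_species > 2) paste0("out", seq_len(n_species - 2)))
  # disjoint codon pools per defect type so ledgers compose cleanly
  n_burst_codons <- n_bursts * ceiling(burst_span_nt / 3)
  if (n_low_quality + n_gap_codons + n_burst_codons > n_codons) {
    abort("planted features exceed available codons",
          class = "nimtools_fixture_error")
  }
  free <- sample.int(n_codons)
  take <- function(k) {
    out <- free[seq_len(k)]
    free <<- free[-seq_len(k)]
    sort(out)
  }
  lq <- if (n_low_quality > 0) {
    cdn <- take(n_low_quality)
    sp <- sample.int(n_species, n_low_quality, replace = TRUE)
    nt_off <- sample.int(3L, n_low_quality, replace = TRUE)
    nt <- (cdn - 1L) * 3L + nt_off
    q <- sample(0:30, n_low_quality, replace = TRUE)
    for (i in seq_len(n_low_quality)) qual[sp[i], nt[i]] <- q[i]
    tibble(species = species[sp], codon = cdn, nt = nt, phred = q)
  } else tibble(species = character(), codon = integer(), nt = integer(),
                phred = integer())
  gp <- if (n_gap_codons > 0) {
    cdn <- take(n_gap_codons)
    sp <- sample.int(n_species, n_gap_codons, replace = TRUE)
    for (i in seq_len(n_gap_codons)) {
      cols <- codon_nt_cols(cdn[i])
      bases[sp[i], cols] <- "-"
      qual[sp[i], cols] <- NA_integer_
    }
    tibble(species = species[sp], codon = cdn)
  } else tibble(species = character(), codon = integer())
  br <- if (n_bursts > 0) {
    # bursts start on a codon boundary and need a contiguous free codon run
    span_codons <- ceiling(burst_span_nt / 3)
    rows <- vector("list", n_bursts)
    for (b in seq_len(n_bursts)) {
      cand <- free[free + span_codons - 1L <= n_codons]
      cand <- cand[vapply(cand, function(a)
        all(seq.int(a, a + span_codons - 1L) %in% free), logical(1))]
      if (!length(cand)) {
        abort("no contiguous codon run left for a substitution burst",
              class = "nimtools_fixture_error")
      }
      anchor <- if (length(cand) == 1L) cand else sample(cand, 1L)
      free <- setdiff(free, seq.int(anchor, anchor + span_codons - 1L))
      start_nt <- (anchor - 1L) * 3L + 1L
      end_nt <- min(start_nt + burst_span_nt - 1L, n_nt)
      at <- sort(sample(start_nt:end_nt, burst_subs))
      old <- bases[2L, at]
      shift <- sample.int(3L, burst_subs, replace = TRUE)
      bases[2L, at] <- BASES[((match(old, BASES) - 1L + shift) %% 4L) + 1L]
      rows[[b]] <- tibble(start_nt = start_nt, end_nt = end_nt,
                          n_subs = burst_subs)
    }
    bind_rows(rows)
  } else tibble(start_nt = integer(), end_nt = integer(), n_subs = integer())
  aln <- codon_alignment(bases, qual, species, predicted_codon_count)
  attr(aln, "planted") <- list(low_quality = lq, gaps = gp, bursts = br)
  aln
}
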