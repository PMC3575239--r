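# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain column walks and explicit enumerations.

# inter-gap segments by walking columns one at a time
igs_brute <- function(ref_text, qry_text) {
  r <- strsplit(ref_text, "")[[1]]
  q <- strsplit(qry_text, "")[[1]]
  n <- length(r)
  lens <- integer(0)
  trunc <- logical(0)
  cur <- 0L
  started_at_edge <- FALSE
  for (i in seq_len(n)) {
    if (r[i] != "-" && q[i] != "-") {
      if (cur == 0L) started_at_edge <- (i == 1L)
      cur <- cur + 1L
    } else if (cur > 0L) {
      lens <- c(lens, cur)
      trunc <- c(trunc, started_at_edge)
      cur <- 0L
    }
  }
  if (cur > 0L) {
    lens <- c(lens, cur)
    trunc <- c(trunc, TRUE) # runs to the final column
  }
  data.frame(length = lens, boundary_truncated = trunc)
}

# three-way indel events by walking columns
threeway_brute <- function(out_txt, tgt_txt, sis_txt) {
  o <- strsplit(out_txt, "")[[1]]
  t <- strsplit(tgt_txt, "")[[1]]
  s <- strsplit(sis_txt, "")[[1]]
  n <- length(o)
  events <- 0L
  prev_pat <- 0L
  for (i in seq_len(n)) {
    pat <- (o[i] == "-") + 2L * (t[i] == "-") + 4L * (s[i] == "-")
    if (pat != prev_pat && pat %in% c(2L, 5L)) events <- events + 1L
    prev_pat <- pat
  }
  list(events = events, aligned_kb = sum(o != "-") / 1000)
}

# which codons contain a base at or below the phred threshold
quality_brute <- function(aln, threshold = 30) {
  bad <- integer(0)
  for (cdn in seq_len(aln$n_codons)) {
    cols <- (cdn - 1L) * 3L + 1:3
    q <- aln$qualities[, cols]
    if (any(!is.na(q) & q <= threshold)) bad <- c(bad, cdn)
  }
  bad
}

# which codons contain a gap character in any species
gap_brute <- function(aln) {
  bad <- integer(0)
  for (cdn in seq_len(aln$n_codons)) {
    cols <- (cdn - 1L) * 3L + 1:3
    if (any(aln$bases[, cols] == "-")) bad <- c(bad, cdn)
  }
  bad
}

# codons removed by the sliding-window substitution rule, enumerating every
# window explicitly over the kept-codon nucleotide sequence
window_brute <- function(aln, pair, kept_codons, window_nt = 15, max_subs = 5) {
  cols <- unlist(lapply(kept_codons, function(cdn) (cdn - 1L) * 3L + 1:3))
  a <- aln$bases[pair[1], cols]
  b <- aln$bases[pair[2], cols]
  mm <- a != "-" & b != "-" & a != "N" & b != "N" & a != b
  M <- length(mm)
  flagged <- rep(FALSE, M)
  if (M >= window_nt) {
    for (st in 1:(M - window_nt + 1L)) {
      win <- st:(st + window_nt - 1L)
      if (sum(mm[win]) > max_subs) flagged[win] <- TRUE
    }
  }
  sort(unique(kept_codons[(which(flagged) - 1L) %/% 3L + 1L]))
}

# single-pass flank dilation of a removed-codon set
flank_brute <- function(removed, n_codons, flank = 7) {
  out <- logical(n_codons)
  for (r in removed) {
    lo <- max(1L, r - flank)
    hi <- min(n_codons, r + flank)
    out[lo:hi] <- TRUE
  }
  sort(setdiff(which(out), removed))
}

# exhaustive hypergeometric upper tail: enumerate every placement of the K
# "selected" labels over N sites and count placements with >= k in the first n
hyper_enum <- function(k, n, K, N) {
  if (K == 0) return(as.numeric(k <= 0))
  picks <- utils::combn(N, K)
  hits <- colSums(picks <= n)
  mean(hits >= k)
}

# convenience: removed set of a mask
removed_set <- function(mask) sort(mask$codon[mask$removed])
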