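#' Simulation parameters for the two-branch indel simulator
#'
#' Bundles and validates the parameters of [simulate_alignment()]. The
#' simulator realises the null model behind the Neutral Indel Model —
#' insertions and deletions accumulating uniformly at random in neutral
#' sequence — plus optional indel-free constrained elements whose purging of
#' indels is what the downstream estimator detects.
#'
#' @param genome_length Ancestral genome length in bases.
#' @param indel_rate Expected indel events per neutral ancestral base on
#'   *each* branch (the per-branch rate theta).
#' @param indel_mean_length Mean of the geometric indel length distribution
#'   (lengths are `1 + Geom`, so the mean must be >= 1).
#' @param substitution_rate Per-base substitution probability on each branch.
#' @param constrained_fraction Proportion of ancestral bases inside
#'   constrained (indel-free) elements; in `[0, 1)`.
#' @param element_length Length of each constrained element, bases.
#' @param gc_profile Per-window target G+C fraction; recycled across windows.
#'   A single value gives a homogeneous genome; a vector gives a GC gradient.
#' @param gc_window Window length (bases) over which `gc_profile` applies.
#' @param element_weight_by_gc If `TRUE`, constrained elements are placed
#'   preferentially in high-GC windows (probability proportional to the
#'   squared window GC target), producing a monotone GC-versus-constraint
#'   structure; if `FALSE` placement is uniform.
#' @param seed Integer seed; identical parameters (including seed) give
#'   byte-identical output.
#' @return A `sim_params` object (a validated list).
#' @export
sim_params <- function(genome_length = 1e6,
                       indel_rate = 0.005,
                       indel_mean_length = 3,
                       substitution_rate = 0.05,
                       constrained_fraction = 0,
                       element_length = 500,
                       gc_profile = 0.42,
                       gc_window = 10000,
                       element_weight_by_gc = FALSE,
                       seed = 1L) {
  stopifnot(
    length(genome_length) == 1L, genome_length >= 1,
    indel_rate >= 0, substitution_rate >= 0,
    indel_mean_length >= 1,
    constrained_fraction >= 0, constrained_fraction < 1,
    element_length >= 1, gc_window >= 1,
    all(gc_profile >= 0), all(gc_profile <= 1)
  )
  p <- list(
    genome_length = as.double(genome_length),
    indel_rate = indel_rate,
    indel_mean_length = indel_mean_length,
    substitution_rate = substitution_rate,
    constrained_fraction = constrained_fraction,
    element_length = as.integer(element_length),
    gc_profile = gc_profile,
    gc_window = as.integer(gc_window),
    element_weight_by_gc = isTRUE(element_weight_by_gc),
    seed = as.integer(seed)
  )
  structure(p, class = "sim_params")
}

# non-overlapping element placement; returns tibble(start, end) 1-based incl.
place_elements <- function(L, n_elem, elen, win_weights = NULL, gc_window = NULL) {
  if (n_elem == 0L) return(tibble(start = integer(), end = integer()))
  free <- L - as.double(n_elem) * elen
  if (free < 0) {
    abort(sprintf(
      "cannot place %d elements of %d bp in %g bp of sequence",
      n_elem, elen, L
    ), class = "nimtools_placement_error")
  }
  if (is.null(win_weights)) {
    # spacing construction: exact, no rejection
    gaps <- sort(runif(n_elem, 0, free))
    start <- as.integer(floor(gaps)) + (seq_len(n_elem) - 1L) * elen + 1L
    return(tibble(start = start, end = start + elen - 1L))
  }
  # GC-weighted placement: draw windows by weight, rejection-resolve overlaps
  placed_start <- integer(0)
  remaining <- n_elem
  nwin <- length(win_weights)
  for (iter in 1:200) {
    if (remaining == 0L) break
    win <- sample.int(nwin, remaining, replace = TRUE, prob = win_weights)
    off <- sample.int(gc_window, remaining, replace = TRUE)
    cand <- (win - 1L) * gc_window + off
    cand <- sort(unique(cand[cand + elen - 1L <= L]))
    if (length(placed_start) && length(cand)) {
      i <- findInterval(cand, placed_start)
      bad_left <- i >= 1L & placed_start[pmax(i, 1L)] + elen - 1L >= cand
      nxt <- pmin(i + 1L, length(placed_start))
      bad_right <- i < length(placed_start) & placed_start[nxt] <= cand + elen - 1L
      cand <- cand[!(bad_left | bad_right)]
    }
    if (length(cand) > 1L) { # greedy left-to-right self-overlap removal
      keep <- logical(length(cand))
      last_end <- -1L
      for (k in seq_along(cand)) {
        if (cand[k] > last_end) {
          keep[k] <- TRUE
          last_end <- cand[k] + elen - 1L
        }
      }
      cand <- cand[keep]
    }
    if (length(cand) > remaining) cand <- cand[seq_len(remaining)]
    placed_start <- sort(c(placed_start, cand))
    remaining <- n_elem - length(placed_start)
  }
  if (remaining > 0L) {
    abort("could not place all constrained elements without overlap",
          class = "nimtools_placement_error")
  }
  tibble(start = placed_start, end = placed_start + elen - 1L)
}

# draw indel events on one branch; footprints avoid elements (rejection)
draw_events <- function(L, n_ev, mean_len, elem) {
  if (n_ev == 0L) {
    return(tibble(pos = integer(), len = integer(), is_del = logical()))
  }
  geo_p <- 1 / mean_len
  pos <- sample.int(L, n_ev, replace = TRUE)
  len <- rgeom(n_ev, geo_p) + 1L
  is_del <- runif(n_ev) < 0.5
  if (nrow(elem) > 0L) {
    st <- elem$start; en <- elem$end
    for (iter in 1:200) {
      # deletion footprint [pos, pos+len-1]; insertion point is "before pos"
      i <- findInterval(pos, st)
      del_end <- pmin(L, pos + len - 1L)
      hit_left <- i >= 1L & en[pmax(i, 1L)] >= pos
      nxt <- pmin(i + 1L, length(st))
      hit_right <- i < length(st) & st[nxt] <= del_end
      del_bad <- is_del & (hit_left | hit_right)
      j <- findInterval(pos - 1L, st)
      ins_bad <- !is_del & j >= 1L & pos <= en[pmax(j, 1L)]
      bad <- del_bad | ins_bad
      if (!any(bad)) break
      pos[bad] <- sample.int(L, sum(bad), replace = TRUE)
      if (iter == 200L) {
        abort("indel rejection sampling failed to escape constrained elements",
              class = "nimtools_placement_error")
      }
    }
  }
  tibble(pos = pos, len = as.integer(len), is_del = is_del)
}

# apply substitutions in-place on integer base codes 1..4
substitute_codes <- function(code, rate) {
  if (rate <= 0) return(code)
  idx <- which(runif(length(code)) < rate)
  if (length(idx)) {
    shift <- sample.int(3L, length(idx), replace = TRUE)
    code[idx] <- ((code[idx] - 1L + shift) %% 4L) + 1L
  }
  code
}

#' Simulate a pairwise alignment under neutral indel accumulation
#'
#' Evolves an ancestral sequence down two independent branches. On each
#' branch, indel events (insertion or deletion with equal probability,
#' geometric lengths) occur uniformly at rate `indel_rate` per neutral base;
#' events whose footprint would touch a constrained element are redrawn
#' outside, so constrained elements are exactly indel-free. Substitutions are
#' applied everywhere. The true alignment of the two descendant sequences is
#' assembled from the event bookkeeping (never re-inferred by alignment), so
#' the returned blocks are exact, and a truth ledger reports the constrained
#' intervals and realised event counts.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `sim_alignment`:
#' \describe{
#'   \item{blocks}{one-row pairwise alignment block tibble (see [read_maf()]
#'     for the column contract); reference row is species "simA".}
#'   \item{sequences}{named character vector of the two ungapped descendant
#'     genomes (`simA`, `simB`).}
#'   \item{truth}{list with `true_constrained_bases`,
#'     `element_intervals` (0-based half-open tibble),
#'     `constrained_by_window`, `realized_indel_events` per branch, and the
#'     per-branch `events` tables (ancestral position, length, type).}
#'   \item{params}{the input parameters.}
#' }
#' @export
simulate_alignment <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  L <- as.integer(params$genome_length)
  nwin <- ceiling(L / params$gc_window)
  win_gc <- rep(params$gc_profile, length.out = nwin)
  gc_base <- rep(win_gc, each = params$gc_window)[seq_len(L)]

  # ancestral sequence as integer codes 1..4 = A,C,G,T
  is_gc <- runif(L) < gc_base
  coin <- runif(L) < 0.5
  code <- integer(L)
  code[is_gc] <- 2L + coin[is_gc]            # C or G
  code[!is_gc] <- 1L + 3L * coin[!is_gc]     # A or T

  # constrained elements
  elen <- params$element_length
  n_elem <- as.integer(round(params$constrained_fraction * L / elen))
  weights <- if (params$element_weight_by_gc) win_gc^2 else NULL
  elem <- place_elements(L, n_elem, elen, weights, params$gc_window)
  constrained_bases <- if (nrow(elem)) sum(elem$end - elem$start + 1L) else 0L
  neutral_bases <- L - constrained_bases

  # indel events per branch
  n_ev <- rpois(2L, params$indel_rate * neutral_bases)
  evA <- draw_events(L, n_ev[1], params$indel_mean_length, elem)
  evB <- draw_events(L, n_ev[2], params$indel_mean_length, elem)

  del_mask <- function(ev) {
    d <- ev[ev$is_del, ]
    mark_ranges(L, d$pos, d$pos + d$len - 1L)
  }
  delA <- del_mask(evA)
  delB <- del_mask(evB)

  codeA <- substitute_codes(code, params$substitution_rate)
  codeB <- substitute_codes(code, params$substitution_rate)

  insA <- evA[!evA$is_del, ]
  insB <- evB[!evB$is_del, ]
  nIA <- sum(insA$len); nIB <- sum(insB$len)
  insA_codes <- if (nIA) sample.int(4L, nIA, replace = TRUE) else integer(0)
  insB_codes <- if (nIB) sample.int(4L, nIB, replace = TRUE) else integer(0)

  # column assembly: ancestral columns keyed by position; insertions keyed
  # just before the base they precede (branch A's columns before branch B's)
  keep <- !(delA & delB)
  key_anc <- as.double(seq_len(L))[keep]
  keyA <- if (nIA) rep(insA$pos, insA$len) - 0.50 else double(0)
  keyB <- if (nIB) rep(insB$pos, insB$len) - 0.25 else double(0)
  o <- order(c(key_anc, keyA, keyB))

  colA <- codeA
  colA[delA] <- 5L
  colA <- c(colA[keep], insA_codes, rep(5L, nIB))[o]
  colB <- codeB
  colB[delB] <- 5L
  colB <- c(colB[keep], rep(5L, nIA), insB_codes)[o]

  chars <- c(BASES, "-")
  ref_text <- paste(chars[colA], collapse = "")
  qry_text <- paste(chars[colB], collapse = "")
  seqA <- paste(chars[colA[colA != 5L]], collapse = "")
  seqB <- paste(chars[colB[colB != 5L]], collapse = "")

  blocks <- tibble(
    ref_name = "simA", ref_start = 0L, ref_size = nchar(seqA),
    ref_strand = "+", ref_src_size = nchar(seqA), ref_text = ref_text,
    qry_name = "simB", qry_start = 0L, qry_size = nchar(seqB),
    qry_strand = "+", qry_src_size = nchar(seqB), qry_text = qry_text
  )

  by_window <- if (nrow(elem)) {
    pos <- unlist(Map(seq.int, elem$start, elem$end), use.names = FALSE)
    tibble(window = as.integer((pos - 1L) %/% params$gc_window)) |>
      count(.data$window, name = "constrained_bases")
  } else {
    tibble(window = integer(), constrained_bases = integer())
  }

  structure(list(
    blocks = blocks,
    sequences = c(simA = seqA, simB = seqB),
    truth = list(
      true_constrained_bases = constrained_bases,
      element_intervals = tibble(start = elem$start - 1L, end = elem$end),
      constrained_by_window = by_window,
      realized_indel_events = c(A = nrow(evA), B = nrow(evB)),
      events = list(A = evA, B = evB)
    ),
    params = params
  ), class = "sim_alignment")
}

#' @export
print.sim_alignment <- function(x, ...) {
  cat(sprintf(
    "<sim_alignment> %s ancestral bases, %d constrained bases, %d/%d indel events (A/B)\n",
    format(x$params$genome_length, big.mark = ",", scientific = FALSE),
    x$truth$true_constrained_bases,
    x$truth$realized_indel_events[["A"]],
    x$truth$realized_indel_events[["B"]]
  ))
  invisible(x)
}
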