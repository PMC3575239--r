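#' Fit the neutral geometric IGS length distribution for one GC bin
#'
#' Under neutral indel accumulation the number of aligned bases between
#' successive indels is geometric, so observed counts O(l) of inter-gap
#' segment lengths decay as `O(l) = scale * (1-p)^l` and `ln O(l)` is linear
#' in `l`. The fit is a count-weighted least-squares regression of
#' `ln O(l)` on `l` over a short-length window assumed free of constrained
#' sequence; the slope `b` gives the per-base indel rate `p = 1 - exp(b)`
#' and the mean neutral spacing `K = 1/p`.
#'
#' Zero-count lengths inside the window are dropped from the regression
#' (their log is undefined) but the fitted expectation is still evaluated at
#' every length.
#'
#' @param histogram An [build_histogram()] result.
#' @param bin GC bin id to fit.
#' @param fit_window Integer length range `c(lo, hi)` used for the fit
#'   (default `c(2, 50)`; length-1 segments are alignment-artifact-prone).
#' @return A `neutral_fit` list: `bin`, `p_hat`, `K`, `scale`,
#'   `fit_window`, `r_squared`, `n_segments`.
#' @export
fit_neutral_geometric <- function(histogram, bin, fit_window = c(2, 50)) {
  stopifnot(length(fit_window) == 2L, fit_window[1] < fit_window[2])
  h <- histogram[!is.na(histogram$gc_bin) & histogram$gc_bin == bin, ]
  h <- h[h$length >= fit_window[1] & h$length <= fit_window[2] & h$count > 0, ]
  if (nrow(h) < 2L) {
    abort(sprintf("bin %s: fewer than 2 distinct lengths in fit window", bin),
          class = "nimtools_fit_error")
  }
  fit <- stats::lm(log(count) ~ length, data = h, weights = h$count)
  b <- unname(stats::coef(fit)[2])
  if (b >= -1e-12) {
    abort(sprintf("bin %s: IGS counts do not decay over the fit window", bin),
          class = "nimtools_fit_error")
  }
  p_hat <- 1 - exp(b)
  structure(list(
    bin = bin,
    p_hat = p_hat,
    K = 1 / p_hat,
    scale = exp(unname(stats::coef(fit)[1])),
    slope = b,
    intercept = unname(stats::coef(fit)[1]),
    fit_window = as.integer(fit_window),
    r_squared = summary(fit)$r.squared,
    n_segments = sum(h$count)
  ), class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("<neutral_fit> bin %s: p = %.4g, K = %.1f bases (R2 = %.3f, n = %d)\n",
              format(x$bin), x$p_hat, x$K, x$r_squared, x$n_segments))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.neutral_fit <- function(x, ...) {
  tibble(bin = x$bin, p_hat = x$p_hat, K = x$K, scale = x$scale,
         fit_lo = x$fit_window[1], fit_hi = x$fit_window[2],
         r_squared = x$r_squared, n_segments = x$n_segments)
}

# expected count at length l under the fit
expected_counts <- function(fit, l) exp(fit$intercept + fit$slope * l)

# closed-form tails of the fitted expectation: sum_{l>=m} E(l), sum l*E(l)
expected_tail <- function(fit, m) {
  q <- exp(fit$slope)
  a <- exp(fit$intercept)
  s0 <- a * q^m / (1 - q)
  s1 <- a * q^m * (m + q * (1 - m)) / (1 - q)^2
  c(count = s0, bases = s1)
}

# default threshold: smallest length past the fit window where the fitted
# geometric tail probability drops below tail_prob, preferring the first
# such length with an observed excess
default_l_star <- function(fit, obs, tail_prob = 0.01) {
  lo <- fit$fit_window[2] + 1L
  tail_ok <- function(l) (1 - fit$p_hat)^(l - 1) < tail_prob
  l_tail <- lo
  while (!tail_ok(l_tail)) l_tail <- l_tail + 1L
  cand <- obs$length[obs$length >= l_tail &
                       obs$count > expected_counts(fit, obs$length)]
  if (length(cand)) min(cand) else l_tail
}

#' Estimate constrained (indel-purified) sequence from the IGS excess
#'
#' For each GC bin with a valid neutral fit, sums the observed-minus-expected
#' excess of segments at lengths `l >= l_star`: `S = sum(O - E)` segments and
#' `B = sum(l * (O - E))` bases, with the fitted expectation's infinite tail
#' evaluated in closed form. Each excess segment is assumed to carry between
#' `K` and `2K` neutral bases (depending on how functional elements cluster
#' within it), giving `lower = B - 2K*S` and `upper = B - K*S`. All
#' quantities are clamped at zero per bin.
#'
#' @param histogram An [build_histogram()] result.
#' @param fits A single `neutral_fit` or list of them (one per bin).
#' @param l_star Optional threshold length; must lie beyond the fit window.
#'   Default: smallest length past the window where the fitted tail
#'   probability is below 1% and an observed excess exists.
#' @param min_segments Bins with fewer segments than this in the fit window
#'   are flagged `low_confidence` and dropped from the aggregate.
#' @return A `constraint_estimate` tibble, one row per bin, with attribute
#'   `aggregate` (list: `S`, `B`, `lower`, `upper`, `aligned_bases`).
#' @export
estimate_constrained <- function(histogram, fits, l_star = NULL,
                                 min_segments = 1000) {
  if (inherits(fits, "neutral_fit")) fits <- list(fits)
  aligned <- attr(histogram, "aligned_bases")
  rows <- map_dfr(fits, function(fit) {
    if (!is.null(l_star) && l_star <= fit$fit_window[2]) {
      abort("l_star must lie beyond the fit window",
            class = "nimtools_parameter_error")
    }
    obs <- histogram[!is.na(histogram$gc_bin) & histogram$gc_bin == fit$bin, ]
    ls <- if (is.null(l_star)) default_l_star(fit, obs) else as.integer(l_star)
    tail_obs <- obs[obs$length >= ls, ]
    o_count <- sum(tail_obs$count)
    o_bases <- sum(as.double(tail_obs$length) * tail_obs$count)
    e <- expected_tail(fit, ls)
    S <- max(0, o_count - e[["count"]])
    B <- max(0, o_bases - e[["bases"]])
    lower <- max(0, B - 2 * fit$K * S)
    upper <- max(0, B - fit$K * S)
    ab <- aligned$aligned_bases[match(fit$bin, aligned$gc_bin)]
    tibble(
      bin = fit$bin, p_hat = fit$p_hat, K = fit$K, l_star = ls,
      n_segments = fit$n_segments,
      aligned_bases = ab %||% NA_real_,
      S_excess = S, B_excess = B, lower = lower, upper = upper,
      low_confidence = fit$n_segments < min_segments
    )
  })
  used <- rows[!rows$low_confidence, ]
  agg <- list(
    S = sum(used$S_excess), B = sum(used$B_excess),
    lower = sum(used$lower), upper = sum(used$upper),
    aligned_bases = sum(aligned$aligned_bases[!is.na(aligned$gc_bin)])
  )
  structure(rows, aggregate = agg,
            class = c("constraint_estimate", class(rows)))
}

#' Run the full neutral indel model analysis
#'
#' Pipeline: read or accept pairwise alignment blocks, weight genome windows
#' by aligned bases, split them into equally populated GC bins, extract
#' inter-gap segments, histogram their lengths, fit the neutral geometric
#' expectation per bin, and convert the long-segment excess into lower/upper
#' bounds on constrained sequence. Bins whose counts do not decay over the
#' fit window, or with too few segments, are excluded from the aggregate and
#' reported as unusable.
#'
#' @param x Pairwise alignment block tibble or a MAF path.
#' @param genome Reference genome (FASTA path, `DNAStringSet`, or named
#'   character vector). May be `NULL` only when `n_bins = 1`.
#' @param n_bins Number of GC bins (default 20).
#' @param window_size GC window size, bases (default 10 kb).
#' @param fit_window Length window for the neutral fit (default `c(2, 50)`).
#' @param l_star Optional excess threshold length (see
#'   [estimate_constrained()]).
#' @param min_segments Low-confidence cutoff per bin (default 1000).
#' @param exclude_pattern Sequence-name regex excluded from binning.
#' @param exclude_truncated Drop block-edge segments (default TRUE).
#' @param out_dir If non-NULL, write `per_bin.tsv`, `histogram.tsv` and
#'   `summary.json` there (deterministic content).
#' @return A `nim_result` list: `per_bin` (constraint_estimate tibble),
#'   `aggregate`, `fits`, `failed_bins`, `histogram`, `binner`, `config`.
#' @export
run_nim <- function(x, genome = NULL, n_bins = 20, window_size = 10000,
                    fit_window = c(2, 50), l_star = NULL,
                    min_segments = 1000,
                    exclude_pattern = "chrZ|chrW|chrUn|random",
                    exclude_truncated = TRUE, out_dir = NULL) {
  blocks <- if (is.character(x)) read_maf(x) else validate_pair_blocks(x)
  config <- list(n_bins = n_bins, window_size = window_size,
                 fit_window = fit_window, l_star = l_star,
                 min_segments = min_segments,
                 exclude_pattern = exclude_pattern,
                 exclude_truncated = exclude_truncated)
  empty <- function() {
    h <- build_histogram(extract_igs(blocks[0, ]))
    res <- list(
      per_bin = tibble(), aggregate = list(S = 0, B = 0, lower = 0, upper = 0,
                                           aligned_bases = 0),
      fits = list(), failed_bins = character(), histogram = h,
      binner = NULL, config = config
    )
    structure(res, class = "nim_result")
  }
  if (!nrow(blocks)) {
    res <- empty()
    if (!is.null(out_dir)) write_nim(res, out_dir)
    return(res)
  }
  binner <- NULL
  if (n_bins > 1 || !is.null(genome)) {
    if (is.null(genome)) {
      abort("a reference genome is required when n_bins > 1")
    }
    w <- aligned_bases_by_window(blocks, window_size)
    binner <- gc_binner(genome, window_size, n_bins, weights = w,
                        exclude_pattern = exclude_pattern)
  }
  segs <- extract_igs(blocks, binner)
  if (is.null(binner)) segs$gc_bin <- ifelse(is.na(segs$gc_bin), 1L, segs$gc_bin)
  hist <- build_histogram(segs, exclude_truncated = exclude_truncated)
  bins <- sort(unique(hist$gc_bin[!is.na(hist$gc_bin)]))
  if (!length(bins)) {
    res <- empty()
    if (!is.null(out_dir)) write_nim(res, out_dir)
    return(res)
  }
  fits <- list()
  failed <- character()
  for (b in bins) {
    f <- tryCatch(fit_neutral_geometric(hist, b, fit_window),
                  nimtools_fit_error = function(e) e)
    if (inherits(f, "neutral_fit")) {
      fits[[as.character(b)]] <- f
    } else {
      failed <- c(failed, as.character(b))
    }
  }
  if (!length(fits)) {
    res <- empty()
    res$failed_bins <- failed
    if (!is.null(out_dir)) write_nim(res, out_dir)
    return(res)
  }
  est <- estimate_constrained(hist, fits, l_star = l_star,
                              min_segments = min_segments)
  if (!is.null(binner)) {
    gcr <- binner$windows |>
      filter(!is.na(.data$gc_bin)) |>
      group_by(bin = .data$gc_bin) |>
      summarise(gc_lo = min(.data$gc), gc_hi = max(.data$gc),
                gc_mean = sum(.data$gc * .data$weight) /
                  pmax(sum(.data$weight), 1e-300),
                .groups = "drop")
    agg <- attr(est, "aggregate")
    est <- left_join(as_tibble(est), gcr, by = "bin")
    est <- structure(est, aggregate = agg,
                     class = c("constraint_estimate", class(est)))
  }
  res <- structure(list(
    per_bin = est,
    aggregate = attr(est, "aggregate"),
    fits = fits,
    failed_bins = failed,
    histogram = hist,
    binner = binner,
    config = config
  ), class = "nim_result")
  if (!is.null(out_dir)) write_nim(res, out_dir)
  res
}

#' @export
print.nim_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<nim_result> %d usable bin(s); constrained sequence %.0f-%.0f bases (%.2f-%.2f%% of %.0f aligned)\n",
    length(x$fits), a$lower, a$upper,
    if (a$aligned_bases > 0) 100 * a$lower / a$aligned_bases else 0,
    if (a$aligned_bases > 0) 100 * a$upper / a$aligned_bases else 0,
    a$aligned_bases
  ))
  invisible(x)
}

#' Broom-style tidiers for NIM results
#'
#' `tidy()` returns the per-bin table (for `nim_result`) or a one-row fit
#' summary (for `neutral_fit`); `glance()` returns the aggregate bounds.
#'
#' @param x A `nim_result` or `neutral_fit`.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.nim_result <- function(x, ...) as_tibble(x$per_bin)

#' @rdname tidiers
#' @export
glance.nim_result <- function(x, ...) {
  a <- x$aggregate
  tibble(
    n_bins_used = length(x$fits), n_bins_failed = length(x$failed_bins),
    S_excess = a$S, B_excess = a$B, lower = a$lower, upper = a$upper,
    aligned_bases = a$aligned_bases,
    lower_frac = if (a$aligned_bases > 0) a$lower / a$aligned_bases else 0,
    upper_frac = if (a$aligned_bases > 0) a$upper / a$aligned_bases else 0
  )
}

#' Write NIM outputs (TSV + JSON) to a directory
#'
#' Outputs are deterministic: identical inputs and configuration produce
#' byte-identical files.
#'
#' @param result A `nim_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_nim <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_bin <- if (nrow(as_tibble(result$per_bin))) as_tibble(result$per_bin) else
    tibble(bin = integer())
  write_tsv_strict(per_bin, file.path(out_dir, "per_bin.tsv"))
  write_igs_tsv(result$histogram, file.path(out_dir, "histogram.tsv"))
  a <- result$aggregate
  jsonlite::write_json(
    list(lower = a$lower, upper = a$upper, S_excess = a$S, B_excess = a$B,
         aligned_bases = a$aligned_bases,
         per_bin = per_bin),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' Histogram-versus-expectation plot for a NIM result
#'
#' One panel per GC bin: observed IGS length counts (points, log scale)
#' against the fitted neutral geometric expectation (line). The area where
#' observed counts exceed the line at long lengths is the signal converted
#' into the constrained-sequence estimate.
#'
#' @param object A `nim_result`.
#' @param bins Optional subset of bins to plot.
#' @param max_length Truncate the x axis (default: 99.9th percentile of
#'   observed lengths).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nim_result <- function(object, bins = NULL, max_length = NULL, ...) {
  h <- as_tibble(object$histogram)
  h <- h[!is.na(h$gc_bin), ]
  if (!is.null(bins)) h <- h[h$gc_bin %in% bins, ]
  if (is.null(max_length)) {
    max_length <- stats::quantile(rep(h$length, h$count), 0.999, names = FALSE)
  }
  h <- h[h$length <= max_length, ]
  exp_df <- map_dfr(object$fits, function(f) {
    if (!is.null(bins) && !(f$bin %in% bins)) return(NULL)
    l <- seq_len(max_length)
    tibble(gc_bin = f$bin, length = l, expected = expected_counts(f, l))
  })
  ggplot2::ggplot(h, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = exp_df,
                       ggplot2::aes(y = .data$expected), colour = "orange") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~gc_bin, scales = "free_y") +
    ggplot2::labs(x = "inter-gap segment length (bp)", y = "count",
                  title = "Observed IGS lengths vs neutral expectation")
}

#' Constraint-versus-GC plot
#'
#' Per-bin constrained-sequence density (midpoint of the lower/upper bounds
#' divided by aligned bases) against the bin's mean GC.
#'
#' @param result A `nim_result` produced with a genome (so bins carry GC).
#' @return A ggplot object.
#' @export
plot_constraint_vs_gc <- function(result) {
  pb <- as_tibble(result$per_bin)
  stopifnot("gc_mean" %in% names(pb))
  pb <- pb |>
    mutate(density = (.data$lower + .data$upper) / 2 /
             pmax(.data$aligned_bases, 1))
  ggplot2::ggplot(pb, ggplot2::aes(x = .data$gc_mean, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin mean G+C", y = "constrained fraction of aligned bases",
                  title = "Constrained-sequence density by G+C bin")
}
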