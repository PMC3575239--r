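test_that("no mutation yields two identical ungapped rows", {
  s <- simulate_alignment(sim_params(genome_length = 1e4, indel_rate = 0,
                                     substitution_rate = 0, seed = 3))
  expect_equal(nrow(s$blocks), 1L)
  expect_identical(s$blocks$ref_text, s$blocks$qry_text)
  expect_false(grepl("-", s$blocks$ref_text, fixed = TRUE))
  expect_identical(s$truth$realized_indel_events, c(A = 0L, B = 0L))
  expect_equal(nchar(s$blocks$ref_text), 1e4)
})

test_that("identical parameters reproduce byte-identical output", {
  p <- sim_params(genome_length = 5e4, indel_rate = 0.01,
                  substitution_rate = 0.05, constrained_fraction = 0.05,
                  seed = 11)
  s1 <- simulate_alignment(p)
  s2 <- simulate_alignment(p)
  expect_identical(s1$blocks, s2$blocks)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$truth, s2$truth)
})

test_that("gap-stripped rows reproduce each species' emitted sequence", {
  s <- simulate_alignment(sim_params(genome_length = 2e5, indel_rate = 0.01,
                                     substitution_rate = 0.05, seed = 7))
  expect_identical(gsub("-", "", s$blocks$ref_text, fixed = TRUE),
                   unname(s$sequences["simA"]))
  expect_identical(gsub("-", "", s$blocks$qry_text, fixed = TRUE),
                   unname(s$sequences["simB"]))
})

test_that("mean IGS length matches the realized delimiter density", {
  s <- neutral_sim_1mb()
  # oracle: count gap runs and aligned columns directly on the emitted text
  r <- charToRaw(s$blocks$ref_text) == charToRaw("-")
  q <- charToRaw(s$blocks$qry_text) == charToRaw("-")
  gap <- r | q
  runs <- rle(gap)
  n_delims <- sum(runs$values)
  aligned_cols <- sum(!gap)
  mean_igs <- mean(igs_brute(s$blocks$ref_text, s$blocks$qry_text)$length)
  expect_lt(abs(mean_igs - aligned_cols / n_delims) / (aligned_cols / n_delims),
            0.05)
})

test_that("constrained elements are placed to spec and stay indel-free", {
  p <- sim_params(genome_length = 1e6, indel_rate = 0.005,
                  substitution_rate = 0, constrained_fraction = 0.10,
                  element_length = 500, seed = 5)
  s <- simulate_alignment(p)
  expect_lte(abs(s$truth$true_constrained_bases - 1e5), 500)
  el <- s$truth$element_intervals # 0-based half-open
  expect_true(all(diff(el$start) > 0))
  expect_true(all(el$end > el$start))
  expect_true(all(el$start[-1] >= el$end[-nrow(el)]))
  # interval intersection check: no event footprint touches an element
  for (branch in c("A", "B")) {
    ev <- s$truth$events[[branch]]
    del <- ev[ev$is_del, ]
    if (nrow(del)) {
      # deletion footprint [pos, pos+len-1] 1-based = [pos-1, pos+len-1) 0-based
      for (j in seq_len(nrow(el))) {
        expect_false(any(del$pos - 1L < el$end[j] &
                           del$pos + del$len - 1L > el$start[j]),
                     info = paste("deletion overlaps element", j, "branch", branch))
      }
    }
    ins <- ev[!ev$is_del, ]
    if (nrow(ins)) {
      # insertion point "before base pos" is interior iff start < pos-1 < end
      for (j in seq_len(nrow(el))) {
        expect_false(any(ins$pos - 1L > el$start[j] & ins$pos - 1L < el$end[j]),
                     info = paste("insertion inside element", j, "branch", branch))
      }
    }
  }
})

test_that("infeasible element placement raises a placement error", {
  expect_error(
    simulate_alignment(sim_params(genome_length = 1000,
                                  constrained_fraction = 0.9,
                                  element_length = 251, seed = 1)),
    class = "nimtools_placement_error"
  )
})

test_that("neutral IGS lengths pass a geometric goodness-of-fit test", {
  s <- neutral_sim_1mb()
  segs <- igs_brute(s$blocks$ref_text, s$blocks$qry_text)
  x <- segs$length[!segs$boundary_truncated]
  expect_gt(length(x), 1e4)
  p_hat <- length(x) / sum(x)
  # chi-squared on length bins with expected mass from geometric(p_hat)
  brks <- c(0, stats::qgeom(seq(0.1, 0.9, by = 0.1), p_hat) + 1, Inf)
  obs <- table(cut(x, brks))
  pr <- diff(stats::pgeom(brks - 1, p_hat)) # support shifted to 1,2,...
  gof <- suppressWarnings(stats::chisq.test(obs, p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.001)
})

test_that("codon and GO fixtures regenerate identically under one seed", {
  a1 <- make_codon_fixture(n_codons = 80, n_low_quality = 5, n_gap_codons = 4,
                           n_bursts = 2, seed = 9)
  a2 <- make_codon_fixture(n_codons = 80, n_low_quality = 5, n_gap_codons = 4,
                           n_bursts = 2, seed = 9)
  expect_identical(a1$bases, a2$bases)
  expect_identical(a1$qualities, a2$qualities)
  expect_identical(attr(a1, "planted"), attr(a2, "planted"))
  g1 <- make_go_fixture(seed = 4)
  g2 <- make_go_fixture(seed = 4)
  expect_identical(g1$annotations, g2$annotations)
  expect_identical(g1$sites, g2$sites)
  f1 <- make_spliced_gene_fixture(n_splice_errors = 3, n_indel_errors = 4,
                                  seed = 2)
  f2 <- make_spliced_gene_fixture(n_splice_errors = 3, n_indel_errors = 4,
                                  seed = 2)
  expect_identical(f1$genomes, f2$genomes)
  expect_identical(f1$truth, f2$truth)
})

test_that("spliced-gene fixture plants exactly what its ledger says", {
  f <- make_spliced_gene_fixture(n_genes = 10, introns_per_gene = 5,
                                 n_splice_errors = 0, seed = 1)
  expect_equal(f$truth$n_splice_nt, 200L) # 50 introns x 4 nt
  expect_equal(nrow(f$truth$splice_errors), 0L)
  f3 <- make_spliced_gene_fixture(n_genes = 10, introns_per_gene = 5,
                                  n_splice_errors = 3, seed = 1)
  expect_equal(nrow(f3$truth$splice_errors), 3L)
  # the target really differs at exactly the ledgered positions
  ref <- strsplit(f3$genomes[["reference"]], "")[[1]]
  tgt_aln <- strsplit(f3$blocks3$target, "")[[1]]
  out_aln <- strsplit(f3$blocks3$outgroup, "")[[1]]
  ref_pos <- cumsum(out_aln != "-")
  for (i in seq_len(nrow(f3$truth$splice_errors))) {
    pos <- f3$truth$splice_errors$pos[i]
    col <- match(pos, ref_pos)
    expect_identical(tgt_aln[col], f3$truth$splice_errors$target_base[i])
    expect_false(tgt_aln[col] == ref[pos])
  }
})

test_that("codon fixture with no planted features is clean", {
  a <- make_codon_fixture(n_species = 3, n_codons = 50, seed = 1)
  expect_true(all(a$qualities == 40))
  expect_false(any(a$bases == "-"))
  expect_equal(a$n_codons, 50L)
  # planted burst is ledgered inside its span
  b <- make_codon_fixture(n_codons = 50, n_bursts = 1, burst_subs = 6, seed = 2)
  led <- attr(b, "planted")$bursts
  expect_equal(nrow(led), 1L)
  mm <- which(b$bases[1, ] != b$bases[2, ])
  expect_true(all(mm >= led$start_nt & mm <= led$end_nt))
  expect_equal(length(mm), 6L)
})
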