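test_that("quality masking is inclusive at the threshold", {
  a <- make_codon_fixture(n_species = 3, n_codons = 30, seed = 1)
  m <- mask_low_quality_codons(a)
  expect_equal(removed_set(m), integer(0))
  a$qualities[2, 14] <- 30L # codon 5, exactly at the threshold
  m30 <- mask_low_quality_codons(a)
  expect_equal(removed_set(m30), 5L)
  a$qualities[2, 14] <- 31L
  m31 <- mask_low_quality_codons(a)
  expect_equal(removed_set(m31), integer(0))
})

test_that("planted low-quality codons are removed exactly", {
  for (seed in 1:25) {
    a <- make_codon_fixture(n_codons = 60, n_low_quality = sample(1:8, 1),
                            seed = seed)
    m <- mask_low_quality_codons(a)
    expect_equal(removed_set(m), sort(attr(a, "planted")$low_quality$codon))
    expect_equal(removed_set(m), quality_brute(a))
  }
})

test_that("gap columns are removed at codon granularity", {
  a <- make_codon_fixture(n_species = 3, n_codons = 30, seed = 2)
  expect_equal(removed_set(remove_gap_columns(a)), integer(0))
  a$bases[3, 22:24] <- "-" # codon 8 gapped in one species
  m <- remove_gap_columns(a)
  expect_equal(removed_set(m), 8L)
  for (seed in 1:25) {
    b <- make_codon_fixture(n_codons = 60, n_gap_codons = sample(1:8, 1),
                            seed = seed + 100)
    expect_equal(removed_set(remove_gap_columns(b)), gap_brute(b))
    expect_equal(removed_set(remove_gap_columns(b)),
                 sort(attr(b, "planted")$gaps$codon))
  }
})

test_that("the 15-bp window rule keeps 5 substitutions and removes 6", {
  a5 <- make_codon_fixture(n_codons = 60, n_bursts = 1, burst_subs = 5,
                           seed = 3)
  m5 <- window_substitution_filter(a5, c("target", "sister"))
  expect_equal(removed_set(m5), integer(0))
  a6 <- make_codon_fixture(n_codons = 60, n_bursts = 1, burst_subs = 6,
                           seed = 3)
  m6 <- window_substitution_filter(a6, c("target", "sister"))
  expect_gt(length(removed_set(m6)), 0L)
  expect_equal(removed_set(m6),
               window_brute(a6, c("target", "sister"), 1:60))
})

test_that("window filtering equals brute-force enumeration on random data", {
  set.seed(40)
  for (i in 1:30) {
    a <- make_codon_fixture(n_codons = 50,
                            n_bursts = sample(0:2, 1),
                            burst_subs = sample(5:8, 1),
                            seed = i + 200)
    # add scattered background mismatches to exercise window edges
    n_extra <- sample(0:6, 1)
    if (n_extra) {
      at <- sample(150, n_extra)
      a$bases[2, at] <- ifelse(a$bases[2, at] == "A", "C", "A")
    }
    m <- window_substitution_filter(a, c("target", "sister"))
    expect_equal(removed_set(m), window_brute(a, c("target", "sister"), 1:50))
  }
})

test_that("gaps and Ns never count as substitutions in windows", {
  a <- make_codon_fixture(n_codons = 20, seed = 4)
  a$bases[2, 1:12] <- "-"   # gap run
  a$bases[1, 13:18] <- "N"  # ambiguous
  m <- window_substitution_filter(a, c("target", "sister"))
  expect_equal(removed_set(m), integer(0))
})

test_that("flank removal dilates by seven codons in one pass", {
  m <- filter_mask(40)
  expect_equal(removed_set(flank_removal(m)), integer(0))
  m <- nimtools:::mask_remove(filter_mask(40), 20L, "gap")
  f <- flank_removal(m)
  expect_equal(removed_set(f), 13:27)
  expect_equal(sum(f$rule == "flank", na.rm = TRUE), 14L)
  # clipped at the ends
  m2 <- nimtools:::mask_remove(filter_mask(40), c(2L, 39L), "gap")
  expect_equal(removed_set(flank_removal(m2)), c(1:9, 32:40))
  # flanks do not cascade: a long run is dilated once, not iterated
  set.seed(50)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    rem <- sort(sample(n, sample(1:6, 1)))
    m3 <- nimtools:::mask_remove(filter_mask(n), rem, "window")
    got <- removed_set(flank_removal(m3))
    expect_equal(setdiff(got, rem), flank_brute(rem, n))
  }
})

test_that("discard boundaries follow the 100-codon and 10% rules", {
  a <- make_codon_fixture(n_codons = 200, seed = 5)
  keep_some <- function(n_keep, predicted) {
    aa <- make_codon_fixture(n_codons = 200,
                             predicted_codon_count = predicted, seed = 5)
    m <- filter_mask(200)
    m <- nimtools:::mask_remove(m, seq_len(200 - n_keep), "gap")
    discard_gene(aa, m)
  }
  d99 <- keep_some(99, 200)
  expect_false(d99$keep)
  expect_equal(d99$reason, "length")
  d150 <- keep_some(150, 2000) # 7.5% of predicted
  expect_false(d150$keep)
  expect_equal(d150$reason, "fraction")
  d100 <- keep_some(100, 500) # exactly 100 codons and 20%
  expect_true(d100$keep)
  expect_true(is.na(d100$reason))
})

test_that("the cascade composes the individual rules and shrinks monotonically", {
  a <- make_codon_fixture(n_codons = 400, n_low_quality = 6, n_gap_codons = 5,
                          n_bursts = 1, burst_subs = 7, seed = 12)
  res <- run_filter_cascade(a, c("target", "sister"))
  # compose the rules independently in cascade order
  m <- remove_gap_columns(a)
  m <- mask_low_quality_codons(a, m)
  m <- window_substitution_filter(a, c("target", "sister"), m)
  m <- flank_removal(m)
  expect_equal(removed_set(res$mask), removed_set(m))
  expect_identical(res$mask$rule, m$rule)
  # monotone shrinkage along the ledger
  expect_true(all(diff(res$report$remaining) <= 0))
  expect_equal(res$remaining, 400L - length(removed_set(res$mask)))
})

test_that("quality and gap rules commute", {
  a <- make_codon_fixture(n_codons = 120, n_low_quality = 8, n_gap_codons = 6,
                          seed = 13)
  m1 <- mask_low_quality_codons(a, remove_gap_columns(a))
  m2 <- remove_gap_columns(a, mask_low_quality_codons(a))
  expect_equal(removed_set(m1), removed_set(m2))
})

test_that("replaying the ledger reproduces the mask and the alignment", {
  a <- make_codon_fixture(n_codons = 300, n_low_quality = 5, n_gap_codons = 4,
                          n_bursts = 1, seed = 14)
  res <- run_filter_cascade(a, c("target", "sister"))
  replayed <- replay_ledger(res$mask, a$n_codons)
  expect_identical(replayed$removed, res$mask$removed)
  expect_identical(replayed$rule, res$mask$rule)
  expect_identical(apply_mask(a, replayed)$bases, res$alignment$bases)
})

test_that("a clean alignment passes through untouched and is kept", {
  a <- make_codon_fixture(n_codons = 150, seed = 15)
  res <- run_filter_cascade(a, c("target", "sister"))
  expect_true(res$keep)
  expect_equal(res$remaining, 150L)
  expect_identical(res$alignment$bases, a$bases)
})

test_that("external masks are honoured ahead of every internal rule", {
  a <- make_codon_fixture(n_codons = 150, seed = 16)
  res <- run_filter_cascade(a, c("target", "sister"),
                            external_mask = c(50L, 51L))
  expect_true(all(c(50L, 51L) %in% removed_set(res$mask)))
  expect_equal(res$mask$rule[res$mask$codon == 50L], "external")
  # their flanks are removed too
  expect_true(all(43:58 %in% removed_set(res$mask)))
  expect_error(run_filter_cascade(a, external_mask = 999L), "out of range")
})
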