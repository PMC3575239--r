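test_that("coverage-based genome size behaves as a simple quotient", {
  expect_equal(genome_size_from_coverage(7.529e9, 6.0), 7.529e9 / 6.0)
  expect_equal(signif(genome_size_from_coverage(7.529e9, 6.0) / 1e9, 3), 1.25)
  expect_equal(genome_size_from_coverage(123, 1.0), 123)
  expect_error(genome_size_from_coverage(1e9, 0),
               class = "nimtools_domain_error")
  expect_error(genome_size_from_coverage(1e9, -2),
               class = "nimtools_domain_error")
})

test_that("modal coverage recovers a known simulated depth", {
  set.seed(5)
  # symmetric per-base depth around a known 8x over a 1 Mb fixture (an
  # integer-mean Poisson ties its mode between 7 and 8, so a rounded
  # normal emulates the unimodal peak of real coverage tracks)
  cov <- pmax(1L, as.integer(round(rnorm(1e6, 8, 1.5))))
  m <- modal_coverage(cov)
  expect_equal(m, 8L)
  size <- genome_size_from_coverage(sum(as.numeric(cov)), m)
  expect_lt(abs(size - 1e6) / 1e6, 0.02)
})

test_that("euchromatic completeness follows outgroup triangulation", {
  expect_equal(round(100 * euchromatic_completeness(991e6, 122e6)), 89)
  expect_equal(euchromatic_completeness(5e8, 0), 1.0)
  # target assembly missing 10% of outgroup-shared sequence
  shared <- 2e6
  missing <- 0.10 * shared
  expect_equal(euchromatic_completeness(shared - missing, missing), 0.90)
})

test_that("aligned fractions and gene-set completeness round to percents", {
  expect_identical(aligned_fraction(569e6, 991e6), 57L)
  expect_identical(aligned_fraction(823e6, 991e6), 83L)
  expect_identical(aligned_fraction(0, 5e8), 0L)
  expect_identical(geneset_completeness(7416, 10222), 73L)
  expect_identical(geneset_completeness(500, 500), 100L)
  expect_identical(geneset_completeness(0, 10), 0L)
})

test_that("splice audits reproduce planted truth exactly", {
  f0 <- make_spliced_gene_fixture(n_genes = 10, introns_per_gene = 5,
                                  n_splice_errors = 0, seed = 1)
  a0 <- splice_site_substitution_rate(f0$models, c(chr1 = f0$genomes[["reference"]]),
                                      f0$pair_blocks)
  expect_equal(a0$n_sites_nt, 200L)
  expect_equal(a0$n_changed, 0L)
  expect_equal(a0$rate, 0)

  f3 <- make_spliced_gene_fixture(n_genes = 10, introns_per_gene = 5,
                                  n_splice_errors = 3, seed = 2)
  a3 <- splice_site_substitution_rate(f3$models, c(chr1 = f3$genomes[["reference"]]),
                                      f3$pair_blocks)
  expect_equal(a3$n_sites_nt, 200L)
  expect_equal(a3$n_changed, 3L)
  expect_equal(a3$rate, 3 / 200)
})

test_that("the audit works through GFF3 and FASTA files on disk", {
  f <- make_spliced_gene_fixture(n_genes = 4, introns_per_gene = 3,
                                 n_splice_errors = 2, seed = 6)
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_gff3(f$models, gff)
  write_fasta(c(chr1 = f$genomes[["reference"]]), fa)
  a <- splice_site_substitution_rate(gff, fa, f$pair_blocks)
  expect_equal(a$n_sites_nt, 4L * 3L * 4L)
  expect_equal(a$n_changed, 2L)
})

test_that("non-canonical reference introns are skipped with a warning", {
  f <- make_spliced_gene_fixture(n_genes = 3, introns_per_gene = 2, seed = 3)
  ref <- f$genomes[["reference"]]
  models <- f$models
  ex <- models[models$type == "exon" & models$parent == "mRNA001", ]
  donor <- ex$end[1] + 1L # first intron's G of GT
  substr(ref, donor, donor) <- "C"
  expect_warning(
    a <- splice_site_substitution_rate(models, c(chr1 = ref), f$pair_blocks),
    "non-canonical"
  )
  expect_equal(a$n_sites_nt, 3L * 2L * 4L - 4L)
})

test_that("worked splice counts format as the published rate", {
  a <- splice_audit(515, 168849)
  expect_equal(a$percent, 0.31)
  expect_equal(a$rate, 515 / 168849)
})

test_that("three-way indel audit matches planted truth and brute force", {
  same <- tibble::tibble(outgroup = "ACGTACGT", target = "ACGTACGT",
                         sister = "ACGTACGT")
  expect_equal(indel_error_upper_bound(same)$per_kb, 0)

  # 12 planted target-only indel events over exactly 6 kb of outgroup sequence
  f <- make_spliced_gene_fixture(n_genes = 4, introns_per_gene = 5,
                                 exon_length = 120, intron_length = 80,
                                 intergenic_length = 304,
                                 n_indel_errors = 12, seed = 8)
  expect_equal(f$truth$ref_length, 6000L)
  r <- indel_error_upper_bound(f$blocks3)
  expect_equal(r$events, 12L)
  expect_equal(r$aligned_kb, 6)
  expect_equal(r$per_kb, 2.0)

  set.seed(30)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    mk <- function() paste(sample(c("A", "C", "G", "T", "-"), n, TRUE,
                                  prob = c(0.22, 0.22, 0.22, 0.22, 0.12)),
                           collapse = "")
    b <- tibble::tibble(outgroup = mk(), target = mk(), sister = mk())
    got <- indel_error_upper_bound(b)
    want <- threeway_brute(b$outgroup, b$target, b$sister)
    expect_equal(got$events, want$events)
    expect_equal(got$aligned_kb, want$aligned_kb)
  }
})

test_that("indel audit is invariant to splitting a block at a quiet column", {
  f <- make_spliced_gene_fixture(n_genes = 2, introns_per_gene = 3,
                                 n_indel_errors = 4, seed = 9)
  whole <- indel_error_upper_bound(f$blocks3)
  txts <- f$blocks3
  # split at a column where all three rows are ungapped
  o <- strsplit(txts$outgroup, "")[[1]]
  t <- strsplit(txts$target, "")[[1]]
  s <- strsplit(txts$sister, "")[[1]]
  cut_at <- which(o != "-" & t != "-" & s != "-")[100]
  two <- tibble::tibble(
    outgroup = c(paste(o[1:cut_at], collapse = ""),
                 paste(o[-(1:cut_at)], collapse = "")),
    target = c(paste(t[1:cut_at], collapse = ""),
               paste(t[-(1:cut_at)], collapse = "")),
    sister = c(paste(s[1:cut_at], collapse = ""),
               paste(s[-(1:cut_at)], collapse = ""))
  )
  split2 <- indel_error_upper_bound(two)
  expect_equal(split2$events, whole$events)
  expect_equal(split2$per_kb, whole$per_kb)
})
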