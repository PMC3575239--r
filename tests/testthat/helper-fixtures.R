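# shared small fixtures built in code at test time

# random gapped two-row block with no gap-in-both columns
random_block <- function(n_cols, gap_prob = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  state <- sample(c("both", "ref_gap", "qry_gap"), n_cols, replace = TRUE,
                  prob = c(1 - gap_prob, gap_prob / 2, gap_prob / 2))
  r <- ifelse(state == "ref_gap", "-", sample(bases, n_cols, replace = TRUE))
  q <- ifelse(state == "qry_gap", "-", sample(bases, n_cols, replace = TRUE))
  ref_text <- paste(r, collapse = "")
  qry_text <- paste(q, collapse = "")
  tibble::tibble(
    ref_name = "chrR", ref_start = 0L, ref_size = sum(r != "-"),
    ref_strand = "+", ref_src_size = sum(r != "-"), ref_text = ref_text,
    qry_name = "chrQ", qry_start = 0L, qry_size = sum(q != "-"),
    qry_strand = "+", qry_src_size = sum(q != "-"), qry_text = qry_text
  )
}

# small linear-chain GO DAG: root <- A <- B
chain_dag <- function() {
  nimtools::go_dag(
    c("root", "A", "B"),
    tibble::tibble(child = c("A", "B"), parent = c("root", "A"),
                   relation = "is_a")
  )
}

# a cached 1 Mb neutral simulation shared across tests in one run
neutral_sim_1mb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- nimtools::sim_params(genome_length = 1.2e6, indel_rate = 0.005,
                                substitution_rate = 0,
                                constrained_fraction = 0, seed = 42)
      cache <<- nimtools::simulate_alignment(p)
    }
    cache
  }
})
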