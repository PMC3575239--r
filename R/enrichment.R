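#' Gene Ontology DAG container
#'
#' A set of term ids with `is_a` (and optionally `part_of`) parent edges.
#' The graph must be acyclic and is validated on construction.
#'
#' @param terms Character vector of term ids.
#' @param edges Tibble `(child, parent, relation)`.
#' @return A `go_dag` object.
#' @export
go_dag <- function(terms, edges) {
  stopifnot(all(c("child", "parent") %in% names(edges)))
  if (!"relation" %in% names(edges)) edges$relation <- "is_a"
  terms <- unique(c(terms, edges$child, edges$parent))
  # Kahn's algorithm on child->parent edges: peel terms no edge points to
  remaining_nodes <- terms
  remaining_edges <- edges
  repeat {
    leaves <- setdiff(remaining_nodes, remaining_edges$parent)
    if (!length(leaves)) break
    remaining_nodes <- setdiff(remaining_nodes, leaves)
    remaining_edges <- remaining_edges[!(remaining_edges$child %in% leaves), ]
  }
  if (length(remaining_nodes)) {
    abort("GO graph contains a cycle", class = "nimtools_dag_error")
  }
  structure(list(terms = terms, edges = as_tibble(edges)), class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d edges\n", length(x$terms), nrow(x$edges)))
  invisible(x)
}

#' Parse a (minimal) OBO ontology file
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `is_a` and
#' `relationship: part_of` lines. Obsolete terms are dropped.
#'
#' @param path Path to an OBO file.
#' @return A [go_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) abort("no [Term] stanzas found")
  bounds <- c(term_starts, length(lines) + 1L)
  terms <- character(0)
  edges <- list()
  for (i in seq_along(term_starts)) {
    chunk <- lines[seq.int(term_starts[i] + 1L, bounds[i + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    get1 <- function(key) {
      v <- chunk[startsWith(chunk, paste0(key, ":"))]
      if (length(v)) trimws(sub(paste0("^", key, ":"), "", v)) else character(0)
    }
    id <- get1("id")[1]
    if (is.na(id) || !length(id)) next
    if (any(grepl("^is_obsolete: *true", chunk))) next
    terms <- c(terms, id)
    isa <- sub(" *!.*$", "", get1("is_a"))
    for (p in isa) {
      edges[[length(edges) + 1L]] <- tibble(child = id, parent = trimws(p),
                                            relation = "is_a")
    }
    rel <- get1("relationship")
    rel <- rel[startsWith(rel, "part_of")]
    for (p in rel) {
      pid <- trimws(sub(" *!.*$", "", sub("^part_of +", "", p)))
      edges[[length(edges) + 1L]] <- tibble(child = id, parent = pid,
                                            relation = "part_of")
    }
  }
  e <- if (length(edges)) bind_rows(edges) else
    tibble(child = character(), parent = character(), relation = character())
  go_dag(terms, e)
}

#' Write a `go_dag` as a minimal OBO file
#'
#' @param dag A [go_dag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (t in sort(dag$terms)) {
    out <- c(out, "[Term]", paste0("id: ", t))
    e <- dag$edges[dag$edges$child == t, ]
    for (i in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[i] == "is_a") paste0("is_a: ", e$parent[i])
               else paste0("relationship: part_of ", e$parent[i]))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

# ancestor sets per term over the chosen relations (memoised DFS)
dag_ancestors <- function(dag, relations = "is_a") {
  e <- dag$edges[dag$edges$relation %in% relations, ]
  parents <- split(e$parent, e$child)
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (exists(t, envir = memo, inherits = FALSE)) return(get(t, envir = memo))
    ps <- parents[[t]]
    out <- if (is.null(ps)) character(0) else
      unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    memo[[t]] <- out
    out
  }
  stats::setNames(lapply(dag$terms, anc), dag$terms)
}

#' Propagate gene annotations to all parental terms
#'
#' For each GO term assigned to a gene, all ancestral terms (transitive
#' closure over `is_a` edges; `part_of` optional) are also assigned. The
#' operation is idempotent.
#'
#' @param annotations Tibble `(gene, term)`.
#' @param dag A [go_dag()].
#' @param relations Edge types to traverse (default `"is_a"`).
#' @return Tibble `(gene, term)` with ancestors added, duplicates removed.
#' @export
propagate_annotations <- function(annotations, dag, relations = "is_a") {
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  anc <- dag_ancestors(dag, relations)
  extra <- map_dfr(seq_len(nrow(annotations)), function(i) {
    up <- anc[[annotations$term[i]]]
    if (is.null(up) || !length(up)) return(NULL)
    tibble(gene = annotations$gene[i], term = up)
  })
  bind_rows(annotations[, c("gene", "term")], extra) |>
    distinct(.data$gene, .data$term) |>
    arrange(.data$gene, .data$term)
}

#' Upper-tail hypergeometric probability for site enrichment
#'
#' Probability of observing `k` or more positively selected sites among the
#' `n` sites of a term's genes, when `K` of the `N` sites in the universe
#' are positively selected and site labels are exchangeable across genes.
#'
#' @param k Positively selected sites in the term's genes.
#' @param n Total sites in the term's genes.
#' @param K Positively selected sites in the universe.
#' @param N Total sites in the universe.
#' @return Upper-tail probability `P(X >= k)`.
#' @export
site_hypergeometric <- function(k, n, K, N) {
  stopifnot(N >= 1, K >= 0, K <= N, n >= 0, n <= N, k >= 0)
  if (k > min(n, K)) {
    abort("k exceeds min(n, K): inconsistent site counts",
          class = "nimtools_consistency_error")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Site-level GO enrichment with Bonferroni correction
#'
#' Annotations are propagated to parental terms, then every term annotated
#' to at least one site is tested with the upper-tail hypergeometric
#' probability that at least its observed number of positively selected
#' sites would fall in its genes were the positively selected sites
#' distributed randomly across all sites of all tested genes. Raw p-values
#' are Bonferroni-multiplied by the number of tests and the table is sorted
#' by adjusted then raw p.
#'
#' @param sites Tibble `(gene, n_sites, ps_sites)`: filtered codon sites and
#'   positively selected sites per gene.
#' @param annotations Tibble `(gene, term)`.
#' @param dag Optional [go_dag()] for propagation (`NULL` = already
#'   propagated).
#' @param relations Edge types to traverse when propagating.
#' @param bonferroni_universe `"annotated"` (default) counts only tested
#'   terms in the correction; `"all"` counts every term of the DAG.
#' @return An `enrichment_result` tibble: `term`, `n_term_sites`,
#'   `k_term_ps`, `N_total_sites`, `K_total_ps`, `p_raw`, `p_bonferroni`.
#' @export
enrich <- function(sites, annotations, dag = NULL, relations = "is_a",
                   bonferroni_universe = c("annotated", "all")) {
  bonferroni_universe <- match.arg(bonferroni_universe)
  stopifnot(all(c("gene", "n_sites", "ps_sites") %in% names(sites)),
            all(sites$ps_sites <= sites$n_sites))
  ann <- if (is.null(dag)) annotations else
    propagate_annotations(annotations, dag, relations)
  N <- sum(sites$n_sites)
  K <- sum(sites$ps_sites)
  stopifnot(N >= 1)
  per_term <- ann |>
    inner_join(sites, by = "gene") |>
    group_by(term = .data$term) |>
    summarise(n_term_sites = sum(.data$n_sites),
              k_term_ps = sum(.data$ps_sites), .groups = "drop") |>
    filter(.data$n_term_sites > 0)
  m <- if (bonferroni_universe == "all" && !is.null(dag)) {
    length(dag$terms)
  } else {
    nrow(per_term)
  }
  res <- per_term |>
    mutate(
      N_total_sites = N, K_total_ps = K,
      p_raw = purrr::map2_dbl(.data$k_term_ps, .data$n_term_sites,
                              ~site_hypergeometric(.x, .y, K, N)),
      p_bonferroni = pmin(1, m * .data$p_raw)
    ) |>
    arrange(.data$p_bonferroni, .data$p_raw, .data$term)
  structure(res, n_tests = m,
            class = c("enrichment_result", class(res)))
}

#' @rdname tidiers
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_terms_tested = attr(x, "n_tests"),
         n_significant = sum(x$p_bonferroni < 0.05),
         top_term = if (nrow(x)) x$term[1] else NA_character_,
         top_p_bonferroni = if (nrow(x)) x$p_bonferroni[1] else NA_real_)
}

#' Enrichment result plot
#'
#' Horizontal bars of `-log10` Bonferroni-adjusted p for the top terms.
#'
#' @param object An `enrichment_result`.
#' @param top Number of terms to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top = 15, ...) {
  d <- utils::head(as_tibble(object), top)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_bonferroni),
                                  y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ p[Bonferroni]), y = NULL,
                  title = "Site-level GO enrichment")
}

#' Generate a small GO fixture: DAG, annotations, and site table
#'
#' Builds a layered random DAG (every non-root term has at least one `is_a`
#' parent in the layer above), annotates each gene with random leaf-ish
#' terms, and distributes positively selected sites either uniformly at
#' random across all sites (`enriched_term = NULL`, the null fixture) or
#' concentrated in the genes of one term.
#'
#' @param n_genes Number of genes.
#' @param n_layers DAG depth (root layer excluded).
#' @param terms_per_layer Terms per layer.
#' @param annotations_per_gene Direct annotations per gene.
#' @param sites_per_gene Filtered sites per gene.
#' @param n_ps_sites Total positively selected sites.
#' @param enriched_term Term id whose genes receive all PS sites, or `NULL`.
#' @param seed Integer seed.
#' @return List: `dag`, `annotations`, `sites`, `enriched_term`.
#' @export
make_go_fixture <- function(n_genes = 30, n_layers = 3, terms_per_layer = 5,
                            annotations_per_gene = 2, sites_per_gene = 50,
                            n_ps_sites = 20, enriched_term = NULL,
                            seed = 1L) {
  set.seed(seed)
  root <- "GO:ROOT"
  layers <- lapply(seq_len(n_layers), function(d) {
    sprintf("GO:L%dT%02d", d, seq_len(terms_per_layer))
  })
  edges <- list()
  for (d in seq_len(n_layers)) {
    parents_above <- if (d == 1L) root else layers[[d - 1L]]
    for (t in layers[[d]]) {
      np <- sample.int(min(2L, length(parents_above)), 1L)
      ps <- sample(parents_above, np)
      for (p in ps) {
        edges[[length(edges) + 1L]] <- tibble(child = t, parent = p,
                                              relation = "is_a")
      }
    }
  }
  dag <- go_dag(c(root, unlist(layers)), bind_rows(edges))
  genes <- sprintf("gene%03d", seq_len(n_genes))
  leafish <- layers[[n_layers]]
  annotations <- map_dfr(genes, function(g) {
    tibble(gene = g,
           term = sample(leafish, min(annotations_per_gene, length(leafish))))
  })
  sites <- tibble(gene = genes, n_sites = sites_per_gene, ps_sites = 0L)
  if (!is.null(enriched_term)) {
    target_genes <- unique(annotations$gene[annotations$term == enriched_term])
    if (!length(target_genes)) {
      abort("enriched_term has no annotated genes in this fixture")
    }
    pool <- rep(target_genes, times = sites_per_gene)
  } else {
    pool <- rep(genes, times = sites_per_gene)
  }
  hit <- sample(pool, n_ps_sites)
  tab <- table(hit)
  idx <- match(names(tab), sites$gene)
  sites$ps_sites[idx] <- as.integer(tab)
  list(dag = dag, annotations = annotations, sites = sites,
       enriched_term = enriched_term)
}
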