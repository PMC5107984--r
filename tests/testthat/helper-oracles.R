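# Independent brute-force oracles used across tests. These deliberately share
# no code with the package: direct predicate evaluation over a raw edge list.

options(pmapr.verbose = FALSE)

bf_neighbors <- function(edges, v) {
  unique(c(edges$gene_b[edges$gene_a == v], edges$gene_a[edges$gene_b == v]))
}

bf_nodes <- function(edges) unique(c(edges$gene_a, edges$gene_b))

# N1 predicate: non-PDEG node with >= min_links PDEG neighbors
bf_discover_n1 <- function(edges, pdegs, min_links = 2L) {
  nodes <- setdiff(bf_nodes(edges), pdegs)
  sort(Filter(function(v) {
    length(intersect(bf_neighbors(edges, v), pdegs)) >= min_links
  }, nodes))
}

# registry: every (pdeg, n1) adjacency pair
bf_registry <- function(edges, pdegs, n1) {
  rows <- list()
  for (g in n1) {
    for (p in intersect(bf_neighbors(edges, g), pdegs)) {
      rows[[length(rows) + 1L]] <- data.frame(pdeg = p, n1_gene = g,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(pdeg = character(), n1_gene = character()))
  out <- do.call(rbind, rows)
  out[order(out$n1_gene, out$pdeg), , drop = FALSE]
}

# N2 predicate: not PDEG/N1/excluded, >= 1 N1 neighbor and >= min_links PDEG
# neighbors
bf_discover_n2 <- function(edges, pdegs, n1, min_links = 2L, excluded = "UBC") {
  nodes <- setdiff(bf_nodes(edges), c(pdegs, n1, excluded))
  sort(Filter(function(v) {
    nb <- bf_neighbors(edges, v)
    length(intersect(nb, n1)) >= 1L &&
      length(intersect(nb, pdegs)) >= min_links
  }, nodes))
}

# Erdos-Renyi random edge list over lettered nodes
random_edges <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2L))
  keep <- runif(nrow(pairs)) < p_edge
  data.frame(gene_a = pairs[keep, 1L], gene_b = pairs[keep, 2L],
             stringsAsFactors = FALSE)
}

# independent 4PL evaluator
oracle_4pl <- function(d, lower, upper, ec50, hill) {
  lower + (upper - lower) / (1 + (d / ec50)^hill)
}

extdata <- function(...) system.file("extdata", ..., package = "pmapr")

small_synth_config <- function(seed = 1L, ...) {
  synth_config(n_genes = 200L, n_samples_per_condition = 40L,
               n_planted_pdegs_per_class = 10L, ppi_n_nodes = 280L,
               n_planted_n1 = 3L, k = 10L, seed = seed, ...)
}
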