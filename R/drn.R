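#' Build a PPI graph from a cleaned edge list
#'
#' Plain adjacency-list representation of an undirected simple graph; input
#' edges are re-cleaned (self-loops/duplicates dropped) so construction is
#' idempotent.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @return object of class `pmap_ppi`: list with `nodes`, `adj` (named list
#'   of lexicographically sorted neighbor vectors) and `n_edges`.
#' @export
ppi_graph <- function(edges) {
  edges <- clean_ppi_edges(edges)
  nodes <- sort_c(unique(c(edges$gene_a, edges$gene_b)))
  adj <- split(c(edges$gene_b, edges$gene_a), c(edges$gene_a, edges$gene_b))
  adj <- lapply(adj, sort_c)
  # isolated nodes cannot occur from an edge list, but keep the contract tight
  structure(list(nodes = nodes, adj = adj, n_edges = nrow(edges),
                 edges = edges),
            class = "pmap_ppi")
}

#' @export
print.pmap_ppi <- function(x, ...) {
  cat(sprintf("<pmap_ppi> %d nodes, %d edges\n", length(x$nodes), x$n_edges))
  invisible(x)
}

neighbors_of <- function(graph, v) graph$adj[[v]] %||% character(0)

#' Discover first-tier (N1) PDEG-interacting genes
#'
#' N1 genes are non-PDEG nodes directly adjacent to at least `min_links`
#' PDEGs of the phenotype class. The pair registry lists every
#' (PDEG, N1 gene) adjacency; its length M is the row dimension of the M x F
#' frequency matrix and the basis of N1 occurrence frequencies.
#'
#' @param graph `pmap_ppi` object.
#' @param pdegs character vector of PDEG symbols (unmapped symbols are
#'   logged and ignored).
#' @param min_links minimum number of PDEG neighbors (default 2).
#' @return list with `n1` (sorted symbols), `pair_registry` (data.frame
#'   `pdeg`, `n1_gene`, sorted), and `freq` (named integer vector; per-N1
#'   count of registry rows).
#' @export
discover_n1 <- function(graph, pdegs, min_links = 2L) {
  if (min_links < 1L) pmap_config_error("min_links must be >= 1")
  if (!length(graph$nodes)) pmap_config_error("empty PPI graph")
  pdegs <- unique(pdegs)
  unmapped <- setdiff(pdegs, graph$nodes)
  if (length(unmapped))
    pmap_log("discover_n1: %d PDEGs not present in PPI graph", length(unmapped))
  pdeg_in <- intersect(pdegs, graph$nodes)
  pset <- as.environment(stats::setNames(as.list(rep(TRUE, length(pdeg_in))),
                                         pdeg_in))
  # candidates: union of neighbors of PDEGs, excluding PDEGs themselves
  cand <- setdiff(unique(unlist(graph$adj[pdeg_in], use.names = FALSE)), pdeg_in)
  n1 <- character(0)
  reg_p <- character(0)
  reg_g <- character(0)
  for (g in cand) {
    nb <- neighbors_of(graph, g)
    hits <- nb[vapply(nb, function(v) !is.null(pset[[v]]), logical(1))]
    if (length(hits) >= min_links) {
      n1 <- c(n1, g)
      reg_p <- c(reg_p, hits)
      reg_g <- c(reg_g, rep(g, length(hits)))
    }
  }
  n1 <- sort_c(n1)
  o <- order(reg_g, reg_p, method = "radix")
  registry <- data.frame(pdeg = reg_p[o], n1_gene = reg_g[o],
                         stringsAsFactors = FALSE)
  freq <- table(registry$n1_gene)
  freq <- stats::setNames(as.integer(freq), names(freq))[n1]
  list(n1 = n1, pair_registry = registry,
       freq = stats::setNames(as.integer(freq), n1))
}

#' Discover second-tier (N2) PDEG-interacting genes
#'
#' N2 genes are nodes outside PDEGs, N1 and the exclusion list that are
#' adjacent to at least one N1 gene and to at least `min_links` PDEGs.
#' Ubiquitin C (UBC) is excluded by default: as an extreme hub it would
#' otherwise join every N2 list. The N2-role frequency of a gene g counts
#' registry rows (p, n) such that g is adjacent to both p and n, tying N2
#' occurrences to the same M pair rows as N1 (the F = 2 columns are
#' commensurable); `freq_mode = "pdeg_neighbors"` instead counts g's PDEG
#' neighbors.
#'
#' @param graph `pmap_ppi` object.
#' @param pdegs PDEG symbols.
#' @param n1_result result of [discover_n1()] on the same graph/PDEGs.
#' @param min_links minimum PDEG adjacency (default 2).
#' @param excluded symbols barred from N2 (default `"UBC"`).
#' @param freq_mode `"registry"` (default) or `"pdeg_neighbors"`.
#' @return list with `n2` (sorted) and `freq` (named integer).
#' @export
discover_n2 <- function(graph, pdegs, n1_result, min_links = 2L,
                        excluded = "UBC",
                        freq_mode = c("registry", "pdeg_neighbors")) {
  freq_mode <- match.arg(freq_mode)
  pdeg_in <- intersect(unique(pdegs), graph$nodes)
  n1 <- n1_result$n1
  barred <- unique(c(pdeg_in, n1, excluded))
  cand <- setdiff(unique(unlist(graph$adj[n1], use.names = FALSE)), barred)
  if (length(intersect(excluded, unique(unlist(graph$adj[n1], use.names = FALSE)))))
    pmap_log("discover_n2: excluded gene(s) %s met adjacency conditions or were candidates",
             paste(intersect(excluded, unlist(graph$adj[n1], use.names = FALSE)),
                   collapse = ","))
  n2 <- character(0)
  for (g in cand) {
    nb <- neighbors_of(graph, g)
    if (length(intersect(nb, pdeg_in)) >= min_links &&
        length(intersect(nb, n1)) >= 1L) {
      n2 <- c(n2, g)
    }
  }
  n2 <- sort_c(n2)
  reg <- n1_result$pair_registry
  freq <- if (freq_mode == "registry") {
    vapply(n2, function(g) {
      nb <- neighbors_of(graph, g)
      sum(reg$pdeg %in% nb & reg$n1_gene %in% nb)
    }, integer(1))
  } else {
    vapply(n2, function(g) length(intersect(neighbors_of(graph, g), pdeg_in)),
           integer(1))
  }
  list(n2 = n2, freq = stats::setNames(as.integer(freq), n2))
}

#' Assemble a drug response network (DRN)
#'
#' Induced subgraph over PDEGs, N1 and N2 genes, with endpoint roles
#' annotated and a per-node degree table. The degree summary is emitted so
#' users can audit hub-driven calls: high-degree nodes are enriched among
#' N1/N2 and are known false-positive risks.
#'
#' @param graph `pmap_ppi` object.
#' @param pdegs PDEG symbols.
#' @param n1,n2 character vectors from [discover_n1()]/[discover_n2()].
#' @return list with `edges` (data.frame `gene_a`, `gene_b`, `role_a`,
#'   `role_b`) and `degrees` (data.frame `gene`, `role`, `degree`, degree
#'   within the DRN).
#' @export
assemble_drn <- function(graph, pdegs, n1, n2) {
  pdeg_in <- intersect(unique(pdegs), graph$nodes)
  members <- c(stats::setNames(rep("PDEG", length(pdeg_in)), pdeg_in),
               stats::setNames(rep("N1", length(n1)), n1),
               stats::setNames(rep("N2", length(n2)), n2))
  if (!length(members)) {
    return(list(edges = data.frame(gene_a = character(), gene_b = character(),
                                   role_a = character(), role_b = character(),
                                   stringsAsFactors = FALSE),
                degrees = data.frame(gene = character(), role = character(),
                                     degree = integer(),
                                     stringsAsFactors = FALSE)))
  }
  e <- graph$edges
  keep <- e$gene_a %in% names(members) & e$gene_b %in% names(members)
  e <- e[keep, , drop = FALSE]
  e$role_a <- unname(members[e$gene_a])
  e$role_b <- unname(members[e$gene_b])
  rownames(e) <- NULL
  degs <- table(factor(c(e$gene_a, e$gene_b), levels = sort_c(names(members))))
  degrees <- data.frame(gene = names(degs),
                        role = unname(members[names(degs)]),
                        degree = as.integer(degs),
                        stringsAsFactors = FALSE)
  list(edges = e, degrees = degrees)
}

#' Build the full DRN result for one phenotype class
#'
#' Runs [discover_n1()], [discover_n2()] and [assemble_drn()] and records
#' role-separated occurrence frequencies.
#'
#' @param graph `pmap_ppi` object.
#' @param pdegs PDEG symbols for this phenotype class.
#' @param phenotype_class label, e.g. `"anthracycline-resistant"`.
#' @param min_links adjacency threshold (default 2).
#' @param excluded N2 exclusion list (default `"UBC"`).
#' @param freq_mode N2 frequency definition, see [discover_n2()].
#' @return object of class `pmap_drn`.
#' @export
build_drn <- function(graph, pdegs, phenotype_class, min_links = 2L,
                      excluded = "UBC", freq_mode = "registry") {
  r1 <- discover_n1(graph, pdegs, min_links = min_links)
  r2 <- discover_n2(graph, pdegs, r1, min_links = min_links,
                    excluded = excluded, freq_mode = freq_mode)
  asm <- assemble_drn(graph, pdegs, r1$n1, r2$n2)
  structure(list(phenotype_class = phenotype_class,
                 pdegs_in_graph = sort_c(intersect(unique(pdegs), graph$nodes)),
                 n1 = r1$n1, n2 = r2$n2,
                 pair_registry = r1$pair_registry,
                 freq_n1 = r1$freq, freq_n2 = r2$freq,
                 edges = asm$edges, degrees = asm$degrees),
            class = "pmap_drn")
}

#' @export
print.pmap_drn <- function(x, ...) {
  cat(sprintf("<pmap_drn> %s: %d PDEGs in graph, %d N1, %d N2, M = %d pairs, %d edges\n",
              x$phenotype_class, length(x$pdegs_in_graph), length(x$n1),
              length(x$n2), nrow(x$pair_registry), nrow(x$edges)))
  invisible(x)
}

#' Phenotypic frequency (PF) scores
#'
#' For each gene in the union of N1/N2 members of the sensitive and resistant
#' DRNs of one drug class:
#' `pf_n1 = freq_sensitive_N1 - freq_resistant_N1` (and analogously `pf_n2`),
#' with missing-role frequencies counted as 0, and `pf_sum = pf_n1 + pf_n2`.
#' A positive score means the gene occurs more often as a PDEG-interacting
#' gene in the sensitive network; under knockdown the sign predicts the
#' direction of drug-response change.
#'
#' @param sensitive,resistant `pmap_drn` objects for the same drug class.
#' @return data.frame `gene`, `freq_sensitive_n1`, `freq_resistant_n1`,
#'   `freq_sensitive_n2`, `freq_resistant_n2`, `pf_n1`, `pf_n2`, `pf_sum`,
#'   `rank`; sorted by `pf_sum` descending, ties by symbol.
#' @export
pf_scores <- function(sensitive, resistant) {
  cls_s <- sub("-(sensitive|resistant)$", "", sensitive$phenotype_class)
  cls_r <- sub("-(sensitive|resistant)$", "", resistant$phenotype_class)
  if (cls_s != cls_r)
    pmap_config_error("PF scores require DRNs of the same drug class (got %s vs %s)",
                      cls_s, cls_r)
  genes <- sort_c(unique(c(names(sensitive$freq_n1), names(sensitive$freq_n2),
                           names(resistant$freq_n1), names(resistant$freq_n2))))
  take <- function(freq, g) {
    v <- freq[g]
    v[is.na(v)] <- 0L
    as.integer(v)
  }
  fs1 <- take(sensitive$freq_n1, genes)
  fr1 <- take(resistant$freq_n1, genes)
  fs2 <- take(sensitive$freq_n2, genes)
  fr2 <- take(resistant$freq_n2, genes)
  out <- data.frame(gene = genes,
                    freq_sensitive_n1 = fs1, freq_resistant_n1 = fr1,
                    freq_sensitive_n2 = fs2, freq_resistant_n2 = fr2,
                    pf_n1 = fs1 - fr1, pf_n2 = fs2 - fr2,
                    stringsAsFactors = FALSE)
  out$pf_sum <- out$pf_n1 + out$pf_n2
  out <- out[order(-out$pf_sum, out$gene, method = "radix"), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
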