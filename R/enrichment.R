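#' Hypergeometric over-representation analysis (ORA)
#'
#' Exact upper-tail hypergeometric test of a query gene set against each
#' pathway, restricted to a gene universe, with Bonferroni correction over
#' the pathways actually tested (those with at least `min_genes` in-universe
#' members — excluded pathways do not inflate the correction count).
#'
#' @param query character vector of query genes; members outside the universe
#'   are logged and dropped.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of background genes.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param min_genes minimum in-universe pathway size to be tested (default 5).
#' @return data.frame `pathway`, `overlap`, `pathway_size`, `universe_size`,
#'   `draws`, `p_raw`, `p_adj`, `significant`, sorted by `p_raw`.
#' @export
ora <- function(query, sets, universe, alpha = 0.05, min_genes = 5L) {
  universe <- unique(universe)
  if (!length(universe)) pmap_data_error("empty gene universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    pmap_log("ora: %d query genes outside the universe were dropped",
             length(outside))
    query <- intersect(query, universe)
  }
  in_universe <- lapply(sets, intersect, universe)
  sizes <- lengths(in_universe)
  tested <- names(sets)[sizes >= min_genes]
  n_tested <- length(tested)
  if (!n_tested)
    return(data.frame(pathway = character(), overlap = integer(),
                      pathway_size = integer(), universe_size = integer(),
                      draws = integer(), p_raw = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  N <- length(universe)
  k <- length(query)
  rows <- lapply(tested, function(nm) {
    K <- sizes[[nm]]
    x <- length(intersect(in_universe[[nm]], query))
    p <- stats::phyper(x - 1L, K, N - K, k, lower.tail = FALSE)
    data.frame(pathway = nm, overlap = x, pathway_size = K,
               universe_size = N, draws = k, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * n_tested)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_raw, out$pathway, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score for hit positions
# `hits` (indices into the ranking) with scores `s` and weight exponent `p`.
# Returns the signed maximum deviation and its position.
gsea_es <- function(hits, s, p) {
  N <- length(s)
  k <- length(hits)
  w <- if (p == 0) rep(1, k) else abs(s[hits])^p
  tot <- sum(w)
  if (tot == 0) { # all-zero scores in the set: fall back to unweighted
    w <- rep(1, k)
    tot <- k
  }
  inc <- rep(-1 / (N - k), N)
  inc[hits] <- w / tot
  cs <- cumsum(inc)
  i <- which.max(abs(cs))
  list(es = cs[[i]], at = i)
}

#' Pre-ranked gene set enrichment analysis (GSEA)
#'
#' Classic weighted KS running-sum enrichment on a ranked gene list, with the
#' null built by randomly swapping gene labels (equivalently, permuting the
#' score vector over genes). The nominal p-value uses the +1 correction,
#' `np = (1 + #{|ES_perm| >= |ES_obs|}) / (n_perm + 1)`, and
#' `NES = ES / mean(|same-sign permuted ES|)`. When `exhaustive = TRUE` and
#' the weight exponent is 0, all `choose(N, k)` hit-position assignments are
#' enumerated instead of sampled, giving an exact permutation p.
#'
#' @param scores named numeric vector (gene -> ranking score, e.g. PF score).
#'   Ties are broken by gene symbol for determinism.
#' @param sets named list of character vectors; sets with zero overlap with
#'   the ranking are skipped with a log line.
#' @param n_perm number of label permutations (default 1000).
#' @param p weight exponent on |score| for hit increments (default 1;
#'   0 = unweighted classic KS).
#' @param seed RNG seed for the permutation null.
#' @param exhaustive enumerate all hit-position assignments (requires
#'   `p = 0` and small `choose(N, k)`).
#' @return data.frame `gene_set`, `size`, `es`, `nes`, `np`, `n_perm`,
#'   `leading_edge` (comma-collapsed gene symbols).
#' @export
gsea_preranked <- function(scores, sets, n_perm = 1000L, p = 1, seed = 1L,
                           exhaustive = FALSE) {
  if (any(!is.finite(scores))) pmap_data_error("non-finite ranking scores")
  o <- order(-scores, names(scores), method = "radix")
  s <- as.numeric(scores[o])
  genes <- names(scores)[o]
  N <- length(s)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], genes)
    k <- length(members)
    if (k == 0L) {
      pmap_log("gsea: set '%s' has no overlap with the ranking; skipped", nm)
      return(NULL)
    }
    if (k == N) { # hit and miss distributions coincide; ES is 0 by definition
      return(data.frame(gene_set = nm, size = k, es = 0, nes = 0, np = 1,
                        n_perm = 0L, leading_edge = "",
                        stringsAsFactors = FALSE))
    }
    hits <- which(genes %in% members)
    obs <- gsea_es(hits, s, p)
    if (exhaustive) {
      if (p != 0)
        pmap_config_error("exhaustive GSEA enumeration requires weight p = 0")
      combos <- utils::combn(N, k)
      es_null <- apply(combos, 2L, function(h) gsea_es(h, s, 0)$es)
      n_eff <- ncol(combos)
    } else {
      set.seed(as.integer(seed))
      es_null <- vapply(seq_len(n_perm), function(i) {
        gsea_es(sort.int(sample.int(N, k)), s, p)$es
      }, numeric(1))
      n_eff <- as.integer(n_perm)
    }
    np <- (1 + sum(abs(es_null) >= abs(obs$es))) / (n_eff + 1)
    same_sign <- es_null[sign(es_null) == sign(obs$es)]
    nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
    le <- if (obs$es >= 0) genes[hits[hits <= obs$at]] else
      genes[hits[hits > obs$at]]
    data.frame(gene_set = nm, size = k, es = obs$es, nes = nes, np = np,
               n_perm = n_eff, leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_set = character(), size = integer(), es = numeric(),
               nes = numeric(), np = numeric(), n_perm = integer(),
               leading_edge = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
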