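star_graph <- function() {
  ppi_graph(data.frame(gene_a = c("A", "B", "C"), gene_b = "h",
                       stringsAsFactors = FALSE))
}

test_that("star graph: hub adjacent to three PDEGs is N1 with freq 3", {
  g <- star_graph()
  r <- discover_n1(g, c("A", "B", "C"))
  expect_equal(r$n1, "h")
  expect_equal(unname(r$freq["h"]), 3L)
  expect_equal(nrow(r$pair_registry), 3L)
  expect_setequal(r$pair_registry$pdeg, c("A", "B", "C"))
  asm <- assemble_drn(g, c("A", "B", "C"), r$n1, character(0))
  expect_equal(nrow(asm$edges), 3L)
  expect_equal(asm$degrees$degree[asm$degrees$gene == "h"], 3L)
})

test_that("a gene adjacent to exactly one PDEG is not N1", {
  g <- ppi_graph(data.frame(gene_a = c("A", "x"), gene_b = c("x", "B2")))
  r <- discover_n1(g, "A")
  expect_length(r$n1, 0L)
})

test_that("N2 definition and the UBC exclusion", {
  # path PDEG_A - n1x - g, with g also adjacent to PDEG_A and PDEG_B;
  # and UBC satisfying the same conditions
  edges <- data.frame(
    gene_a = c("PDEG_A", "PDEG_B", "n1x", "g", "g", "UBC", "UBC", "UBC"),
    gene_b = c("n1x", "n1x", "g", "PDEG_A", "PDEG_B", "n1x", "PDEG_A", "PDEG_B"),
    stringsAsFactors = FALSE)
  g <- ppi_graph(edges)
  pdegs <- c("PDEG_A", "PDEG_B")
  r1 <- discover_n1(g, pdegs)
  expect_true(all(c("n1x", "g", "UBC") %in% r1$n1) ||
                all(c("n1x") %in% r1$n1))
  # force g and UBC out of N1 to exercise the N2 predicate directly
  r1_forced <- list(n1 = "n1x",
                    pair_registry = data.frame(pdeg = c("PDEG_A", "PDEG_B"),
                                               n1_gene = "n1x"))
  r2 <- discover_n2(g, pdegs, r1_forced)
  expect_true("g" %in% r2$n2)
  expect_false("UBC" %in% r2$n2)
  # registry-row frequency: g is adjacent to n1x and both registry PDEGs
  expect_equal(unname(r2$freq["g"]), 2L)
})

test_that("discover_n1/discover_n2 match exhaustive brute force on random graphs", {
  n_checked <- 0L
  for (seed in 1:50) {
    edges <- random_edges(sample(20:60, 1L), runif(1, 0.05, 0.2), seed = seed)
    if (!nrow(edges)) next
    g <- ppi_graph(edges)
    nodes <- g$nodes
    pdegs <- sample(nodes, min(8L, length(nodes) %/% 3L))
    r1 <- discover_n1(g, pdegs)
    expect_identical(r1$n1, bf_discover_n1(edges, pdegs))
    reg <- bf_registry(edges, pdegs, r1$n1)
    got <- r1$pair_registry[order(r1$pair_registry$n1_gene,
                                  r1$pair_registry$pdeg), ]
    expect_equal(got$pdeg, reg$pdeg)
    expect_equal(got$n1_gene, reg$n1_gene)
    r2 <- discover_n2(g, pdegs, r1)
    expect_identical(r2$n2, bf_discover_n2(edges, pdegs, r1$n1))
    # frequency conservation: sum of N1 frequencies equals M
    expect_equal(sum(r1$freq), nrow(r1$pair_registry))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 45L)
})

test_that("min_links is honored and validated", {
  g <- star_graph()
  expect_length(discover_n1(g, c("A", "B", "C"), min_links = 4L)$n1, 0L)
  expect_error(discover_n1(g, "A", min_links = 0L), "min_links")
})

test_that("adding a PDEG edge never decreases an N1 gene's frequency", {
  for (seed in 1:10) {
    edges <- random_edges(30L, 0.1, seed = seed + 100L)
    g <- ppi_graph(edges)
    pdegs <- sample(g$nodes, 6L)
    r1 <- discover_n1(g, pdegs)
    if (!length(r1$n1)) next
    gene <- r1$n1[[1L]]
    new_pdeg <- "freshPDEG"
    g2 <- ppi_graph(rbind(edges, data.frame(gene_a = gene, gene_b = new_pdeg)))
    r1b <- discover_n1(g2, c(pdegs, new_pdeg))
    expect_gte(r1b$freq[[gene]], r1$freq[[gene]])
  }
})

test_that("PF scores are antisymmetric and missing roles count as zero", {
  cfg <- small_synth_config(seed = 31L)
  b <- synth_bundle(cfg)
  g <- ppi_graph(b$ppi_edges)
  cls <- "anthracycline"
  s <- build_drn(g, b$truth$planted_pdegs[[paste0(cls, "-sensitive")]],
                 paste0(cls, "-sensitive"))
  r <- build_drn(g, b$truth$planted_pdegs[[paste0(cls, "-resistant")]],
                 paste0(cls, "-resistant"))
  pf <- pf_scores(s, r)
  pf_rev <- pf_scores(r, s)
  m <- merge(pf, pf_rev, by = "gene")
  expect_equal(m$pf_n1.x, -m$pf_n1.y)
  expect_equal(m$pf_n2.x, -m$pf_n2.y)
  expect_equal(m$pf_sum.x, -m$pf_sum.y)
  expect_equal(pf$pf_sum, pf$pf_n1 + pf$pf_n2)
  # a gene with equal frequencies on both sides scores zero
  same <- pf_scores(s, s)
  expect_true(all(same$pf_sum == 0L))
})

test_that("mismatched drug classes are rejected by pf_scores", {
  g <- star_graph()
  a <- build_drn(g, c("A", "B"), "anthracycline-sensitive")
  t <- build_drn(g, c("A", "B"), "taxane-resistant")
  expect_error(pf_scores(a, t), "same drug class")
})

test_that("empty PDEG set yields an empty DRN", {
  g <- star_graph()
  drn <- build_drn(g, character(0), "x-sensitive")
  expect_length(drn$n1, 0L)
  expect_length(drn$n2, 0L)
  expect_equal(nrow(drn$edges), 0L)
})
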