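test_that("identical config and seed give bit-identical outputs", {
  cfg <- small_synth_config(seed = 5L)
  b1 <- synth_bundle(cfg)
  b2 <- synth_bundle(cfg)
  expect_identical(b1$expr, b2$expr)
  expect_identical(b1$ec50, b2$ec50)
  expect_identical(b1$ppi_edges, b2$ppi_edges)
  expect_identical(b1$truth, b2$truth)
  b3 <- synth_bundle(small_synth_config(seed = 6L))
  expect_false(identical(b1$expr, b3$expr))
})

test_that("config invariants are validated", {
  expect_error(synth_config(n_genes = 0L), "positive")
  expect_error(synth_config(planted_n1_min_pdeg_links = 1L), ">= 2")
  expect_error(synth_config(n_planted_pdegs_per_class = 200L, n_genes = 300L),
               "too large")
  expect_error(synth_config(ppi_n_nodes = 601L), "ppi_n_nodes")
  expect_error(synth_config(n_planted_pdegs_per_class = 2L,
                            planted_n1_min_pdeg_links = 3L), "infeasible")
})

test_that("generated PPI is simple with planted N1 wiring satisfied", {
  cfg <- small_synth_config(seed = 7L)
  b <- synth_bundle(cfg)
  e <- b$ppi_edges
  expect_true(all(e$gene_a != e$gene_b))
  expect_equal(anyDuplicated(paste(e$gene_a, e$gene_b)), 0L)
  for (cls in names(b$truth$planted_n1)) {
    pdegs <- b$truth$planted_pdegs[[cls]]
    for (g in b$truth$planted_n1[[cls]]) {
      nb <- c(e$gene_b[e$gene_a == g], e$gene_a[e$gene_b == g])
      expect_gte(length(intersect(nb, pdegs)),
                 cfg$planted_n1_min_pdeg_links)
    }
  }
  # heavy tail: max degree far above the median (preferential attachment)
  deg <- table(c(e$gene_a, e$gene_b))
  expect_gt(max(deg), 5 * median(deg))
})

test_that("planted N1 genes are disjoint from planted PDEGs and recovered by discover_n1", {
  cfg <- small_synth_config(seed = 8L)
  b <- synth_bundle(cfg)
  g <- ppi_graph(b$ppi_edges)
  for (cls in names(b$truth$planted_n1)) {
    expect_length(intersect(b$truth$planted_n1[[cls]],
                            b$truth$planted_pdegs[[cls]]), 0L)
    r1 <- discover_n1(g, b$truth$planted_pdegs[[cls]],
                      min_links = cfg$planted_n1_min_pdeg_links)
    expect_true(all(b$truth$planted_n1[[cls]] %in% r1$n1))
  }
})

test_that("planted PDEGs are elevated in their tails; null case has no signal", {
  cfg <- small_synth_config(seed = 9L)
  b <- synth_bundle(cfg)
  cls <- "anthracycline-resistant"
  gset <- b$truth$planted_pdegs[[cls]]
  drugs <- names(cfg$drugs)[cfg$drugs == "anthracycline"]
  tails <- unique(b$assignment$sample_id[b$assignment$drug %in% drugs &
                                           b$assignment$tail == "resistant"])
  rest <- setdiff(colnames(b$expr), tails)
  lift <- mean(b$expr[gset, tails]) - mean(b$expr[gset, rest])
  expect_gt(lift, cfg$pdeg_effect_size * 0.8)

  # effect 0: planted and null genes are exchangeable
  cfg0 <- small_synth_config(seed = 9L, pdeg_effect_size = 0)
  b0 <- synth_bundle(cfg0)
  g0 <- b0$truth$planted_pdegs[[cls]]
  lift0 <- mean(b0$expr[g0, tails]) - mean(b0$expr[g0, rest])
  expect_lt(abs(lift0), 0.1)
})

test_that("null calibration: with zero effect, PDEG calls match the nominal rate", {
  cfg0 <- small_synth_config(seed = 10L, pdeg_effect_size = 0)
  b0 <- synth_bundle(cfg0)
  alpha <- 1e-3
  tm <- template_match(b0$expr, b0$assignment, alpha = alpha)
  # per-condition false-positive fraction across all genes x conditions
  n_conditions <- length(unique(paste(b0$assignment$drug, b0$assignment$group)))
  n_tests <- nrow(b0$expr) * n_conditions
  rate <- nrow(tm) / n_tests
  # binomial 99.9% envelope around alpha
  expect_lt(rate, alpha + 3.3 * sqrt(alpha / n_tests))
})

test_that("dose-response generation follows the stated assay design", {
  cfg <- synth_config(n_samples_per_condition = 16L, groups = "Eur",
                      k = 8L, seed = 12L, ppi_n_nodes = 700L)
  dr <- synth_dose_response(cfg)
  one <- dr$dose_response[dr$dose_response$sample_id == dr$true_ec50$sample_id[[1L]] &
                            dr$dose_response$drug == dr$true_ec50$drug[[1L]], ]
  # 9 doses x 3 replicate wells = 27 rows per sample and drug
  expect_equal(nrow(one), 27L)
  expect_equal(length(unique(one$dose)), 9L)
  # anthracycline grid 0-2 uM, taxane grid 0-5000 nM
  anth <- dr$dose_response[dr$dose_response$drug == "doxorubicin", ]
  expect_equal(max(anth$dose), 2)
  tax <- dr$dose_response[dr$dose_response$drug == "paclitaxel", ]
  expect_equal(max(tax$dose), 5000)
})

test_that("noiseless generation recovers EC50 exactly through the fitter", {
  cfg <- synth_config(n_samples_per_condition = 4L, groups = "Eur",
                      drugs = c(doxorubicin = "anthracycline"),
                      k = 2L, dr_noise_sd = 0, seed = 13L, ppi_n_nodes = 700L)
  dr <- synth_dose_response(cfg)
  fits <- fit_ec50_table(dr$dose_response)
  m <- merge(fits, dr$true_ec50, by = c("sample_id", "drug", "group"))
  expect_equal(nrow(m), 4L)
  expect_true(all(abs(m$ec50.x / m$ec50.y - 1) < 1e-6))
})

test_that("synthetic screen is consistent with planted PF signs", {
  cfg <- small_synth_config(seed = 14L)
  b <- synth_bundle(cfg)
  screen <- synth_screen(b$truth)
  genes <- names(b$truth$planted_pf_sign)
  pf <- data.frame(gene = genes,
                   pf_sum = b$truth$planted_pf_sign * 50L)
  calls <- classify_screen(pf, screen)
  expect_true(all(calls$category == "moderate"))
})

test_that("bundle writes round-trip through the readers", {
  cfg <- small_synth_config(seed = 15L)
  b <- synth_bundle(cfg)
  d <- tempfile("synth")
  synth_write(b, d)
  expr <- read_expression(file.path(d, "expression.tsv"))
  expect_equal(dim(expr), dim(b$expr))
  expect_equal(unname(expr), unname(b$expr), tolerance = 1e-12)
  ppi <- read_ppi(file.path(d, "ppi.tsv"))
  expect_equal(nrow(ppi), nrow(b$ppi_edges))
  sets <- read_gmt(file.path(d, "sets.gmt"))
  expect_equal(lengths(sets), lengths(b$gene_sets))
  ec <- read_ec50(file.path(d, "ec50.tsv"))
  expect_equal(nrow(ec), nrow(b$ec50))
})
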