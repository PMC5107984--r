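#' Configuration for the synthetic data generator
#'
#' The defaults state the emulated world: four drugs in two classes
#' (anthracyclines: doxorubicin, epirubicin; taxanes: docetaxel, paclitaxel),
#' three population groups, 60 cell lines per group assayed against every
#' drug, EC50 tails of 15, planted two-state PDEGs with a 2.0 log2 effect
#' over 0.5-sd Gaussian noise, and a preferential-attachment PPI graph with
#' planted N1 wiring (each planted N1 gene linked to at least
#' `planted_n1_min_pdeg_links` planted PDEGs of its phenotype class).
#'
#' @param n_genes number of expression genes.
#' @param n_samples_per_condition cell lines per population group (shared
#'   across drugs, as one cell line is assayed against every drug).
#' @param drugs named character vector: drug name -> drug class.
#' @param groups population group labels.
#' @param n_planted_pdegs_per_class planted PDEGs per phenotype class
#'   (drug class x response).
#' @param pdeg_effect_size log2 elevation of planted PDEGs in their tails.
#' @param noise_sd log2-scale Gaussian noise standard deviation.
#' @param ppi_n_nodes PPI node count (must exceed `n_genes` by enough to
#'   host the planted N1 genes and the UBC hub).
#' @param ppi_attachment edges added per node in preferential attachment.
#' @param n_planted_n1 planted N1 genes per phenotype class.
#' @param planted_n1_min_pdeg_links minimum planted links per N1 gene (>= 2).
#' @param k phenotype tail size.
#' @param dr_noise_sd viability noise for dose-response generation.
#' @param seed integer RNG seed; identical config implies bit-identical
#'   outputs.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 600L,
                         n_samples_per_condition = 60L,
                         drugs = c(doxorubicin = "anthracycline",
                                   epirubicin = "anthracycline",
                                   docetaxel = "taxane",
                                   paclitaxel = "taxane"),
                         groups = c("African", "Caucasian", "Chinese"),
                         n_planted_pdegs_per_class = 20L,
                         pdeg_effect_size = 2.0,
                         noise_sd = 0.5,
                         ppi_n_nodes = 800L,
                         ppi_attachment = 2L,
                         n_planted_n1 = 5L,
                         planted_n1_min_pdeg_links = 3L,
                         k = 15L,
                         dr_noise_sd = 0.05,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_condition = as.integer(n_samples_per_condition),
              drugs = drugs, groups = groups,
              n_planted_pdegs_per_class = as.integer(n_planted_pdegs_per_class),
              pdeg_effect_size = pdeg_effect_size, noise_sd = noise_sd,
              ppi_n_nodes = as.integer(ppi_n_nodes),
              ppi_attachment = as.integer(ppi_attachment),
              n_planted_n1 = as.integer(n_planted_n1),
              planted_n1_min_pdeg_links = as.integer(planted_n1_min_pdeg_links),
              k = as.integer(k), dr_noise_sd = dr_noise_sd,
              seed = as.integer(seed))
  counts <- c(cfg$n_genes, cfg$n_samples_per_condition,
              cfg$n_planted_pdegs_per_class, cfg$ppi_n_nodes,
              cfg$ppi_attachment, cfg$n_planted_n1, cfg$k)
  if (any(counts <= 0L)) pmap_config_error("all synth counts must be positive")
  if (cfg$planted_n1_min_pdeg_links < 2L)
    pmap_config_error("planted_n1_min_pdeg_links must be >= 2")
  if (cfg$planted_n1_min_pdeg_links > cfg$n_planted_pdegs_per_class)
    pmap_config_error("planted N1 wiring infeasible: too few planted PDEGs per class")
  n_classes <- 2L * length(unique(unname(cfg$drugs)))
  if (n_classes * cfg$n_planted_pdegs_per_class >= cfg$n_genes)
    pmap_config_error("n_planted_pdegs_per_class too large for n_genes")
  n_extras <- n_classes * cfg$n_planted_n1 + 1L # planted N1 pool + UBC
  if (cfg$ppi_n_nodes < cfg$n_genes + n_extras)
    pmap_config_error("ppi_n_nodes must be >= n_genes + %d (planted N1 pool + UBC)",
                      n_extras)
  if (is.null(names(cfg$drugs)))
    pmap_config_error("drugs must be a named vector: name -> drug class")
  structure(cfg, class = "synth_config")
}

synth_gene_names <- function(config) {
  sprintf("G%04d", seq_len(config$n_genes))
}

synth_sample_ids <- function(config) {
  ids <- lapply(config$groups, function(g) {
    sprintf("%s_%03d", toupper(substr(g, 1L, 3L)),
            seq_len(config$n_samples_per_condition))
  })
  stats::setNames(ids, config$groups)
}

synth_phenotype_classes <- function(config) {
  cls <- sort_c(unique(unname(config$drugs)))
  as.vector(outer(cls, c("sensitive", "resistant"), paste, sep = "-"))
}

# drug class -> dose grid and EC50 center; grids follow the 9-point assay
# design (anthracyclines 0-2 uM, taxanes 0-5000 nM)
synth_dose_grid <- function(drug_class) {
  if (drug_class == "taxane") {
    list(doses = c(0, 0.01, 0.1, 1, 10, 50, 100, 1000, 5000), units = "nM",
         log10_center = log10(20), log10_sd = 0.5)
  } else {
    list(doses = c(0, 0.0156, 0.03125, 0.0625, 0.125, 0.25, 0.55, 1, 2),
         units = "uM", log10_center = log10(0.2), log10_sd = 0.35)
  }
}

#' Generate true EC50 values per sample and drug
#'
#' Log-normal EC50s centered inside each drug's dose grid; continuous, so
#' ranked tails are distinguishable by construction.
#'
#' @param config `synth_config`.
#' @return data.frame `sample_id`, `drug`, `group`, `ec50`, `units`.
#' @export
synth_ec50 <- function(config) {
  set.seed(derive_seed(config$seed, 101L))
  ids <- synth_sample_ids(config)
  rows <- list()
  for (grp in config$groups) {
    for (drug in names(config$drugs)) {
      grid <- synth_dose_grid(config$drugs[[drug]])
      ec <- 10^stats::rnorm(length(ids[[grp]]), grid$log10_center, grid$log10_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[[grp]], drug = drug, group = grp, ec50 = ec,
        units = grid$units, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate raw dose-response viability data
#'
#' Four-parameter logistic curves with known EC50 and Hill slope plus
#' Gaussian viability noise; triplicate wells at each of 9 doses give 27
#' rows per sample and drug. True EC50s are returned for parameter-recovery
#' tests.
#'
#' @param config `synth_config`.
#' @param ec50s optional pre-generated true EC50 table (from
#'   [synth_ec50()]); generated if missing.
#' @return list with `dose_response` (long data.frame `sample_id`, `drug`,
#'   `group`, `dose`, `viability`) and `true_ec50`.
#' @export
synth_dose_response <- function(config, ec50s = NULL) {
  ec50s <- ec50s %||% synth_ec50(config)
  set.seed(derive_seed(config$seed, 102L))
  n_rep <- 3L
  rows <- vector("list", nrow(ec50s))
  for (i in seq_len(nrow(ec50s))) {
    drug <- ec50s$drug[[i]]
    grid <- synth_dose_grid(config$drugs[[drug]])
    if (any(grid$doses[-1L] <= 0))
      pmap_data_error("non-positive dose beyond the zero anchor in grid for %s", drug)
    hill <- stats::runif(1, 0.8, 2)
    d <- rep(grid$doses, each = n_rep)
    v <- logistic4(d, 0.05, 1, ec50s$ec50[[i]], hill) +
      stats::rnorm(length(d), 0, config$dr_noise_sd)
    rows[[i]] <- data.frame(sample_id = ec50s$sample_id[[i]], drug = drug,
                            group = ec50s$group[[i]], dose = d, viability = v,
                            stringsAsFactors = FALSE)
  }
  list(dose_response = do.call(rbind, rows), true_ec50 = ec50s)
}

#' Generate a basal expression matrix with planted PDEGs
#'
#' Per-gene baseline means are drawn from a common log2-scale distribution
#' (N(7, 1)); planted PDEGs of each phenotype class are elevated by
#' `pdeg_effect_size` in every sample belonging to that class's response
#' tails (union over the class's member conditions); all values carry
#' N(0, noise_sd) noise. No missing values.
#'
#' @param config `synth_config`.
#' @param assignment phenotype assignment from [assign_phenotypes()] covering
#'   all (drug, group) conditions of the config.
#' @return list with `expr` (genes x samples matrix) and `truth` (list:
#'   `planted_pdegs` per phenotype class, `planted_n1` placeholder,
#'   `planted_pf_sign`).
#' @export
synth_expression <- function(config, assignment) {
  conds <- unique(assignment[, c("drug", "group")])
  want <- expand.grid(drug = names(config$drugs), group = config$groups,
                      stringsAsFactors = FALSE)
  have <- paste(conds$drug, conds$group)
  miss <- setdiff(paste(want$drug, want$group), have)
  if (length(miss))
    pmap_config_error("assignment does not cover conditions: %s",
                      paste(utils::head(miss, 4L), collapse = "; "))
  samples <- sort_c(unique(assignment$sample_id))
  n_cond_samples <- table(paste(assignment$drug, assignment$group))
  if (any(n_cond_samples != config$n_samples_per_condition))
    pmap_config_error("assignment sample counts disagree with n_samples_per_condition")
  genes <- synth_gene_names(config)
  set.seed(derive_seed(config$seed, 103L))
  classes <- synth_phenotype_classes(config)
  pool <- sample(genes)
  planted <- stats::setNames(vector("list", length(classes)), classes)
  idx <- 1L
  for (cls in classes) {
    planted[[cls]] <- sort_c(pool[idx:(idx + config$n_planted_pdegs_per_class - 1L)])
    idx <- idx + config$n_planted_pdegs_per_class
  }
  base_mu <- stats::rnorm(length(genes), 7, 1)
  expr <- matrix(stats::rnorm(length(genes) * length(samples), 0, config$noise_sd),
                 nrow = length(genes),
                 dimnames = list(genes, samples))
  expr <- expr + base_mu
  for (cls in classes) {
    parts <- strsplit(cls, "-", fixed = TRUE)[[1L]]
    drug_class <- parts[[1L]]
    response <- parts[[2L]]
    member_drugs <- names(config$drugs)[config$drugs == drug_class]
    tail_samples <- unique(assignment$sample_id[
      assignment$drug %in% member_drugs & assignment$tail == response])
    expr[planted[[cls]], tail_samples] <-
      expr[planted[[cls]], tail_samples] + config$pdeg_effect_size
  }
  truth <- list(planted_pdegs = planted,
                planted_n1 = NULL,
                planted_pf_sign = NULL)
  list(expr = expr, truth = truth)
}

#' Generate a scale-free PPI network with planted N1 wiring
#'
#' A Barabási–Albert preferential-attachment backbone (heavy-tailed degree
#' distribution) over `ppi_n_nodes` nodes, with the highest-attachment node
#' named UBC to emulate the ubiquitin hub. Planted N1 genes are PPI-only
#' nodes (absent from the expression matrix, so they can never be called
#' PDEGs); each is wired to at least `planted_n1_min_pdeg_links` planted
#' PDEGs of its phenotype class, and any background edge to an
#' opposite-response planted PDEG of the same drug class is removed so the
#' planted PF sign is structural. Self-loops and duplicate edges are removed.
#'
#' @param config `synth_config`.
#' @param truth ground-truth list from [synth_expression()].
#' @return list with `edges` (cleaned data.frame `gene_a`, `gene_b`) and
#'   `truth` updated with `planted_n1` (per phenotype class) and
#'   `planted_pf_sign` (gene -> +1 sensitive / -1 resistant).
#' @export
synth_ppi <- function(config, truth) {
  set.seed(derive_seed(config$seed, 104L))
  g <- igraph::sample_pa(config$ppi_n_nodes, power = 1,
                         m = config$ppi_attachment, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  classes <- synth_phenotype_classes(config)
  n_extra_n1 <- length(classes) * config$n_planted_n1
  genes <- synth_gene_names(config)
  extras <- sprintf("X%04d", seq_len(config$ppi_n_nodes - config$n_genes - 1L))
  # node 1 is the oldest (highest-degree) node: name it UBC; remaining names
  # are assigned by random permutation so planted genes are not systematic hubs
  node_names <- character(config$ppi_n_nodes)
  node_names[1L] <- "UBC"
  node_names[-1L] <- sample(c(genes, extras))
  edges <- data.frame(gene_a = node_names[el[, 1L]],
                      gene_b = node_names[el[, 2L]],
                      stringsAsFactors = FALSE)
  n1_pool <- sample(extras, n_extra_n1)
  planted_n1 <- stats::setNames(vector("list", length(classes)), classes)
  sign_map <- integer(0)
  add_a <- character(0)
  add_b <- character(0)
  i <- 1L
  for (cls in classes) {
    take <- sort_c(n1_pool[i:(i + config$n_planted_n1 - 1L)])
    i <- i + config$n_planted_n1
    planted_n1[[cls]] <- take
    response <- sub("^.*-", "", cls)
    sgn <- if (response == "sensitive") 1L else -1L
    sign_map <- c(sign_map, stats::setNames(rep(sgn, length(take)), take))
    pdegs_cls <- truth$planted_pdegs[[cls]]
    for (ggene in take) {
      links <- sample(pdegs_cls, config$planted_n1_min_pdeg_links)
      add_a <- c(add_a, rep(ggene, length(links)))
      add_b <- c(add_b, links)
    }
  }
  edges <- rbind(edges, data.frame(gene_a = add_a, gene_b = add_b,
                                   stringsAsFactors = FALSE))
  # drop background edges that would contaminate the planted PF sign
  opp <- function(cls) {
    parts <- strsplit(cls, "-", fixed = TRUE)[[1L]]
    paste(parts[[1L]], if (parts[[2L]] == "sensitive") "resistant" else "sensitive",
          sep = "-")
  }
  bad <- rep(FALSE, nrow(edges))
  for (cls in classes) {
    opp_pdegs <- truth$planted_pdegs[[opp(cls)]]
    n1c <- planted_n1[[cls]]
    bad <- bad | (edges$gene_a %in% n1c & edges$gene_b %in% opp_pdegs) |
      (edges$gene_b %in% n1c & edges$gene_a %in% opp_pdegs)
  }
  edges <- edges[!bad, , drop = FALSE]
  truth$planted_n1 <- planted_n1
  truth$planted_pf_sign <- sign_map
  list(edges = clean_ppi_edges(edges), truth = truth)
}

#' Generate toy gene-set collections
#'
#' One set per phenotype class holding its planted PDEGs (so ORA on a
#' recovered PDEG set is positive by construction), one per class holding
#' the planted N1 genes (for PF-ranked GSEA), and random null sets.
#'
#' @param config `synth_config`.
#' @param truth ground truth with `planted_pdegs` and `planted_n1`.
#' @param n_null number of random null sets (default 5).
#' @param null_size genes per null set (default 15).
#' @return named list of character vectors.
#' @export
synth_gene_sets <- function(config, truth, n_null = 5L, null_size = 15L) {
  set.seed(derive_seed(config$seed, 105L))
  genes <- synth_gene_names(config)
  sets <- list()
  for (cls in names(truth$planted_pdegs)) {
    sets[[paste0("PLANTED_PDEG_", toupper(gsub("-", "_", cls)))]] <-
      truth$planted_pdegs[[cls]]
  }
  if (!is.null(truth$planted_n1)) {
    for (cls in names(truth$planted_n1)) {
      sets[[paste0("PLANTED_N1_", toupper(gsub("-", "_", cls)))]] <-
        truth$planted_n1[[cls]]
    }
  }
  for (j in seq_len(n_null)) {
    sets[[sprintf("NULL_SET_%02d", j)]] <- sort_c(sample(genes, null_size))
  }
  sets
}

#' Generate a synthetic knockdown-screen outcome table
#'
#' Observed directionality follows the planted PF sign in both simulated
#' cell lines — a fully PF-consistent screen for exercising the consistency
#' classifier end to end.
#'
#' @param truth ground truth with `planted_pf_sign`.
#' @param cell_lines simulated cell line labels.
#' @param drugs drug names to record per line.
#' @return data.frame `gene`, `cell_line`, `drug`, `observation`.
#' @export
synth_screen <- function(truth, cell_lines = c("LINE_A", "LINE_B"),
                         drugs = c("drug1", "drug2")) {
  genes <- names(truth$planted_pf_sign)
  obs <- ifelse(truth$planted_pf_sign > 0, "increased_sensitivity",
                "decreased_sensitivity")
  out <- expand.grid(gene = genes, cell_line = cell_lines, drug = drugs,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$observation <- obs[out$gene]
  out[order(out$gene, out$cell_line, out$drug, method = "radix"), ,
      drop = FALSE]
}

#' Generate the full synthetic input bundle
#'
#' EC50 table -> phenotype assignment -> expression with planted PDEGs ->
#' PPI with planted N1 wiring -> gene sets, all under one seed.
#'
#' @param config `synth_config`.
#' @return list with `config`, `ec50`, `assignment`, `expr`, `ppi_edges`,
#'   `gene_sets`, `truth`.
#' @export
synth_bundle <- function(config) {
  ec50 <- synth_ec50(config)
  assignment <- assign_phenotypes(ec50, k = config$k)
  ex <- synth_expression(config, assignment)
  pp <- synth_ppi(config, ex$truth)
  sets <- synth_gene_sets(config, pp$truth)
  list(config = config, ec50 = ec50, assignment = assignment,
       expr = ex$expr, ppi_edges = pp$edges, gene_sets = sets,
       truth = pp$truth)
}

#' Write a synthetic bundle to disk
#'
#' Emits expression.tsv (genes as rows), ec50.tsv, ppi.tsv, sets.gmt,
#' ground_truth.json and config.json in the pipeline's input dialects.
#'
#' @param bundle from [synth_bundle()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
synth_write <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_df <- data.frame(gene = rownames(bundle$expr), bundle$expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(expr_df, file.path(dir, "expression.tsv"))
  write_tsv(bundle$ec50, file.path(dir, "ec50.tsv"))
  write_tsv(bundle$ppi_edges, file.path(dir, "ppi.tsv"))
  write_gmt(bundle$gene_sets, file.path(dir, "sets.gmt"))
  jsonlite::write_json(bundle$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(bundle$config)
  cfg$drugs <- as.list(cfg$drugs)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
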