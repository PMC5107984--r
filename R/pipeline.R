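#' Build a pipeline configuration
#'
#' Validates and normalizes the end-to-end run configuration. Input paths
#' may be omitted when `synth` is given, in which case the synthetic bundle
#' supplies all inputs in memory.
#'
#' @param out_dir output directory.
#' @param expression,ec50,ppi,gmt,screen input file paths (screen optional).
#' @param dose_response optional raw dose-response TSV; when given, EC50s
#'   are fitted with [fit_ec50_table()] instead of read from `ec50`.
#' @param class_map named character vector drug -> drug class.
#' @param k tail size (default 15).
#' @param alpha template-matching significance level (default 1e-3).
#' @param up_z per-cell-line up-regulation z threshold (default 1).
#' @param min_links N1/N2 PDEG-adjacency threshold (default 2).
#' @param n_perm GSEA permutations (default 1000).
#' @param rank_by GSEA ranking basis: `"pf_n1"` (default) or `"pf_sum"`.
#' @param seed RNG seed.
#' @param synth optional `synth_config`; replaces file inputs.
#' @return list of class `pmap_config`.
#' @export
pmap_config <- function(out_dir,
                        expression = NULL, ec50 = NULL, ppi = NULL,
                        gmt = NULL, screen = NULL, dose_response = NULL,
                        class_map = c(doxorubicin = "anthracycline",
                                      epirubicin = "anthracycline",
                                      docetaxel = "taxane",
                                      paclitaxel = "taxane"),
                        k = 15L, alpha = 1e-3, up_z = 1.0, min_links = 2L,
                        n_perm = 1000L, rank_by = c("pf_n1", "pf_sum"),
                        seed = 1L, synth = NULL) {
  rank_by <- match.arg(rank_by)
  if (is.null(synth)) {
    for (p in c(expression, ppi)) {
      if (!is.null(p) && !file.exists(p))
        pmap_config_error("input file not found: %s", p)
    }
    if (is.null(expression) || is.null(ppi) || (is.null(ec50) && is.null(dose_response)))
      pmap_config_error("need expression, ppi and ec50 (or dose_response) inputs, or a synth config")
  }
  if (k < 1L) pmap_config_error("k must be >= 1")
  if (min_links < 1L) pmap_config_error("min_links must be >= 1")
  structure(list(out_dir = out_dir, expression = expression, ec50 = ec50,
                 ppi = ppi, gmt = gmt, screen = screen,
                 dose_response = dose_response, class_map = class_map,
                 k = as.integer(k), alpha = alpha, up_z = up_z,
                 min_links = as.integer(min_links),
                 n_perm = as.integer(n_perm), rank_by = rank_by,
                 seed = as.integer(seed), synth = synth),
            class = "pmap_config")
}

#' Run the full phenotype-mapping pipeline
#'
#' Executes phenotyping -> PDEG calling -> DRN construction (per drug class
#' and response; 2 classes x 2 responses = 4 DRNs) -> PF scoring ->
#' enrichment (ORA on PDEGs, pre-ranked GSEA on PF-ranked genes) ->
#' optional knockdown-consistency classification, writing every stage's
#' tables under `out_dir` plus a run manifest with content hashes. All stage
#' handoffs are plain files, so any stage can be re-run from persisted
#' intermediates.
#'
#' @param config `pmap_config` object.
#' @return the run manifest (list), invisibly the same as written to
#'   `manifest.json`.
#' @export
pmap_run <- function(config) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage <- function(name, fun) {
    st <- Sys.time()
    pmap_log("[stage] %s", name)
    res <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", name, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("pmap_stage_error", class(e))))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    res
  }

  # ---- inputs -------------------------------------------------------------
  inputs <- stage("load_inputs", function() {
    if (!is.null(config$synth)) {
      b <- synth_bundle(config$synth)
      list(expr = b$expr, ec50 = b$ec50, ppi = b$ppi_edges,
           sets = b$gene_sets, screen = NULL, truth = b$truth)
    } else {
      ec50 <- if (!is.null(config$dose_response)) {
        fit_ec50_table(read_tsv(config$dose_response))
      } else read_ec50(config$ec50)
      list(expr = read_expression(config$expression),
           ec50 = ec50,
           ppi = read_ppi(config$ppi),
           sets = if (!is.null(config$gmt)) read_gmt(config$gmt) else NULL,
           screen = if (!is.null(config$screen)) read_tsv(config$screen) else NULL,
           truth = NULL)
    }
  })

  assignment <- stage("phenotyping", function() {
    a <- assign_phenotypes(inputs$ec50, k = config$k)
    write_tsv(a, file.path(config$out_dir, "assignment.tsv"))
    a
  })

  pdegs <- stage("pdeg", function() {
    tm <- template_match(inputs$expr, assignment, alpha = config$alpha)
    write_tsv(tm, file.path(config$out_dir, "template_match.tsv"))
    pd <- call_pdegs(tm, inputs$expr, assignment, config$class_map,
                     up_z = config$up_z)
    write_tsv(pd, file.path(config$out_dir, "pdegs.tsv"))
    pd
  })

  graph <- stage("ppi_graph", function() ppi_graph(inputs$ppi))

  classes <- sort_c(unique(unname(config$class_map)))
  drns <- stage("drn", function() {
    out <- list()
    for (cls in classes) {
      for (response in c("sensitive", "resistant")) {
        pclass <- paste(cls, response, sep = "-")
        drn <- build_drn(graph, pdeg_genes(pdegs, pclass), pclass,
                         min_links = config$min_links)
        ddir <- file.path(config$out_dir, paste0("drn_", pclass))
        dir.create(ddir, showWarnings = FALSE)
        write_tsv(data.frame(gene = drn$n1, freq = unname(drn$freq_n1)),
                  file.path(ddir, "n1.tsv"))
        write_tsv(data.frame(gene = drn$n2, freq = unname(drn$freq_n2)),
                  file.path(ddir, "n2.tsv"))
        write_tsv(drn$pair_registry, file.path(ddir, "pair_registry.tsv"))
        write_tsv(drn$edges, file.path(ddir, "drn_edges.tsv"))
        write_tsv(drn$degrees, file.path(ddir, "degrees.tsv"))
        out[[pclass]] <- drn
      }
    }
    out
  })

  pf <- stage("pf_scores", function() {
    out <- list()
    for (cls in classes) {
      scores <- pf_scores(drns[[paste(cls, "sensitive", sep = "-")]],
                          drns[[paste(cls, "resistant", sep = "-")]])
      write_tsv(scores, file.path(config$out_dir,
                                  sprintf("pf_scores_%s.tsv", cls)))
      out[[cls]] <- scores
    }
    out
  })

  if (!is.null(inputs$sets)) {
    stage("enrichment", function() {
      universe <- rownames(inputs$expr)
      for (cls in classes) {
        for (response in c("sensitive", "resistant")) {
          pclass <- paste(cls, response, sep = "-")
          res <- ora(pdeg_genes(pdegs, pclass), inputs$sets, universe)
          write_tsv(res, file.path(config$out_dir,
                                   sprintf("ora_%s.tsv", pclass)))
        }
      }
      for (cls in classes) {
        scores <- pf[[cls]]
        v <- if (config$rank_by == "pf_n1") scores$pf_n1 else scores$pf_sum
        ranking <- stats::setNames(as.numeric(v), scores$gene)
        res <- gsea_preranked(ranking, inputs$sets, n_perm = config$n_perm,
                              seed = derive_seed(config$seed, 7L))
        write_tsv(res, file.path(config$out_dir,
                                 sprintf("gsea_%s.tsv", cls)))
      }
      NULL
    })
  }

  if (!is.null(inputs$screen)) {
    stage("consistency", function() {
      for (cls in classes) {
        calls <- classify_screen(pf[[cls]], inputs$screen)
        if (!is.null(calls))
          write_tsv(calls, file.path(config$out_dir,
                                     sprintf("consistency_%s.tsv", cls)))
      }
      NULL
    })
  }

  manifest <- stage("manifest", function() {
    files <- sort_c(list.files(config$out_dir, recursive = TRUE,
                               full.names = FALSE))
    files <- setdiff(files, "manifest.json")
    paths <- file.path(config$out_dir, files)
    hashes <- unname(tools::md5sum(paths))
    n_rows <- vapply(paths, function(p) {
      if (grepl("\\.tsv$", p)) length(readLines(p, warn = FALSE)) - 1L else NA_integer_
    }, integer(1))
    list(package_version = as.character(utils::packageVersion("pmapr")),
         seed = config$seed,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         stage_timings_s = timings,
         outputs = data.frame(file = files, md5 = hashes, n_rows = unname(n_rows),
                              stringsAsFactors = FALSE))
  })
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
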