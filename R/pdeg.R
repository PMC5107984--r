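#' Template matching of expression against a binary phenotype
#'
#' For each (drug, group) condition, correlates each gene's expression across
#' the 2k tail samples with the binary template (1 = sensitive tail,
#' 0 = resistant tail). Significance is the two-sided p-value of the Pearson
#' correlation via the t transform with 2k - 2 degrees of freedom; for a
#' binary template with equal group sizes this is a monotone transform of the
#' two-group ANOVA F statistic, so the selection is equivalent to the
#' state-dependent ANOVA formulation. Genes with zero variance across the
#' tails are skipped with a log line.
#'
#' @param expr numeric matrix, genes x samples (log2 scale).
#' @param assignment phenotype assignment from [assign_phenotypes()].
#' @param alpha significance level; only results with `p <= alpha` are
#'   returned (default 1e-3, no multiple-testing correction at this stage).
#' @return data.frame `drug`, `group`, `gene`, `r`, `p`, `direction`
#'   (`"up_in_sensitive"` or `"up_in_resistant"`).
#' @export
template_match <- function(expr, assignment, alpha = 1e-3) {
  tails <- assignment[assignment$tail != "none", , drop = FALSE]
  missing <- setdiff(tails$sample_id, colnames(expr))
  if (length(missing))
    pmap_data_error("tail samples absent from expression matrix: %s",
                    paste(utils::head(missing, 5L), collapse = ", "))
  key <- interaction(tails$drug, tails$group, drop = TRUE)
  res <- lapply(split(tails, key), function(d) {
    tpl <- as.numeric(d$tail == "sensitive")
    if (length(unique(tpl)) < 2L)
      pmap_config_error("condition (%s, %s): template is constant",
                        d$drug[[1L]], d$group[[1L]])
    x <- expr[, d$sample_id, drop = FALSE]
    sds <- apply(x, 1L, stats::sd)
    zero <- sds == 0
    if (any(zero))
      pmap_log("template_match (%s, %s): skipped %d zero-variance genes",
               d$drug[[1L]], d$group[[1L]], sum(zero))
    x <- x[!zero, , drop = FALSE]
    n <- length(tpl)
    tplc <- tpl - mean(tpl)
    xc <- x - rowMeans(x)
    r <- as.numeric(xc %*% tplc) /
      (sqrt(rowSums(xc^2)) * sqrt(sum(tplc^2)))
    r <- pmin(1, pmax(-1, r))
    df <- n - 2L
    tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[abs(r) == 1] <- .Machine$double.xmin # perfect match: p underflows to 0
    keep <- p <= alpha
    if (!any(keep)) return(NULL)
    data.frame(drug = d$drug[[1L]], group = d$group[[1L]],
               gene = rownames(x)[keep], r = r[keep], p = p[keep],
               direction = ifelse(r[keep] > 0, "up_in_sensitive",
                                  "up_in_resistant"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(drug = character(), group = character(),
                      gene = character(), r = numeric(), p = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res[order(res$drug, res$group, res$gene, method = "radix"), , drop = FALSE]
}

#' Call phenotypic differentially expressed genes (PDEGs)
#'
#' Aggregates per-condition template-matching results into per
#' phenotype-class PDEG sets (drug class x response, e.g.
#' "anthracycline-resistant"). A gene enters a class set iff, within member
#' conditions of the class where it passes template matching with the
#' matching direction, it is up-regulated in at least `min_lines` (default 2)
#' tail cell lines of that response. "Up-regulated in a cell line" is
#' operationalized as a z-score above `up_z` relative to all samples of the
#' condition — a scale-free, auditable criterion.
#'
#' @param tm template-matching results from [template_match()] (already
#'   filtered at alpha).
#' @param expr expression matrix.
#' @param assignment phenotype assignment (all ranked samples, used for the
#'   per-condition z-score reference).
#' @param class_map named character vector mapping drug -> drug class, e.g.
#'   `c(doxorubicin = "anthracycline", ...)`.
#' @param up_z per-cell-line up-regulation z threshold (default 1.0).
#' @param min_lines evidence threshold (default 2 cell lines).
#' @return data.frame `phenotype_class`, `gene`, `n_evidence_lines`,
#'   `best_p`; per-gene evidence detail in `attr(, "evidence")`.
#' @export
call_pdegs <- function(tm, expr, assignment, class_map, up_z = 1.0,
                       min_lines = 2L) {
  unknown <- setdiff(unique(tm$drug), names(class_map))
  if (length(unknown))
    pmap_data_error("template results contain drugs absent from class_map: %s",
                    paste(unknown, collapse = ", "))
  classes <- sort_c(unique(unname(class_map)))
  # per-condition z-scores against all ranked samples of the condition
  cond_key <- interaction(assignment$drug, assignment$group, drop = TRUE)
  cond_split <- split(assignment, cond_key)

  rows <- list()
  evidence <- list()
  for (cls in classes) {
    drugs <- names(class_map)[class_map == cls]
    for (response in c("sensitive", "resistant")) {
      want_dir <- if (response == "sensitive") "up_in_sensitive" else "up_in_resistant"
      sub <- tm[tm$drug %in% drugs & tm$direction == want_dir, , drop = FALSE]
      pclass <- paste(cls, response, sep = "-")
      if (!nrow(sub)) next
      counts <- new.env(parent = emptyenv())
      bestp <- new.env(parent = emptyenv())
      ev <- list()
      key2 <- interaction(sub$drug, sub$group, drop = TRUE)
      for (d in split(sub, key2)) {
        cond <- cond_split[[paste(d$drug[[1L]], d$group[[1L]], sep = ".")]]
        if (is.null(cond)) next
        samples <- cond$sample_id
        tail_ids <- cond$sample_id[cond$tail == response]
        x <- expr[d$gene, samples, drop = FALSE]
        mu <- rowMeans(x)
        sd_ <- apply(x, 1L, stats::sd)
        z <- (x[, tail_ids, drop = FALSE] - mu) / sd_
        nup <- rowSums(z > up_z)
        for (i in seq_along(d$gene)) {
          g <- d$gene[[i]]
          if (nup[[i]] >= 1L) {
            up_lines <- tail_ids[z[i, ] > up_z]
            # evidence is counted over distinct cell lines, so a line in the
            # tails of several drugs of the class contributes once
            counts[[g]] <- unique(c(counts[[g]] %||% character(0), up_lines))
            ev[[length(ev) + 1L]] <- data.frame(
              phenotype_class = pclass, gene = g, drug = d$drug[[1L]],
              group = d$group[[1L]], cell_lines = paste(up_lines, collapse = ","),
              stringsAsFactors = FALSE)
          }
          bestp[[g]] <- min(bestp[[g]] %||% 1, d$p[[i]])
        }
      }
      genes <- sort_c(ls(counts))
      n_ev <- vapply(genes, function(g) length(counts[[g]]), integer(1))
      keep <- n_ev >= as.integer(min_lines)
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          phenotype_class = pclass, gene = genes[keep],
          n_evidence_lines = unname(n_ev[keep]),
          best_p = vapply(genes[keep], function(g) bestp[[g]], numeric(1)),
          stringsAsFactors = FALSE)
      }
      evidence <- c(evidence, ev)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phenotype_class = character(), gene = character(),
               n_evidence_lines = integer(), best_p = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "evidence") <- if (length(evidence)) do.call(rbind, evidence) else NULL
  out
}

#' Extract the PDEG gene set of one phenotype class
#'
#' @param pdegs result of [call_pdegs()].
#' @param phenotype_class e.g. `"anthracycline-resistant"`.
#' @return character vector of gene symbols (lexicographic).
#' @export
pdeg_genes <- function(pdegs, phenotype_class) {
  sort_c(pdegs$gene[pdegs$phenotype_class == phenotype_class])
}
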