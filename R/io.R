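#' Read a gene expression matrix
#'
#' Reads a log2-scale expression matrix (genes as rows, samples as columns)
#' from a plain TSV (first column = gene symbol, header row of sample IDs) or
#' a GCT 1.2 file (two header lines, `Name`/`Description` meta columns).
#' Duplicate gene rows are collapsed by the per-sample maximum — the
#' conservative high-signal choice for many-to-one probe-to-gene maps — and
#' the collapse is reported via [message()] so it can be audited.
#'
#' @param path file path.
#' @param dialect `"auto"` (sniff the `#1.2` magic), `"tsv"` or `"gct"`.
#' @return numeric matrix with gene symbols as rownames, sample IDs as
#'   colnames. Symbols are case-sensitive; no aliasing is performed.
#' @export
read_expression <- function(path, dialect = c("auto", "tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) pmap_data_error("expression file not found: %s", path)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (startsWith(first, "#1.2")) "gct" else "tsv"
  }
  if (dialect == "gct") {
    raw <- read.delim(path, skip = 2L, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 3L) pmap_data_error("GCT file must have Name, Description and >=1 sample column")
    genes <- as.character(raw[[1L]])
    vals <- raw[, -c(1L, 2L), drop = FALSE]
  } else {
    raw <- read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 2L) pmap_data_error("expression TSV must have a gene column and >=1 sample column")
    genes <- as.character(raw[[1L]])
    vals <- raw[, -1L, drop = FALSE]
  }
  if (nrow(vals) == 0L) pmap_data_error("expression matrix in %s is empty", path)
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1L]
      pmap_data_error("non-numeric expression value at row %d, column '%s' of %s",
                      bad, colnames(vals)[j], path)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyNA(m)) pmap_data_error("expression matrix %s contains missing values", path)
  if (anyDuplicated(colnames(m))) pmap_data_error("duplicate sample IDs in %s", path)
  dup <- duplicated(genes)
  if (any(dup)) {
    pmap_log("collapsing %d duplicate gene rows by per-sample max", sum(dup))
    m <- collapse_by_max(m)
  }
  m
}

collapse_by_max <- function(m) {
  grp <- rownames(m)
  idx <- split(seq_len(nrow(m)), factor(grp, levels = unique(grp)))
  out <- t(vapply(idx, function(i) {
    apply(m[i, , drop = FALSE], 2L, max)
  }, numeric(ncol(m))))
  colnames(out) <- colnames(m)
  out
}

#' Read a per-sample EC50 table
#'
#' @param path TSV with columns `sample_id`, `drug`, `group`, `ec50`
#'   (optionally `units`).
#' @return data.frame; EC50s must be positive and `(sample_id, drug)` unique.
#' @export
read_ec50 <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "drug", "group", "ec50")
  miss <- setdiff(need, names(df))
  if (length(miss)) pmap_data_error("EC50 table missing columns: %s", paste(miss, collapse = ", "))
  df$ec50 <- as.numeric(df$ec50)
  if (any(!is.finite(df$ec50)) || any(df$ec50 <= 0))
    pmap_data_error("EC50 values must be finite and > 0")
  if (anyDuplicated(df[, c("sample_id", "drug")]))
    pmap_data_error("duplicate (sample_id, drug) rows in EC50 table")
  df
}

# Extract a gene symbol from a PSI-MI TAB-like identifier cell such as
# "uniprotkb:P04637|hgnc:TP53". Precedence: gene symbol namespaces, then
# locus tags, then any accession; a bare token is taken as-is.
extract_symbol <- function(cell) {
  parts <- strsplit(cell, "|", fixed = TRUE)[[1L]]
  best <- NULL
  best_rank <- 99L
  symbol_dbs <- c("hgnc", "genesymbol", "symbol", "gene symbol")
  locus_dbs <- c("locuslink", "locus", "entrezgene", "entrez gene/locuslink")
  for (p in parts) {
    colon <- regexpr(":", p, fixed = TRUE)
    if (colon < 0L) {
      rank <- 1L
      val <- p
    } else {
      db <- tolower(substr(p, 1L, colon - 1L))
      val <- substr(p, colon + 1L, nchar(p))
      rank <- if (db %in% symbol_dbs) 1L else if (db %in% locus_dbs) 2L else 3L
    }
    if (nzchar(val) && rank < best_rank) {
      best <- val
      best_rank <- rank
    }
  }
  best %||% NA_character_
}

#' Read and clean a protein-protein interaction edge list
#'
#' Accepts a plain two-column TSV of gene symbols or a PSI-MI TAB-like file
#' whose first two columns carry `db:accession|db:accession` identifier cells.
#' The result is an undirected simple edge list: self-loops and duplicate
#' unordered pairs are removed and their counts reported.
#'
#' @param path file path. Lines starting with `#` are treated as comments.
#' @return data.frame with columns `gene_a`, `gene_b` (each pair with
#'   `gene_a < gene_b` lexicographically), plus attributes
#'   `n_self_loops_removed` and `n_duplicates_removed`.
#' @export
read_ppi <- function(path) {
  if (!file.exists(path)) pmap_data_error("PPI file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  # tolerate our own writer's header row
  if (length(lines) && startsWith(lines[[1L]], "gene_a\t"))
    lines <- lines[-1L]
  if (length(lines) == 0L) pmap_data_error("PPI file %s has no data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    pmap_data_error("malformed PPI row (need >= 2 columns) at line %d", bad[1L])
  a <- vapply(fields, function(f) extract_symbol(f[[1L]]), character(1))
  b <- vapply(fields, function(f) extract_symbol(f[[2L]]), character(1))
  clean_ppi_edges(data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE))
}

#' @rdname read_ppi
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @export
clean_ppi_edges <- function(edges) {
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)
  self <- a == b
  n_self <- sum(self)
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  key <- paste(a2, b2, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  out <- data.frame(gene_a = a2[!dup], gene_b = b2[!dup],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  if (n_self + n_dup > 0L)
    pmap_log("PPI cleanup: removed %d self-loops, %d duplicate edges", n_self, n_dup)
  attr(out, "n_self_loops_removed") <- n_self
  attr(out, "n_duplicates_removed") <- n_dup
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene symbols. Duplicate members within a set are dropped with
#' a warning-level log line.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions in
#'   `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) pmap_data_error("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) pmap_data_error("GMT file %s is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    pmap_data_error("GMT line %d has fewer than 3 fields", short[1L])
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) {
    members <- f[-c(1L, 2L)]
    members <- members[nzchar(members)]
    u <- unique(members)
    if (length(u) < length(members))
      pmap_log("GMT set '%s': dropped %d duplicated members", f[[1L]],
               length(members) - length(u))
    u
  })
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(desc, nm)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions; defaults to `"na"`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in names(sets)) {
    writeLines(paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}
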