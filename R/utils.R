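#' @keywords internal
"_PACKAGE"

# Lightweight condition helpers: config errors (bad parameters) and data
# errors (bad input content) get distinct classes so the CLI can map them to
# exit codes 2 and 3.
pmap_config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pmap_config_error", "pmap_error")))
}

pmap_data_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pmap_data_error", "pmap_error")))
}

pmap_log <- function(msg, ..., verbose = getOption("pmapr.verbose", TRUE)) {
  if (isTRUE(verbose)) message(sprintf(msg, ...))
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# deterministic string sort, independent of locale
sort_c <- function(x) sort(x, method = "radix")

# deterministic data.frame writer: tab-separated, "\n" line endings, no quotes
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# RNG seeds derived from a base seed stay below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483629L
}
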