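#' Predict the direction of drug-response change under knockdown
#'
#' A negative PF score marks a resistant-network gene: knocking it down is
#' predicted to decrease drug sensitivity. A positive PF score marks a
#' sensitive-network gene: knockdown is predicted to increase sensitivity.
#' A zero score yields no prediction.
#'
#' @param pf_sum integer PF score (N1 + N2 sum, or N1-only).
#' @return one of `"increased_sensitivity"`, `"decreased_sensitivity"`,
#'   `"none"`.
#' @export
predict_direction <- function(pf_sum) {
  vapply(pf_sum, function(x) {
    if (x > 0) "increased_sensitivity"
    else if (x < 0) "decreased_sensitivity"
    else "none"
  }, character(1))
}

pf_band <- function(pf_sum) {
  a <- abs(pf_sum)
  # boundaries 10 and 100 belong to the moderate band ("between 10 and 100"
  # read as inclusive; no observed screen row contradicts this choice)
  if (a < 10) "weak" else if (a <= 100) "moderate" else "strong"
}

valid_obs <- c("increased_sensitivity", "decreased_sensitivity",
               "non_responsive")

# Per cell line, reduce per-drug observations to one direction: the direction
# of the responsive drugs if they agree; non_responsive if no drug responded;
# "mixed" if responsive drugs disagree.
line_direction <- function(obs) {
  obs <- obs[obs != "non_responsive"]
  if (!length(obs)) return("non_responsive")
  u <- unique(obs)
  if (length(u) == 1L) u else "mixed"
}

#' Classify knockdown-screen consistency for one gene
#'
#' Compares the PF-sign prediction with observed directionality per cell
#' line. If every recorded cell line matches the prediction the call is the
#' magnitude band (weak `|PF| < 10`, moderate `10 <= |PF| <= 100`, strong
#' `|PF| > 100`); if a strict subset matches, the same band restricted to the
#' matching lines; if no line matches (including all-non-responsive screens)
#' the call is inconsistent. A zero PF score is not evaluable. Mixed per-drug
#' observations within a line are classified by the responsive drug(s).
#'
#' @param gene gene symbol.
#' @param pf_sum integer PF score.
#' @param observations data.frame with columns `cell_line`, `drug`,
#'   `observation` (tokens `increased_sensitivity`, `decreased_sensitivity`,
#'   `non_responsive`).
#' @return one-row data.frame `gene`, `pf_sum`, `predicted_direction`,
#'   `category`, `matched_lines`, `restricted`.
#' @export
classify_consistency <- function(gene, pf_sum, observations) {
  if (!nrow(observations))
    pmap_data_error("no screen observations for gene %s", gene)
  bad <- setdiff(unique(observations$observation), valid_obs)
  if (length(bad))
    pmap_data_error("unknown observation token(s): %s", paste(bad, collapse = ", "))
  pred <- predict_direction(pf_sum)
  lines <- sort_c(unique(observations$cell_line))
  dirs <- vapply(lines, function(cl) {
    line_direction(observations$observation[observations$cell_line == cl])
  }, character(1))
  if (pred == "none") {
    return(data.frame(gene = gene, pf_sum = pf_sum,
                      predicted_direction = pred, category = "not_evaluable",
                      matched_lines = "", restricted = FALSE,
                      stringsAsFactors = FALSE))
  }
  matched <- lines[dirs == pred]
  category <- if (length(matched) == 0L) "inconsistent" else pf_band(pf_sum)
  restricted <- length(matched) > 0L && length(matched) < length(lines)
  data.frame(gene = gene, pf_sum = pf_sum, predicted_direction = pred,
             category = category,
             matched_lines = paste(matched, collapse = ","),
             restricted = restricted, stringsAsFactors = FALSE)
}

#' Classify a whole knockdown screen against PF scores
#'
#' @param pf data.frame with columns `gene`, `pf_sum`.
#' @param screen data.frame with columns `gene`, `cell_line`, `drug`,
#'   `observation`.
#' @return data.frame of per-gene calls (see [classify_consistency()]),
#'   in the row order of `pf`.
#' @export
classify_screen <- function(pf, screen) {
  calls <- lapply(seq_len(nrow(pf)), function(i) {
    g <- pf$gene[[i]]
    obs <- screen[screen$gene == g, , drop = FALSE]
    if (!nrow(obs)) return(NULL)
    classify_consistency(g, pf$pf_sum[[i]], obs)
  })
  out <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Summarize consistency calls for a knockdown screen
#'
#' Reports how many genes match the PF prediction in all recorded cell
#' lines, in a strict subset, not at all, or are not evaluable, plus the
#' observed-direction tally irrespective of prediction (screens can agree
#' between cell lines while disagreeing with the PF sign, so both numbers
#' are reported separately).
#'
#' @param calls data.frame from [classify_screen()].
#' @param screen optional raw screen table; when given, per-direction counts
#'   of genes with the same observed direction in every recorded cell line
#'   are added.
#' @return list of counts and fractions.
#' @export
summarize_screen <- function(calls, screen = NULL) {
  if (!nrow(calls)) pmap_config_error("no consistency calls to summarize")
  consistent <- calls$category %in% c("weak", "moderate", "strong")
  full <- consistent & !calls$restricted
  partial <- consistent & calls$restricted
  n_tested <- sum(calls$category != "not_evaluable")
  out <- list(n_genes = nrow(calls),
              n_tested = n_tested,
              n_consistent_all_lines = sum(full),
              n_consistent_partial = sum(partial),
              n_inconsistent = sum(calls$category == "inconsistent"),
              n_not_evaluable = sum(calls$category == "not_evaluable"),
              fraction_consistent_all_lines = sum(full) / n_tested)
  if (!is.null(screen)) {
    genes <- unique(calls$gene)
    dirs <- vapply(genes, function(g) {
      obs <- screen[screen$gene == g, , drop = FALSE]
      lines <- unique(obs$cell_line)
      d <- vapply(lines, function(cl) {
        line_direction(obs$observation[obs$cell_line == cl])
      }, character(1))
      u <- unique(d)
      if (length(u) == 1L) u else "discordant"
    }, character(1))
    out$n_observed_increase_all_lines <- sum(dirs == "increased_sensitivity")
    out$n_observed_decrease_all_lines <- sum(dirs == "decreased_sensitivity")
  }
  out
}
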