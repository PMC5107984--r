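# Four-parameter logistic on dose d:
#   v(d) = lower + (upper - lower) / (1 + (d / ec50)^hill)
# hill > 0 gives a decreasing viability curve; the zero-dose anchor maps to
# the upper asymptote.
logistic4 <- function(d, lower, upper, ec50, hill) {
  lower + (upper - lower) / (1 + (d / ec50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of viability against dose with the EC50 parameterized on
#' the log10 scale. The EC50 is constrained to
#' `[min positive dose / 10, max dose * 10]`; fits that hit no decreasing
#' trend (e.g. monotone increasing "viability") or fail to move off a flat
#' response are flagged `converged = FALSE` rather than raising an error, so
#' callers can exclude the sample downstream with a logged reason.
#'
#' @param doses numeric vector of doses (a zero anchor is allowed; other
#'   doses must be positive); recycled against `viability` if replicates are
#'   supplied as repeated dose entries.
#' @param viability numeric vector, fraction-of-control scale.
#' @param pin_upper if `TRUE` the upper asymptote is fixed at 1.
#' @return list with `ec50`, `hill`, `lower`, `upper`, `rss`, `converged`.
#' @export
fit_ec50 <- function(doses, viability, pin_upper = FALSE) {
  if (length(doses) != length(viability))
    pmap_config_error("doses and viability lengths differ")
  if (any(doses < 0)) pmap_data_error("negative dose encountered")
  if (any(!is.finite(viability))) pmap_data_error("non-finite viability values")
  if (length(unique(doses)) < 4L)
    pmap_config_error("need >= 4 distinct doses to fit a 4PL curve")

  pos <- doses[doses > 0]
  lo_bound <- min(pos) / 10
  hi_bound <- max(doses) * 10
  fail <- list(ec50 = NA_real_, hill = NA_real_, lower = NA_real_,
               upper = NA_real_, rss = NA_real_, converged = FALSE)

  if (stats::sd(viability) == 0) return(fail)
  # mean response per dose; require an overall decreasing trend
  mu <- tapply(viability, doses, mean)
  ord <- order(as.numeric(names(mu)))
  mu <- mu[ord]
  if (mu[[1L]] <= mu[[length(mu)]]) return(fail)

  vmin <- min(viability); vmax <- max(viability)
  obj <- function(p) {
    ec50 <- 10^p[[1L]]
    hill <- exp(p[[2L]])
    lower <- p[[3L]]
    upper <- if (pin_upper) 1 else p[[4L]]
    sum((viability - logistic4(doses, lower, upper, ec50, hill))^2)
  }
  # multi-start across the dose range; refine the best with a tight restart
  starts_ec <- log10(exp(seq(log(min(pos)), log(max(doses)), length.out = 5L)))
  best <- NULL
  for (s in starts_ec) {
    p0 <- c(s, log(1.5), vmin, if (pin_upper) NULL else vmax)
    o <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000L, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  for (i in 1:2) { # polish: Nelder-Mead restarts sharpen the optimum
    o <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000L, reltol = 1e-15))
    if (o$value < best$value) best <- o
  }
  ec50 <- 10^best$par[[1L]]
  ec50 <- min(max(ec50, lo_bound), hi_bound)
  list(ec50 = ec50,
       hill = exp(best$par[[2L]]),
       lower = best$par[[3L]],
       upper = if (pin_upper) 1 else best$par[[4L]],
       rss = best$value,
       converged = TRUE)
}

#' Fit EC50s for a long-format dose-response table
#'
#' @param dr data.frame with columns `sample_id`, `drug`, `group`, `dose`,
#'   `viability` (replicates as repeated rows).
#' @param pin_upper passed to [fit_ec50()].
#' @return EC50 table (`sample_id`, `drug`, `group`, `ec50`); non-convergent
#'   fits are dropped with a log line.
#' @export
fit_ec50_table <- function(dr, pin_upper = FALSE) {
  need <- c("sample_id", "drug", "group", "dose", "viability")
  miss <- setdiff(need, names(dr))
  if (length(miss)) pmap_data_error("dose-response table missing columns: %s",
                                    paste(miss, collapse = ", "))
  key <- interaction(dr$sample_id, dr$drug, drop = TRUE)
  out <- lapply(split(dr, key), function(d) {
    fit <- fit_ec50(d$dose, d$viability, pin_upper = pin_upper)
    if (!fit$converged) {
      pmap_log("fit_ec50: sample %s / drug %s did not converge; excluded",
               d$sample_id[[1L]], d$drug[[1L]])
      return(NULL)
    }
    data.frame(sample_id = d$sample_id[[1L]], drug = d$drug[[1L]],
               group = d$group[[1L]], ec50 = fit$ec50,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out[order(out$sample_id, out$drug, method = "radix"), , drop = FALSE]
}

#' Enumerate drug-response conditions
#'
#' Full cross product of drugs, population groups and the two response
#' phenotypes. Four drugs and three groups yield the canonical 24 conditions.
#'
#' @param drugs,groups non-empty character vectors.
#' @return data.frame `drug`, `group`, `response`.
#' @export
enumerate_conditions <- function(drugs, groups) {
  if (!length(drugs) || !length(groups))
    pmap_config_error("drugs and groups must be non-empty")
  out <- expand.grid(response = c("sensitive", "resistant"),
                     group = groups, drug = drugs,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("drug", "group", "response")]
  rownames(out) <- NULL
  out
}

#' Assign sensitive and resistant phenotype tails per condition
#'
#' Within each (drug, group) condition, samples are ranked by EC50 ascending
#' (ties broken by lexicographic sample ID for determinism); the `k` lowest
#' define the sensitive tail and the `k` highest the resistant tail.
#'
#' @param ec50s EC50 table as from [read_ec50()] / [fit_ec50_table()].
#' @param k tail size (default 15).
#' @return data.frame `drug`, `group`, `sample_id`, `ec50`, `rank`, `tail`
#'   with `tail` in `{"sensitive", "resistant", "none"}`.
#' @export
assign_phenotypes <- function(ec50s, k = 15L) {
  k <- as.integer(k)
  if (k < 1L) pmap_config_error("tail size k must be >= 1")
  key <- interaction(ec50s$drug, ec50s$group, drop = TRUE)
  out <- lapply(split(ec50s, key), function(d) {
    n <- nrow(d)
    if (n < 2L * k)
      pmap_data_error("condition (%s, %s) has %d samples; need >= 2k = %d",
                      d$drug[[1L]], d$group[[1L]], n, 2L * k)
    o <- order(d$ec50, d$sample_id, method = "radix")
    d <- d[o, , drop = FALSE]
    d$rank <- seq_len(n)
    d$tail <- "none"
    d$tail[seq_len(k)] <- "sensitive"
    d$tail[(n - k + 1L):n] <- "resistant"
    d[, c("drug", "group", "sample_id", "ec50", "rank", "tail")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(out$drug, out$group, out$rank, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- k
  out
}
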