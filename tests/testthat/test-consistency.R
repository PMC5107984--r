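obs_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(cell_line = r[[1]], drug = r[[2]], observation = r[[3]],
               stringsAsFactors = FALSE)
  }))
}

test_that("PF sign predicts knockdown direction; zero is not evaluable", {
  expect_equal(predict_direction(c(-204, 17, 0)),
               c("decreased_sensitivity", "increased_sensitivity", "none"))
  call <- classify_consistency("g", 0, obs_df(list("L1", "d", "non_responsive")))
  expect_equal(call$category, "not_evaluable")
})

test_that("magnitude bands partition |PF| with inclusive 10..100 moderate band", {
  both_down <- obs_df(list("BT549", "d", "decreased_sensitivity"),
                      list("MDA-MB-231", "d", "decreased_sensitivity"))
  for (case in list(list(-1, "weak"), list(-9, "weak"), list(-10, "moderate"),
                    list(-100, "moderate"), list(-101, "strong"),
                    list(-1101, "strong"))) {
    call <- classify_consistency("g", case[[1]], both_down)
    expect_equal(call$category, case[[2]])
    expect_false(call$restricted)
  }
})

test_that("partial agreement restricts the call to matching cell lines", {
  obs <- obs_df(list("BT549", "doxorubicin", "non_responsive"),
                list("BT549", "epirubicin", "non_responsive"),
                list("MDA-MB-231", "doxorubicin", "decreased_sensitivity"),
                list("MDA-MB-231", "epirubicin", "decreased_sensitivity"))
  call <- classify_consistency("CAV1", -331, obs)
  expect_equal(call$category, "strong")
  expect_true(call$restricted)
  expect_equal(call$matched_lines, "MDA-MB-231")
})

test_that("mixed per-drug observations classify by the responsive drug", {
  obs <- obs_df(list("MDA-MB-231", "epirubicin", "decreased_sensitivity"),
                list("MDA-MB-231", "doxorubicin", "non_responsive"))
  call <- classify_consistency("CXCL9", -8, obs)
  expect_equal(call$category, "weak")
})

test_that("all-non-responsive and opposite-direction screens are inconsistent", {
  nr <- obs_df(list("BT549", "d", "non_responsive"),
               list("MDA-MB-231", "d", "non_responsive"))
  expect_equal(classify_consistency("EP300", -308, nr)$category, "inconsistent")
  up <- obs_df(list("BT549", "d", "increased_sensitivity"),
               list("MDA-MB-231", "d", "increased_sensitivity"))
  expect_equal(classify_consistency("NME7", -41, up)$category, "inconsistent")
  expect_error(classify_consistency("g", 5, obs_df(list("L", "d", "huh"))),
               "unknown observation")
})

test_that("the published knockdown screens reproduce every printed category", {
  pf <- read.delim(extdata("knockdown_pf_scores.tsv"))
  expected <- read.delim(extdata("knockdown_expected_consistency.tsv"))
  for (cls in c("anthracycline", "taxane")) {
    screen <- read.delim(extdata(paste0(cls, "_knockdown_screen.tsv")))
    calls <- classify_screen(pf[pf$drug_class == cls, ], screen)
    e <- expected[expected$drug_class == cls, ]
    m <- merge(calls, e, by = "gene")
    expect_equal(nrow(m), nrow(e))
    expect_equal(m$category.x, m$category.y,
                 info = paste("class:", cls))
    expect_equal(m$restricted.x, m$restricted.y)
  }
})

test_that("screen summaries reproduce the published counts", {
  pf <- read.delim(extdata("knockdown_pf_scores.tsv"))
  s1 <- read.delim(extdata("anthracycline_knockdown_screen.tsv"))
  s2 <- read.delim(extdata("taxane_knockdown_screen.tsv"))
  c1 <- classify_screen(pf[pf$drug_class == "anthracycline", ], s1)
  c2 <- classify_screen(pf[pf$drug_class == "taxane", ], s2)
  sum1 <- summarize_screen(c1, s1)
  sum2 <- summarize_screen(c2, s2)
  expect_equal(sum1$n_genes, 19L)
  expect_equal(sum2$n_genes, 13L)
  # 10 of 19 anthracycline genes PF-consistent in both cell lines
  expect_equal(sum1$n_consistent_all_lines, 10L)
  # 6 of 13 taxane genes PF-consistent in both cell lines
  expect_equal(sum2$n_consistent_all_lines, 6L)
  # overall both-line agreement 16/32 = 50%
  total <- sum1$n_consistent_all_lines + sum2$n_consistent_all_lines
  tested <- sum1$n_tested + sum2$n_tested
  expect_equal(total / tested, 0.5)
  # 11 taxane genes show increased sensitivity in both lines irrespective of
  # PF sign (reported separately from the 6 PF-consistent ones)
  expect_equal(sum2$n_observed_increase_all_lines, 11L)
})

test_that("single strong call summarizes to 100% agreement", {
  obs <- obs_df(list("L1", "d", "decreased_sensitivity"))
  call <- classify_consistency("g", -500, obs)
  s <- summarize_screen(call)
  expect_equal(s$fraction_consistent_all_lines, 1)
})

test_that("negating pf_sum flips the prediction", {
  for (v in c(-300, -10, -1, 1, 10, 300)) {
    a <- predict_direction(v)
    b <- predict_direction(-v)
    expect_true(a != b)
  }
})
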