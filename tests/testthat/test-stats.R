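test_that("exact signed-rank p-values match full sign enumeration", {
  # all-positive differences 1..5: only the two extreme assignments are as
  # extreme, p = 2/32
  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(r$p_value, 0.0625)
  expect_equal(r$W, 15)
  expect_true(r$exact)

  # perfect symmetry with tied magnitudes
  r2 <- wilcoxon_signed_rank(c(1, 0), c(0, 1))
  expect_equal(r2$W, 0)
  expect_equal(r2$p_value, 1)

  # random paired data, several sizes incl. ties, against the brute-force
  # oracle over all 2^n assignments
  set.seed(19)
  for (n in c(4, 7, 10, 13)) {
    a <- round(rnorm(n, 1, 2), 1)
    b <- round(rnorm(n, 0, 2), 1)
    d <- a - b
    if (all(d == 0)) next
    r <- wilcoxon_signed_rank(a, b)
    expect_equal(r$p_value, brute_wilcoxon_p(d), tolerance = 1e-12,
                 label = paste("n =", n))
  }
})

test_that("exact untied p-values agree with the reference implementation", {
  set.seed(5)
  for (n in c(6, 9, 13)) {
    a <- rnorm(n); b <- rnorm(n)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("identical samples give an undefined, flagged p-value", {
  x <- c(3, 1, 4, 1, 5)
  r <- wilcoxon_signed_rank(x, x)
  expect_true(r$flagged)
  expect_true(is.na(r$p_value))
})

test_that("large-sample path uses the tie-corrected normal approximation", {
  set.seed(8)
  a <- rnorm(40); b <- rnorm(40, 0.4)
  r <- wilcoxon_signed_rank(a, b)
  expect_false(r$exact)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(r$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("Bonferroni threshold keeps full precision but truncates the display", {
  b <- bonferroni_threshold(0.05, 3)
  expect_equal(b$threshold, 0.05 / 3)
  expect_equal(b$display, "0.016")
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.05, 5)$threshold, 0.01)
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})

make_reports <- function(n_subj, shift = list()) {
  positions <- c("supine", "prone", "right_lateral", "left_lateral")
  grid <- expand.grid(subject = seq_len(n_subj),
                      lung = c("right", "left"),
                      section = c("apical", "middle", "basal", "diaphragm"),
                      stringsAsFactors = FALSE)
  out <- lapply(positions, function(p) {
    g <- grid
    g$ratio_pct <- 25 + stats::rnorm(nrow(g), 0, 5)
    sh <- shift[[p]]
    if (!is.null(sh)) {
      sel <- g$lung == sh$lung
      g$ratio_pct[sel] <- g$ratio_pct[sel] + sh$delta
    }
    g
  })
  names(out) <- positions
  out
}

test_that("position comparison flags a strong one-sided shift and not a null one", {
  set.seed(77)
  reports <- make_reports(13, shift = list(
    right_lateral = list(lung = "right", delta = 30)))
  cmp <- compare_positions(reports, alpha = 0.05, m = 3)
  expect_equal(nrow(cmp), 2 * 4 * 3)
  rd_right <- cmp$significant[cmp$contrast == "supine_vs_right_lateral" &
                              cmp$lung == "right"]
  expect_true(all(rd_right))
  prone <- cmp$significant[cmp$contrast == "supine_vs_prone"]
  expect_false(any(prone))
  expect_equal(attr(cmp, "threshold"), 0.05 / 3)
})

test_that("identical reports across positions yield no significant contrasts", {
  set.seed(1)
  reports <- make_reports(8)
  for (p in c("prone", "right_lateral", "left_lateral")) reports[[p]] <- reports$supine
  cmp <- compare_positions(reports)
  expect_true(all(is.na(cmp$significant)))  # all-zero differences are flagged
})

test_that("subject mismatch across positions is rejected", {
  set.seed(2)
  reports <- make_reports(6)
  reports$prone <- reports$prone[reports$prone$subject != 6, ]
  expect_error(compare_positions(reports), "subject mismatch")
})
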