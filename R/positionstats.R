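#' Wilcoxon signed-rank test with exact enumeration
#'
#' Paired two-sided Wilcoxon signed-rank test. Zero differences are dropped
#' (Wilcoxon's convention) and ties in |difference| receive mid-ranks. The
#' statistic W is the sum of signed ranks. For n <= 25 the p-value is exact
#' over all 2^n equally likely sign assignments (computed by subset-sum
#' convolution, identical to full enumeration); for larger n a normal
#' approximation with tie and continuity correction is used.
#'
#' @param a,b equal-length paired samples.
#' @return A list with \code{W}, \code{p_value}, \code{n_used} (pairs after
#'   dropping zero differences), \code{exact} (logical) and \code{flagged}
#'   (TRUE when all differences are zero and the p-value is undefined).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(W = NA_real_, p_value = NA_real_, n_used = 0L,
                exact = NA, flagged = TRUE))
  r <- rank(abs(d))
  W <- sum(sign(d) * r)
  if (n <= 25L) {
    # distribution of the positive-rank sum in half-rank integer units
    r2 <- as.integer(round(2 * r))
    S2 <- sum(r2)
    f <- numeric(S2 + 1)
    f[1] <- 1
    for (ri in r2) {
      g <- numeric(S2 + 1)
      g[(ri + 1):(S2 + 1)] <- f[1:(S2 + 1 - ri)]
      f <- f + g
    }
    t2 <- 2 * (0:S2) - S2        # signed-rank sum (doubled units) per mass point
    p <- sum(f[abs(t2) >= abs(2 * W) - 1e-9]) / 2^n
    return(list(W = W, p_value = min(1, p), n_used = n, exact = TRUE,
                flagged = FALSE))
  }
  # normal approximation, tie and continuity corrected
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- V - mu
  z <- (z - sign(z) * 0.5) / sqrt(sig2)
  p <- 2 * stats::pnorm(-abs(z))
  list(W = W, p_value = min(1, p), n_used = n, exact = FALSE, flagged = FALSE)
}

#' Bonferroni-adjusted significance threshold
#'
#' Per-comparison threshold alpha/m at full precision, with the display value
#' truncated (not rounded) to three decimals — 0.05 over three contrasts
#' displays as "0.016".
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return A list with \code{threshold} (numeric, full precision) and
#'   \code{display} (character, truncated to 3 decimals).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 3L) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (m < 1) stop("'m' must be >= 1")
  thr <- alpha / m
  list(threshold = thr, display = sprintf("%.3f", floor(thr * 1000) / 1000))
}

#' Compare section ratios across body positions
#'
#' Paired Wilcoxon signed-rank tests of per-subject highly-functional-area
#' ratios in each lung and cranio-caudal section, contrasting each non-supine
#' position against supine, with Bonferroni-adjusted significance over the
#' position contrasts.
#'
#' @param reports named list of per-position data.frames (names must include
#'   "supine" plus at least one of "prone", "right_lateral", "left_lateral"),
#'   each with columns subject, lung, section, ratio_pct, with identical
#'   subject sets across positions.
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of comparisons for the Bonferroni correction (default 3,
#'   the number of position contrasts).
#' @return A data.frame with one row per lung x section x contrast: n, W,
#'   p_value, significant (p < alpha/m; NA when the test is undefined), and
#'   the threshold used as attribute \code{"threshold"}.
#' @export
compare_positions <- function(reports, alpha = 0.05, m = 3L) {
  if (!"supine" %in% names(reports))
    stop("'reports' must contain a 'supine' reference")
  contrasts <- intersect(c("prone", "right_lateral", "left_lateral"),
                         setdiff(names(reports), "supine"))
  if (length(contrasts) == 0L) stop("no non-supine positions to compare")
  ref <- reports$supine
  subj <- sort(unique(ref$subject))
  thr <- bonferroni_threshold(alpha, m)$threshold
  rows <- list()
  for (pos in contrasts) {
    other <- reports[[pos]]
    if (!setequal(subj, unique(other$subject)))
      stop("subject mismatch between supine and ", pos)
    for (lg in unique(ref$lung)) for (sec in unique(as.character(ref$section))) {
      va <- vapply(subj, function(s)
        ref$ratio_pct[ref$subject == s & ref$lung == lg & ref$section == sec][1], 0)
      vb <- vapply(subj, function(s)
        other$ratio_pct[other$subject == s & other$lung == lg & other$section == sec][1], 0)
      wt <- wilcoxon_signed_rank(va, vb)
      rows[[length(rows) + 1L]] <- data.frame(
        lung = lg, section = sec, contrast = paste0("supine_vs_", pos),
        n = wt$n_used, W = wt$W, p_value = wt$p_value,
        significant = if (wt$flagged) NA else wt$p_value < thr,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}
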