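# Reporting conventions and nonparametric tests, reproducing the
# behaviour of SPSS (quartile type 6, half-up rounding at 2 dp,
# zeros-dropped tie-corrected Wilcoxon signed-rank without continuity
# correction, McNemar exact/continuity-corrected switch at 25 discordant
# pairs, tie-corrected Mann-Whitney and Kruskal-Wallis, uncorrected
# Pearson chi-square). "Textbook" variants are available behind
# arguments where they differ.

#' Round half-up
#'
#' Decimal rounding where .5 always rounds away from zero (the SPSS /
#' spreadsheet convention), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)  # 0.13 0.14
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # tiny epsilon guards against representation error in x*p (e.g. 16.125
  # stored fractionally below .5); scaled to stay far below any honest
  # half-way gap at <= 15 significant digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count, reporting convention
#'
#' `100 * count / n`, rounded half-up to 2 decimal places.
#'
#' @param count Non-negative integer count, `<= n`.
#' @param n Positive denominator.
#' @return Percentage, 2 dp.
#' @export
#' @examples
#' percent(597, 676)  # 88.31
percent <- function(count, n) {
  if (length(n) != 1 || !is.finite(n) || n <= 0) stop("n must be a positive count", call. = FALSE)
  if (any(count < 0) || any(count > n)) stop("count must lie in [0, n]", call. = FALSE)
  round_half_up(100 * count / n, 2)
}

#' Percentage-point change between two reported percentages
#'
#' Difference of two percentages that have ALREADY been rounded to
#' 2 dp, itself rounded half-up to 2 dp. Forming the change from the
#' rounded operands (rather than from raw counts) is the published-table
#' convention this package reproduces; the two can differ in the last
#' digit.
#'
#' @param pct_before,pct_after Percentages rounded to 2 dp.
#' @return Percentage points, 2 dp.
#' @export
#' @examples
#' pp_change(91.57, 75.44)  # 16.13 (raw counts would give 16.12)
pp_change <- function(pct_before, pct_after) {
  round_half_up(pct_before - pct_after, 2)
}

#' Quartile summary
#'
#' Median and quartiles by linear interpolation. The default convention
#' is type 6 (the SPSS "HAVERAGE" definition); type 7 (the R default) is
#' selectable.
#'
#' @param values Non-empty numeric vector.
#' @param type Quantile type, 6 (default) or 7.
#' @return List with `p50`, `p25`, `p75`, classed `quartile_summary`.
#' @export
#' @examples
#' quartiles(c(1, 2, 3, 4, 5))  # p50 3, p25 1.5, p75 4.5 under type 6
quartiles <- function(values, type = 6) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("quartiles of an empty vector are undefined", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = type, names = FALSE)
  structure(list(p50 = q[2], p25 = q[1], p75 = q[3]), class = "quartile_summary")
}

#' @export
print.quartile_summary <- function(x, ...) {
  cat(fmt_quartiles(x), "\n")
  invisible(x)
}

.paired_result <- function(test_name, statistic, p_value, n_effective,
                           method, degenerate = FALSE, extra = list()) {
  structure(c(list(test_name = test_name, statistic = unname(statistic),
                   p_value = unname(min(1, p_value)), n_effective = n_effective,
                   method = method, degenerate = degenerate), extra),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat("<", x$test_name, "> statistic = ", format(x$statistic, digits = 5),
      ", p = ", format(x$p_value, digits = 4), " (", x$method,
      ", n_eff = ", x$n_effective, ")\n", sep = "")
  invisible(x)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Paired two-sided test on `after - before`. Zero differences are
#' dropped; absolute differences are ranked with midranks for ties. The
#' default method is the SPSS large-sample approximation:
#' `z = (W - n(n+1)/4) / sigma` with tie-corrected
#' `sigma^2 = n(n+1)(2n+1)/24 - sum(t^3 - t)/48` and no continuity
#' correction, `W` the positive-rank sum. `method = "exact"` enumerates
#' all `2^n` sign patterns of the observed absolute ranks (n <= 24) and
#' doubles the smaller tail.
#'
#' @param before,after Equal-length numeric vectors.
#' @param method `"normal"` (SPSS default) or `"exact"`.
#' @return A `paired_test_result` with `statistic` (z, or W for exact),
#'   `p_value`, `n_effective` (non-zero differences) and `W` (positive
#'   rank sum).
#' @export
wilcoxon_signed_rank <- function(before, after, method = c("normal", "exact")) {
  method <- match.arg(method)
  if (length(before) != length(after)) stop("before and after must have equal length", call. = FALSE)
  d <- as.numeric(after) - as.numeric(before)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("no non-zero pairs: the signed-rank test is undefined", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (method == "exact") {
    if (n > 24) stop("exact enumeration limited to 24 non-zero pairs", call. = FALSE)
    # distribution of W over all sign patterns, via convolution
    probs <- 1
    offsets <- 0
    for (ri in r) {
      offsets <- c(offsets, offsets + ri)
      probs <- c(probs, probs) / 2
      agg <- tapply(probs, offsets, sum)
      offsets <- as.numeric(names(agg))
      probs <- as.numeric(agg)
    }
    lo <- sum(probs[offsets <= W + 1e-12])
    hi <- sum(probs[offsets >= W - 1e-12])
    p <- min(1, 2 * min(lo, hi))
    return(.paired_result("WILCOXON_SR", W, p, n, "exact enumeration",
                          extra = list(W = W)))
  }
  e <- n * (n + 1) / 4
  ties <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (v <= 0) stop("zero variance: all absolute differences tied at one value with n = 1",
                   call. = FALSE)
  z <- (W - e) / sqrt(v)
  .paired_result("WILCOXON_SR", z, 2 * stats::pnorm(-abs(z)), n,
                 "normal approximation, tie-corrected, no continuity correction",
                 extra = list(W = W))
}

#' McNemar paired test for a change in a proportion
#'
#' With discordant counts `b` (TRUE -> FALSE) and `c` (FALSE -> TRUE):
#' when `b + c < 25` the exact two-sided binomial p-value
#' `min(1, 2 P(Bin(b+c, 1/2) <= min(b, c)))` is used; otherwise the
#' continuity-corrected chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df
#' (the SPSS dual convention). No discordant pairs gives p = 1 flagged
#' degenerate.
#'
#' @param flags_before,flags_after Equal-length logical vectors.
#' @param exact_threshold Discordant-pair count below which the exact
#'   binomial is used (default 25).
#' @return A `paired_test_result`; `n_effective` is `b + c`.
#' @export
mcnemar <- function(flags_before, flags_after, exact_threshold = 25) {
  if (length(flags_before) != length(flags_after)) {
    stop("flag vectors must have equal length", call. = FALSE)
  }
  keep <- !(is.na(flags_before) | is.na(flags_after))
  fb <- as.logical(flags_before[keep]); fa <- as.logical(flags_after[keep])
  b <- sum(fb & !fa)
  cc <- sum(!fb & fa)
  m <- b + cc
  if (m == 0L) {
    return(.paired_result("MCNEMAR", 0, 1, 0L, "degenerate: no discordant pairs",
                          degenerate = TRUE, extra = list(b = b, c = cc)))
  }
  if (m < exact_threshold) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), m, 0.5))
    .paired_result("MCNEMAR", min(b, cc), p, m, "exact binomial",
                   extra = list(b = b, c = cc))
  } else {
    stat <- (abs(b - cc) - 1)^2 / m
    .paired_result("MCNEMAR", stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
                   m, "continuity-corrected chi-square", extra = list(b = b, c = cc))
  }
}

.group_result <- function(test_name, statistic, p_value, df = NA_real_,
                          method = "", extra = list()) {
  structure(c(list(test_name = test_name, statistic = unname(statistic),
                   p_value = unname(min(1, p_value)), df = df, method = method),
              extra),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat("<", x$test_name, "> statistic = ", format(x$statistic, digits = 5),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis H test
#'
#' Tie-corrected H referred to the chi-square distribution on k - 1 df
#' (delegates to [stats::kruskal.test()]).
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return A `group_test_result`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("kruskal_wallis needs at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  kt <- stats::kruskal.test(groups)
  .group_result("KRUSKAL_WALLIS", kt$statistic, kt$p.value,
                df = unname(kt$parameter), method = "tie-corrected H, chi-square reference")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. When the combined sample has no ties and
#' `n_a * n_b <= 400` the exact null distribution of U is used (doubling
#' the smaller tail); with ties and a small enough combined sample the
#' exact distribution is obtained by complete enumeration of group
#' assignments; otherwise the tie-corrected normal approximation without
#' continuity correction (the SPSS convention) applies.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_limit Use the exact distribution when
#'   `length(a) * length(b)` is at most this (default 400).
#' @return A `group_test_result` with `statistic` = min(U_a, U_b) and a
#'   `U_a` element.
#' @export
mann_whitney <- function(a, b, exact_limit = 400) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  has_ties <- anyDuplicated(pooled) > 0L
  if (na * nb <= exact_limit) {
    if (!has_ties) {
      lo <- stats::pwilcox(Ua, na, nb)
      hi <- 1 - stats::pwilcox(Ua - 1, na, nb)
      p <- min(1, 2 * min(lo, hi))
      return(.group_result("MANN_WHITNEY", min(Ua, Ub), p,
                           method = "exact (no ties)", extra = list(U_a = Ua)))
    }
    if (choose(na + nb, na) <= 2e5) {
      combs <- utils::combn(na + nb, na)
      Us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
      lo <- mean(Us <= Ua + 1e-12)
      hi <- mean(Us >= Ua - 1e-12)
      p <- min(1, 2 * min(lo, hi))
      return(.group_result("MANN_WHITNEY", min(Ua, Ub), p,
                           method = "exact (enumeration with ties)",
                           extra = list(U_a = Ua)))
    }
  }
  n <- na + nb
  ties <- table(r)
  v <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) {
    # all observations identical: no evidence either way
    return(.group_result("MANN_WHITNEY", min(Ua, Ub), 1,
                         method = "degenerate: all values tied", extra = list(U_a = Ua)))
  }
  z <- (Ua - na * nb / 2) / sqrt(v)
  .group_result("MANN_WHITNEY", min(Ua, Ub), 2 * stats::pnorm(-abs(z)),
                method = "normal approximation, tie-corrected, no continuity correction",
                extra = list(U_a = Ua, z = z))
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square on an r x c table of counts (the SPSS
#' "Pearson Chi-Square" row), df = (r-1)(c-1).
#'
#' @param table Matrix of non-negative integer counts with positive row
#'   and column margins.
#' @return A `group_test_result`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table))) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square test undefined with a zero margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  .group_result("CHI_SQUARE", ct$statistic, ct$p.value,
                df = unname(ct$parameter), method = "Pearson, uncorrected")
}
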