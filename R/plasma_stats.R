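# Cohort-level inference: exact Fisher test on the 2x2 detection table,
# detection-rate ratio, and the three-group Kruskal-Wallis +
# Student-Newman-Keuls comparison of normalized concentrations.

#' Build a 2x2 plasma detection table
#'
#' Counts of detected/undetected samples by outcome group, with the exact
#' two-sided Fisher p-value and the detection-rate ratio attached.
#'
#' @param a Case positives.
#' @param b Case negatives.
#' @param c Control positives.
#' @param d Control negatives.
#' @return Object of class `detection_table`: list with the four counts,
#'   `p_two_sided` and `rate_ratio`.
#' @examples
#' detection_table(6, 4, 1, 26)
#' @export
detection_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d,
                 p_two_sided = fisher_exact_two_sided(a, b, c, d),
                 rate_ratio = detection_rate_ratio(a, b, c, d)),
            class = "detection_table")
}

#' @export
print.detection_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2,
              dimnames = list(c("positive", "negative"),
                              c("case", "control")))
  print(m)
  cat(sprintf("Fisher exact (two-sided) p = %.3g; detection-rate ratio = %.3g\n",
              x$p_two_sided, x$rate_ratio))
  invisible(x)
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric point
#' probabilities of every admissible table whose probability does not
#' exceed that of the observed table (point-probability method, with a
#' relative tolerance of 1e-7 on the comparison). A table with a zero
#' margin carries no information and returns p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = detection status,
#'   columns = outcome group.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(6, 4, 1, 26)   # 0.00056
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  m <- a + c            # total positives
  n <- b + d            # total negatives
  k <- a + b            # case column total
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Detection-rate ratio of a 2x2 table
#'
#' The case detection rate divided by the control detection rate,
#' `(a/(a+b)) / (c/(c+d))`. With no control positives the ratio is
#' undefined and reported as `Inf` with a warning.
#'
#' @inheritParams fisher_exact_two_sided
#' @return The rate ratio (0 when there are no case positives).
#' @examples
#' detection_rate_ratio(6, 4, 1, 26)   # 16.2
#' @export
detection_rate_ratio <- function(a, b, c, d) {
  if (a + b == 0 || c + d == 0)
    stop("both groups need at least one sample", call. = FALSE)
  if (c == 0) {
    warning("no control positives: rate ratio undefined, reporting Inf",
            call. = FALSE)
    return(Inf)
  }
  (a / (a + b)) / (c / (c + d))
}

#' Kruskal-Wallis rank test across groups
#'
#' `H = 12 / (N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2`, corrected for ties
#' by dividing by `1 - sum(t^3 - t) / (N^3 - N)`, with the p-value from the
#' chi-square distribution on g-1 degrees of freedom. H is invariant under
#' monotone transformation of the pooled data. When all observations are
#' identical, H = 0 and p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   observations).
#' @return List with `H`, `p`, `df`, and the per-group mean ranks
#'   `mean_ranks`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))   # H = 4.571
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2)
    stop("at least 2 groups are required", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  nn <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  ni <- lengths(groups)
  h <- 12 / (nn * (nn + 1)) * sum(ni * (rbar - (nn + 1) / 2)^2)
  ties <- table(pooled)
  corr <- 1 - sum(ties^3 - ties) / (nn^3 - nn)
  if (corr > 0) h <- h / corr else h <- 0
  df <- length(groups) - 1
  p <- if (h == 0) 1 else stats::pchisq(h, df, lower.tail = FALSE)
  mr <- as.numeric(rbar)
  names(mr) <- names(groups) %||% as.character(seq_along(groups))
  list(H = h, p = p, df = df, mean_ranks = mr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Student-Newman-Keuls post hoc comparison on ranks
#'
#' Rank-based SNK following a Kruskal-Wallis test: groups are ordered by
#' mean rank of the pooled data; for a pair whose ordered positions span
#' `p` groups, the studentized-range statistic is
#' `q = (Rbar_A - Rbar_B) / sqrt((N(N+1)/12) * ((1/n_A + 1/n_B)/2))`,
#' compared against the infinite-df critical value `q(alpha, p, Inf)`.
#' Acceptance is step-down: when a comparison is not significant, every
#' comparison nested inside its span is declared not significant without
#' further testing.
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param alpha Familywise level (default 0.05).
#' @return Object of class `snk_result`: data frame with one row per
#'   unordered pair (`group_a`, `group_b`, `span`, `q`, `q_critical`,
#'   `significant`), plus attributes `H`, `kw_p` from the accompanying
#'   Kruskal-Wallis test.
#' @examples
#' snk_posthoc(list(g1 = c(1, 2), g2 = c(3, 4), g3 = c(5, 6)))
#' @export
snk_posthoc <- function(groups, alpha = 0.05) {
  if (length(groups) < 2)
    stop("at least 2 groups are required", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  kw <- kruskal_wallis(groups)
  nn <- sum(lengths(groups))
  ord <- order(kw$mean_ranks, decreasing = TRUE)
  g <- length(groups)
  rows <- list()
  blocked <- matrix(FALSE, g, g)  # by ordered positions
  for (span in g:2) {
    for (i in seq_len(g - span + 1)) {
      j <- i + span - 1
      ga <- ord[i]; gb <- ord[j]
      na <- length(groups[[ga]]); nb <- length(groups[[gb]])
      se <- sqrt((nn * (nn + 1) / 12) * ((1 / na + 1 / nb) / 2))
      q <- abs(kw$mean_ranks[ga] - kw$mean_ranks[gb]) / se
      qc <- stats::qtukey(1 - alpha, span, Inf)
      sig <- !blocked[i, j] && q >= qc
      if (!sig) {
        for (ii in i:j) for (jj in ii:j) blocked[ii, jj] <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = names(groups)[ga], group_b = names(groups)[gb],
        span = span, q = unname(q), q_critical = qc, significant = sig,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("snk_result", "data.frame"),
            H = kw$H, kw_p = kw$p, alpha = alpha)
}

#' @export
print.snk_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f (p = %.4g); SNK at alpha = %g\n",
              attr(x, "H"), attr(x, "kw_p"), attr(x, "alpha")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
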