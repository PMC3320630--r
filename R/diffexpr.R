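# Two-group differential expression: exact Mann-Whitney rank-sum test,
# Benjamini-Hochberg step-up adjustment, median-based fold-change, and the
# spike-in-derived fold-change threshold.

# Null distribution of the Mann-Whitney U statistic for group sizes (m, n):
# counts of label assignments per U value, built by dynamic programming over
# the pooled ranks (assigning each successive rank to group A adds the
# number of B observations already placed below it). Cached per (m, n).
.mw_cache <- new.env(parent = emptyenv())

mw_null_counts <- function(m, n) {
  key <- paste(m, n, sep = "_")
  if (!is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
  maxu <- m * n
  dp <- matrix(0, m + 1, maxu + 1)
  dp[1, 1] <- 1
  for (i in seq_len(m + n)) {
    new <- matrix(0, m + 1, maxu + 1)
    for (k in 0:min(i, m)) {
      if (i - k <= n)                       # rank i goes to group B
        new[k + 1, ] <- dp[k + 1, ]
      if (k >= 1) {                         # rank i goes to group A
        cc <- i - k                         # B observations below it
        if (cc <= n) {
          src <- dp[k, seq_len(maxu + 1 - cc)]
          new[k + 1, (cc + 1):(maxu + 1)] <-
            new[k + 1, (cc + 1):(maxu + 1)] + src
        }
      }
    }
    dp <- new
  }
  counts <- dp[m + 1, ]
  .mw_cache[[key]] <- counts
  counts
}

# Exact two-sided p for observed U given group sizes, by the equal-tail
# doubling convention on the (symmetric) exact null: 2 * min tail, capped.
mw_exact_p <- function(u, m, n) {
  counts <- mw_null_counts(m, n)
  total <- sum(counts)
  cdf <- cumsum(counts) / total
  lower <- cdf[u + 1]
  upper <- if (u == 0) 1 else 1 - cdf[u]
  min(1, 2 * min(lower, upper))
}

#' Mann-Whitney rank-sum test with an exact small-sample path
#'
#' Two-sided test of a location difference between two independent samples.
#' When the smaller group has at most `exact_max_n` observations and the
#' pooled data contain no ties, the p-value is exact: the null distribution
#' of U is enumerated over all `choose(n_a + n_b, n_a)` label assignments
#' (via a cached dynamic program) and the equal-tail two-sided probability
#' is returned. Otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 observations.
#' @param exact_max_n Largest smaller-group size for which the exact
#'   enumeration path is taken (default 8).
#' @return Two-sided p-value in (0, 1].
#' @examples
#' mann_whitney_exact(1:5, 6:10)   # complete separation: 2/252
#' @export
mann_whitney_exact <- function(group_a, group_b, exact_max_n = 8) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (anyNA(group_a) || anyNA(group_b))
    stop("missing values are not allowed", call. = FALSE)
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && min(na, nb) <= exact_max_n)
    return(mw_exact_p(as.integer(round(u)), na, nb))
  mw_approx_p(u, na, nb, pooled)
}

# Normal approximation with tie and continuity corrections.
mw_approx_p <- function(u, na, nb, pooled) {
  nn <- na + nb
  mu <- na * nb / 2
  tie_tab <- table(pooled)
  sigma2 <- (na * nb / 12) *
    (nn + 1 - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  if (u == mu) z <- 0
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Implements the step-up rule: with ordered p-values p_(1) <= ... <= p_(m),
#' the adjusted value of the i-th ranked test is
#' `min over j >= i of p_(j) * m / j`, capped at 1; the result is returned
#' in the input order.
#'
#' @param p_values Numeric vector of raw p-values, all in (0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stop("p-values must all lie in (0, 1]", call. = FALSE)
  m <- length(p_values)
  o <- order(p_values)
  ranked <- p_values[o]
  adj <- pmin(1, rev(cummin(rev(ranked * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Fold-change between two groups of log2 signals
#'
#' The linear-scale ratio of group medians, `r = 2^(median(case) -
#' median(control))`, reported as a magnitude >= 1 with a direction:
#' `up` when the case median is at least the control median, `down`
#' otherwise. The median-based estimator is robust and consistent with the
#' rank-based test used alongside it.
#'
#' @param case_log2,control_log2 Numeric vectors of normalized log2 signals.
#' @return List with elements `magnitude` (>= 1) and `direction`.
#' @examples
#' fold_change(c(3, 4, 5), c(2, 3, 4))   # 2-fold up
#' @export
fold_change <- function(case_log2, control_log2) {
  if (length(case_log2) == 0 || length(control_log2) == 0)
    stop("empty group", call. = FALSE)
  r <- 2^(stats::median(case_log2) - stats::median(control_log2))
  list(magnitude = max(r, 1 / r),
       direction = if (r >= 1) "up" else "down")
}

#' Derive the fold-change threshold from spike-in controls
#'
#' Spike-in controls are added in identical amounts to every sample, so any
#' apparent fold-change they show is technical variation. The threshold
#' `T_fc` is the maximum observed spike-in fold-change magnitude between the
#' two groups; downstream, a probeset must exceed it strictly
#' (`fold_change > T_fc`) to count as aberrantly expressed.
#'
#' @param normalized A log2-scale [expression_matrix()] from
#'   [quantile_normalize()].
#' @param annotation Probe annotation data.frame (see
#'   [read_probe_annotation()]).
#' @param sample_sheet Sample sheet data.frame.
#' @param case_group,control_group Group labels to compare.
#' @return Object of class `spike_threshold`: list with `t_fc` and the
#'   per-spike-in observed fold-change magnitudes `spike_fc`.
#' @export
derive_spike_threshold <- function(normalized, annotation, sample_sheet,
                                   case_group = "SPB",
                                   control_group = "STB") {
  stopifnot(inherits(normalized, "expr_matrix"))
  validate_probe_annotation(annotation)
  spikes <- annotation$probeset_id[annotation$probe_class == "spike_in"]
  spikes <- intersect(spikes, probeset_ids(normalized))
  if (length(spikes) == 0)
    stop("no spike-in probesets in the matrix; supply an explicit ",
         "fold-change threshold instead", call. = FALSE)
  case_s <- sample_sheet$sample_id[sample_sheet$group == case_group]
  ctrl_s <- sample_sheet$sample_id[sample_sheet$group == control_group]
  x <- normalized$intensities
  fc <- vapply(spikes, function(ps)
    fold_change(x[ps, case_s], x[ps, ctrl_s])$magnitude, numeric(1))
  structure(list(t_fc = max(fc), spike_fc = fc), class = "spike_threshold")
}

#' @export
print.spike_threshold <- function(x, ...) {
  cat(sprintf("Spike-in fold-change threshold T_fc = %.3f (max of %d spike-ins)\n",
              x$t_fc, length(x$spike_fc)))
  invisible(x)
}

#' Per-probeset two-group differential expression
#'
#' Runs the Mann-Whitney test (exact small-sample path where applicable),
#' Benjamini-Hochberg adjustment and median fold-change for every
#' regular-class probeset; spike-in and reference probesets are excluded
#' from the testing universe. A probeset is `significant` when its adjusted
#' p falls below `alpha`, and `passes_fc` when its fold-change magnitude
#' strictly exceeds the threshold.
#'
#' @param normalized Log2-scale [expression_matrix()].
#' @param annotation Probe annotation data.frame.
#' @param sample_sheet Sample sheet data.frame.
#' @param case_group,control_group Group labels (each needs >= 2 samples).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param threshold A `spike_threshold` from [derive_spike_threshold()], a
#'   single numeric fold-change threshold, or `NULL` to derive it from the
#'   spike-ins in `normalized`.
#' @param exact_max_n Passed to [mann_whitney_exact()].
#' @return A data.frame of class `de_table` with columns `probeset_id`,
#'   `gene_symbol`, `fold_change`, `direction`, `p_raw`, `p_adj`,
#'   `significant`, `passes_fc`; the applied threshold and alpha are
#'   attached as attributes `t_fc` and `alpha`.
#' @export
run_differential_expression <- function(normalized, annotation, sample_sheet,
                                        case_group = "SPB",
                                        control_group = "STB",
                                        alpha = 0.05, threshold = NULL,
                                        exact_max_n = 8) {
  stopifnot(inherits(normalized, "expr_matrix"))
  if (normalized$scale != "log2")
    stop("differential expression expects a normalized log2 matrix",
         call. = FALSE)
  validate_probe_annotation(annotation)
  validate_sample_sheet(sample_sheet)

  case_s <- sample_sheet$sample_id[sample_sheet$group == case_group]
  ctrl_s <- sample_sheet$sample_id[sample_sheet$group == control_group]
  if (length(case_s) < 2 || length(ctrl_s) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (is.null(threshold))
    threshold <- derive_spike_threshold(normalized, annotation, sample_sheet,
                                        case_group, control_group)
  t_fc <- if (inherits(threshold, "spike_threshold")) threshold$t_fc
          else as.numeric(threshold)

  reg <- annotation$probeset_id[annotation$probe_class == "regular"]
  reg <- intersect(reg, probeset_ids(normalized))
  x <- normalized$intensities[reg, c(case_s, ctrl_s), drop = FALSE]
  na <- length(case_s); nb <- length(ctrl_s)

  ranks <- t(apply(x, 1, rank))
  u <- rowSums(ranks[, seq_len(na), drop = FALSE]) - na * (na + 1) / 2
  tied <- apply(x, 1, function(r) anyDuplicated(r) > 0)

  p_raw <- numeric(length(reg))
  exact_ok <- !tied & min(na, nb) <= exact_max_n
  if (any(exact_ok)) {
    counts <- mw_null_counts(na, nb)
    cdf <- cumsum(counts) / sum(counts)
    ui <- as.integer(round(u[exact_ok]))
    lower <- cdf[ui + 1]
    upper <- ifelse(ui == 0, 1, 1 - cdf[pmax(ui, 1)])
    p_raw[exact_ok] <- pmin(1, 2 * pmin(lower, upper))
  }
  for (i in which(!exact_ok))
    p_raw[i] <- mw_approx_p(u[i], na, nb, x[i, ])

  med_case <- apply(x[, seq_len(na), drop = FALSE], 1, stats::median)
  med_ctrl <- apply(x[, na + seq_len(nb), drop = FALSE], 1, stats::median)
  r <- 2^(med_case - med_ctrl)
  magnitude <- pmax(r, 1 / r)
  direction <- ifelse(r >= 1, "up", "down")

  p_adj <- benjamini_hochberg(p_raw)
  sym <- annotation$gene_symbol[match(reg, annotation$probeset_id)]
  out <- data.frame(probeset_id = reg, gene_symbol = sym,
                    fold_change = magnitude, direction = direction,
                    p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj < alpha,
                    passes_fc = magnitude > t_fc,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("de_table", "data.frame"),
            t_fc = t_fc, alpha = alpha,
            case_group = case_group, control_group = control_group)
}

#' @export
summary.de_table <- function(object, ...) {
  hit <- object$significant & object$passes_fc
  res <- list(n_probesets = nrow(object),
              t_fc = attr(object, "t_fc"),
              alpha = attr(object, "alpha"),
              n_significant = sum(object$significant),
              n_changed = sum(hit),
              n_up = sum(hit & object$direction == "up"),
              n_down = sum(hit & object$direction == "down"))
  class(res) <- "summary.de_table"
  res
}

#' @export
print.summary.de_table <- function(x, ...) {
  cat(sprintf("Differential expression over %d probesets (alpha = %g, T_fc = %.3f)\n",
              x$n_probesets, x$alpha, x$t_fc))
  cat(sprintf("  significant (adjusted p < alpha): %d\n", x$n_significant))
  cat(sprintf("  significant and > T_fc-fold changed: %d (%d up, %d down)\n",
              x$n_changed, x$n_up, x$n_down))
  invisible(x)
}

#' @export
print.de_table <- function(x, n = 10, ...) {
  print(summary(x))
  ord <- order(x$p_adj, -x$fold_change)
  cat("Top probesets:\n")
  print.data.frame(utils::head(x[ord, ], n), digits = 4, row.names = FALSE)
  invisible(x)
}
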