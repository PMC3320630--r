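# Fixture builders and independent brute-force oracles shared by the suite.

# Tiny expression matrix with named dims.
make_em <- function(values, probes = NULL, samples = NULL,
                    scale = "linear") {
  m <- as.matrix(values)
  if (is.null(probes)) probes <- sprintf("PS%03d_at", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(probes, samples)
  expression_matrix(m, scale = scale)
}

# Minimal sample sheet for a case/control split.
make_sheet <- function(samples, groups) {
  data.frame(sample_id = samples, group = groups,
             gest_week = ifelse(groups == "SPB", 30, 39),
             stringsAsFactors = FALSE)
}

# Hand-built differential-expression table carrying the de_table class.
make_de_table <- function(df, t_fc = 2.9, alpha = 0.05) {
  structure(df, class = c("de_table", "data.frame"),
            t_fc = t_fc, alpha = alpha,
            case_group = "SPB", control_group = "STB")
}

# Brute-force Mann-Whitney oracle: enumerate every label assignment of the
# pooled sample, compute U for each, and read the equal-tail two-sided
# probability off the enumerated null.
oracle_mw_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  picks <- utils::combn(n, na)
  u_all <- apply(picks, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Brute-force two-sided Fisher oracle: enumerate all tables with the
# observed margins via products of binomial coefficients (no distribution
# functions involved) and sum those no more probable than the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Brute-force upper-tail hypergeometric P[X >= x] on the 2x2 margins
# (n, N - n) x (K, N - K), summing binomial-coefficient products.
oracle_hyper_tail <- function(x, n, K, N) {
  support <- max(0, n - (N - K)):min(n, K)
  xs <- support[support >= x]
  if (!length(xs)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}
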