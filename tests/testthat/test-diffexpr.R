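test_that("exact Mann-Whitney reproduces known tail probabilities", {
  # complete separation of 5 vs 5: 2 of the choose(10, 5) assignments
  expect_equal(mann_whitney_exact(1:5, 6:10), 2 / 252, tolerance = 1e-12)
  expect_equal(mann_whitney_exact(6:10, 1:5), 2 / 252, tolerance = 1e-12)
  # identical groups carry no signal (tie-corrected approximation path)
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3)), 1)
  # exchangeability on arbitrary data
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
    expect_equal(mann_whitney_exact(a, b), mann_whitney_exact(b, a),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_exact(numeric(0), 1:3), "at least 2")
})

test_that("the exact path agrees with brute-force enumeration up to 6 vs 6", {
  set.seed(2)
  for (na in 2:6) for (nb in na:6) {
    for (rep in 1:3) {
      a <- rnorm(na); b <- rnorm(nb, mean = rep - 2)
      expect_equal(mann_whitney_exact(a, b), oracle_mw_p(a, b),
                   tolerance = 1e-12,
                   label = sprintf("sizes (%d,%d) rep %d", na, nb, rep))
    }
  }
})

test_that("exact and approximate paths agree with the reference implementation", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(7)
    expect_equal(mann_whitney_exact(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large tie-free samples take the corrected normal approximation
  set.seed(4)
  a <- rnorm(30); b <- rnorm(25)
  expect_equal(mann_whitney_exact(a, b),
               stats::wilcox.test(a, b, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("Benjamini-Hochberg follows the step-up rule", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4), tolerance = 1e-12)
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(c(0.5, 1.0)), c(1.0, 1.0))
  # adjusted never below raw, order preserved, permutation invariant
  set.seed(5)
  p <- runif(50)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p))
  expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  perm <- sample(50)
  expect_equal(benjamini_hochberg(p[perm]), adj[perm], tolerance = 1e-12)
  expect_error(benjamini_hochberg(c(0.5, 0)), "\\(0, 1]")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\(0, 1]")
})

test_that("fold-change is the linear ratio of group medians with direction", {
  fc <- fold_change(c(4, 5, 6), c(3, 4, 5))
  expect_equal(fc$magnitude, 2)
  expect_identical(fc$direction, "up")
  fc0 <- fold_change(c(1, 2, 3), c(1, 2, 3))
  expect_equal(fc0$magnitude, 1)
  expect_identical(fc0$direction, "up")
  dn <- fold_change(c(0, 0, 0), c(log2(3), log2(3), log2(3)))
  expect_equal(dn$magnitude, 3, tolerance = 1e-12)
  expect_identical(dn$direction, "down")
  # reciprocal symmetry under label swap
  set.seed(6)
  a <- rnorm(5); b <- rnorm(5)
  f1 <- fold_change(a, b); f2 <- fold_change(b, a)
  expect_equal(f1$magnitude, f2$magnitude, tolerance = 1e-12)
  expect_false(f1$direction == f2$direction &&
                 abs(f1$magnitude - 1) > 1e-12)
  expect_error(fold_change(numeric(0), 1), "empty")
})

test_that("the spike threshold is the maximum spike-in fold-change", {
  log2x <- rbind(c(4, 4, 5, 5), c(6, 6, 6, 6), c(3, 3, 3, 3))
  # spike FCs: 2^1 = 2.0, 1.0, 1.0 after planting offsets
  log2x[1, 1:2] <- log2x[1, 3:4] + 1
  m <- make_em(log2x, probes = c("SP1", "SP2", "SP3"),
               samples = c("A1", "A2", "B1", "B2"), scale = "log2")
  ann <- data.frame(probeset_id = c("SP1", "SP2", "SP3"),
                    gene_symbol = "", accession = c("x1", "x2", "x3"),
                    probe_class = "spike_in", stringsAsFactors = FALSE)
  sheet <- make_sheet(c("A1", "A2", "B1", "B2"),
                      c("SPB", "SPB", "STB", "STB"))
  th <- derive_spike_threshold(m, ann, sheet)
  expect_equal(th$t_fc, 2)
  expect_identical(length(th$spike_fc), 3L)
  # order-free
  perm <- make_em(log2x[c(3, 1, 2), ], probes = c("SP3", "SP1", "SP2"),
                  samples = c("A1", "A2", "B1", "B2"), scale = "log2")
  expect_equal(derive_spike_threshold(perm, ann, sheet)$t_fc, 2)

  no_spike <- ann; no_spike$probe_class <- "regular"
  no_spike$gene_symbol <- c("G1", "G2", "G3")
  expect_error(derive_spike_threshold(m, no_spike, sheet), "explicit")
})

test_that("planted differential expression is recovered on the default study", {
  s <- simulate_expression_study(sim_config(seed = 7))
  nm <- quantile_normalize(s$matrix)
  de <- run_differential_expression(nm, s$annotation, s$sample_sheet)
  truth <- s$truth$probes[match(de$probeset_id, s$truth$probes$probeset_id), ]
  hit <- de$significant & de$passes_fc
  expect_gte(sum(hit & truth$is_de), 45)
  # all detected planted "up" probes report direction up
  expect_true(all(de$direction[hit & truth$is_de &
                                 truth$true_direction == "up"] == "up"))
  # spike-ins and the reference probe are excluded from the testing universe
  expect_identical(nrow(de), as.integer(s$config$n_probesets))
  expect_error(run_differential_expression(nm, s$annotation,
                                           s$sample_sheet,
                                           case_group = "TCS"),
               "at least 2 samples")
})

test_that("a null study produces no significant fold-change hits", {
  cfg <- sim_config(planted_de = data.frame(n_probesets = integer(0),
                                            fold_change = numeric(0),
                                            direction = character(0)),
                    seed = 3)
  s <- simulate_expression_study(cfg)
  nm <- quantile_normalize(s$matrix)
  de <- run_differential_expression(nm, s$annotation, s$sample_sheet)
  expect_identical(sum(de$significant & de$passes_fc), 0L)
})
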