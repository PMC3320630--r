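null_config <- function(seed, ...) {
  sim_config(planted_de = data.frame(n_probesets = integer(0),
                                     fold_change = numeric(0),
                                     direction = character(0)),
             seed = seed, ...)
}

test_that("the expression study generator is deterministic under a fixed seed", {
  s1 <- simulate_expression_study(sim_config(seed = 1))
  s2 <- simulate_expression_study(sim_config(seed = 1))
  expect_identical(s1$matrix$intensities, s2$matrix$intensities)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$go, s2$go)
  expect_identical(s1$truth$probes, s2$truth$probes)
  s3 <- simulate_expression_study(sim_config(seed = 2))
  expect_false(identical(s1$matrix$intensities, s3$matrix$intensities))
})

test_that("the noise-free limit reproduces the planted fold-change exactly", {
  cfg <- sim_config(n_probesets = 50, n_per_group = 4, n_spike_ins = 2,
                    noise_log2_sd = 0,
                    planted_de = data.frame(n_probesets = 5, fold_change = 4,
                                            direction = "up"),
                    multiprobe_genes = c("2" = 0), seed = 5)
  s <- simulate_expression_study(cfg)
  truth <- s$truth$probes
  planted <- truth$probeset_id[truth$is_de]
  x <- s$matrix$intensities
  case <- s$sample_sheet$sample_id[s$sample_sheet$group == "SPB"]
  ctrl <- s$sample_sheet$sample_id[s$sample_sheet$group == "STB"]
  for (ps in planted) {
    ratio <- median(x[ps, case]) / median(x[ps, ctrl])
    expect_equal(ratio, 4, tolerance = 1e-12)
  }
  # reference probe control median sits at the reference signal
  ref <- s$annotation$probeset_id[s$annotation$probe_class == "reference"]
  expect_equal(median(x[ref, ctrl]), 408, tolerance = 1e-9)
})

test_that("structural bookkeeping matches the config", {
  cfg <- sim_config(seed = 3)
  s <- simulate_expression_study(cfg)
  ann <- s$annotation
  expect_identical(sum(ann$probe_class == "regular"), as.integer(cfg$n_probesets))
  expect_identical(sum(ann$probe_class == "spike_in"), as.integer(cfg$n_spike_ins))
  expect_identical(sum(ann$probe_class == "reference"), 1L)
  expect_identical(dim(s$matrix),
                   as.integer(c(cfg$n_probesets + cfg$n_spike_ins + 1,
                                2 * cfg$n_per_group)))
  # multi-probeset genes: 30 genes x2 and 10 genes x3
  tab <- table(table(ann$gene_symbol[ann$probe_class == "regular" &
                                       nzchar(ann$gene_symbol)]))
  expect_identical(unname(tab[["2"]]), 30L)
  expect_identical(unname(tab[["3"]]), 10L)
  expect_error(sim_config(planted_de = data.frame(n_probesets = 3000,
                                                  fold_change = 6,
                                                  direction = "up")),
               "planted")
})

test_that("spike-in apparent fold-changes stay below 2.9 at the default noise", {
  below <- vapply(1:100, function(seed) {
    s <- simulate_expression_study(sim_config(seed = seed))
    nm <- quantile_normalize(s$matrix)
    th <- derive_spike_threshold(nm, s$annotation, s$sample_sheet)
    th$t_fc < 2.9
  }, logical(1))
  expect_gte(mean(below), 0.95)
})

test_that("qPCR calibration generator honours the standard-curve model", {
  # perfect doubling, noise-free: exactly 1/log10(2) cycles per decade
  cal <- simulate_qpcr_calibration(efficiency = 1, cq_sd = 0,
                                   replicates = 4, seed = 2)
  mean_cq <- tapply(cal$cq, cal$copies, mean, na.rm = TRUE)
  spacing <- as.numeric(-diff(mean_cq))
  expect_equal(spacing, rep(1 / log10(2), length(spacing)),
               tolerance = 1e-12)
  # bookkeeping: 20 replicates at each of 5 dilutions
  cal20 <- simulate_qpcr_calibration(efficiency = 0.9, replicates = 20,
                                     seed = 4)
  expect_identical(nrow(cal20), 100L)
  expect_identical(cal20,
                   simulate_qpcr_calibration(efficiency = 0.9,
                                             replicates = 20, seed = 4))
  expect_error(simulate_qpcr_calibration(efficiency = 1.5), "efficiency")
  expect_error(simulate_qpcr_calibration(1, dilution_log10_range = c(5, 1)),
               "range")
})

test_that("plasma cohort detections follow the Bernoulli design", {
  pos <- vapply(1:200, function(seed) {
    co <- simulate_plasma_cohort(n_case = 10, n_control = 27,
                                 detect_prob_case = 0.6,
                                 detect_prob_control = 0.037, seed = seed)
    sum(co$records$detected[co$cohort$group == "SPB"])
  }, numeric(1))
  expect_equal(mean(pos), 6, tolerance = 0.35)

  none <- simulate_plasma_cohort(detect_prob_case = 0,
                                 detect_prob_control = 0, seed = 9)
  expect_false(any(none$records$detected))
  expect_true(all(none$records$copies_per_ml < 20))

  c1 <- simulate_plasma_cohort(seed = 11)
  c2 <- simulate_plasma_cohort(seed = 11)
  expect_identical(c1, c2)
  expect_error(simulate_plasma_cohort(detect_prob_case = 1.2), "probabilities")
})

test_that("the planted GO term has the largest true enrichment", {
  s <- simulate_expression_study(sim_config(seed = 8))
  truth <- s$truth$probes
  up <- unique(truth$gene_symbol[truth$is_de & nzchar(truth$gene_symbol)])
  bg <- unique(truth$gene_symbol[nzchar(truth$gene_symbol)])
  folds <- vapply(split(s$go$gene_symbol, s$go$term_id), function(members) {
    fold_enrichment(length(intersect(up, members)), length(up),
                    length(intersect(bg, members)), length(bg))
  }, numeric(1))
  expect_identical(names(which.max(folds)), s$truth$enriched_term_id)
})
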