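ref_ann <- function() {
  data.frame(probeset_id = c("REF", "P1", "P2"),
             gene_symbol = c("PLAC4", "G1", "G2"),
             accession = c("r0", "a1", "a2"),
             probe_class = c("reference", "regular", "regular"),
             stringsAsFactors = FALSE)
}

test_that("the expression threshold is the reference-probe median", {
  sheet <- make_sheet(sprintf("S%d", 1:5), rep("STB", 5))
  em <- make_em(rbind(c(390, 400, 408, 415, 430),
                      c(1, 1, 1, 1, 1), c(2, 2, 2, 2, 2)),
                probes = c("REF", "P1", "P2"),
                samples = sprintf("S%d", 1:5))
  expect_equal(expression_threshold(em, ref_ann(), sheet), 408)
  # even count: mean-of-middle convention
  sheet2 <- make_sheet(c("S1", "S2"), c("STB", "STB"))
  em2 <- make_em(rbind(c(400, 420), c(1, 1), c(2, 2)),
                 probes = c("REF", "P1", "P2"), samples = c("S1", "S2"))
  expect_equal(expression_threshold(em2, ref_ann(), sheet2), 410)
  # sample permutation leaves the median unchanged
  em3 <- make_em(em$intensities[, 5:1], probes = c("REF", "P1", "P2"),
                 samples = sprintf("S%d", 5:1))
  expect_equal(expression_threshold(em3, ref_ann(), sheet), 408)
  no_ref <- ref_ann(); no_ref$probe_class[1] <- "regular"
  expect_error(expression_threshold(em, no_ref, sheet), "reference")
})

test_that("highly expressed uses a strict inequality at the threshold", {
  sheet <- make_sheet(c("C1", "C2", "C3"), rep("SPB", 3))
  em <- make_em(rbind(c(409, 409, 409),   # just above
                      c(408, 408, 408),   # exactly at: excluded
                      c(1000, 200, 1000)),
                probes = c("PA", "PB", "PC"), samples = c("C1", "C2", "C3"))
  hi <- highly_expressed(em, sheet, "SPB", t_expr = 408)
  expect_setequal(hi, c("PA", "PC"))
  expect_error(highly_expressed(em, sheet, "TCS", 408), "no samples")
})

test_that("highly expressed matches a brute-force recount on a simulated study", {
  s <- simulate_expression_study(sim_config(n_probesets = 300, seed = 12))
  te <- expression_threshold(s$matrix, s$annotation, s$sample_sheet)
  hi <- highly_expressed(s$matrix, s$sample_sheet, "SPB", te)
  case <- s$sample_sheet$sample_id[s$sample_sheet$group == "SPB"]
  recount <- character()
  for (ps in probeset_ids(s$matrix))
    if (median(s$matrix$intensities[ps, case]) > te)
      recount <- c(recount, ps)
  expect_setequal(hi, recount)
})

test_that("multi-probeset genes report the arithmetic mean fold-change", {
  de <- make_de_table(data.frame(
    probeset_id = c("ps1", "ps2", "ps3", "ps4"),
    gene_symbol = c("IL1RL1", "IL1RL1", "IL1RL1", "OTHER"),
    fold_change = c(15.5, 12.0, 9.38, 3.2),
    direction = c("up", "up", "up", "down"),
    p_raw = rep(0.001, 4), p_adj = rep(0.01, 4),
    significant = TRUE, passes_fc = TRUE, stringsAsFactors = FALSE))
  ann <- data.frame(probeset_id = c("ps1", "ps2", "ps3", "ps4"),
                    gene_symbol = c("IL1RL1", "IL1RL1", "IL1RL1", "OTHER"),
                    accession = paste0("a", 1:4),
                    probe_class = "regular", stringsAsFactors = FALSE)
  panel <- build_panel(de, highly = c("ps1", "ps2", "ps3", "ps4"), ann)
  expect_identical(nrow(panel), 2L)
  il <- panel[panel$gene == "IL1RL1", ]
  expect_equal(il$mean_fold_change, mean(c(15.5, 12.0, 9.38)),
               tolerance = 1e-12)
  expect_identical(il$n_probesets, 3L)
  expect_identical(il$member_probesets, "ps1;ps2;ps3")
  # sorted by descending mean fold-change
  expect_identical(panel$gene[1], "IL1RL1")
})

test_that("empty intersections, symbol fallback and direction conflicts", {
  de <- make_de_table(data.frame(
    probeset_id = c("p1", "p2", "p3"),
    gene_symbol = c("", "GX", "GX"),
    fold_change = c(5, 4, 3), direction = c("up", "up", "down"),
    p_raw = 0.001, p_adj = 0.01, significant = TRUE, passes_fc = TRUE,
    stringsAsFactors = FALSE))
  ann <- data.frame(probeset_id = c("p1", "p2", "p3"),
                    gene_symbol = c("", "GX", "GX"),
                    accession = c("AK00786", "ax", "ax"),
                    probe_class = "regular", stringsAsFactors = FALSE)
  expect_identical(nrow(build_panel(de, character(), ann)), 0L)
  expect_warning(panel <- build_panel(de, c("p1", "p2", "p3"), ann),
                 "conflicting")
  # symbol-less transcript keyed by accession; conflicted gene excluded
  expect_identical(panel$gene, "AK00786")
  expect_identical(attr(panel, "conflicts"), "GX")
})

test_that("the recovered panel equals the planted panel at low noise", {
  # planted fraction kept near the ~1% a genome-scale study shows, with
  # planted baselines clearly above the detectability threshold
  cfg <- sim_config(n_per_group = 10, noise_log2_sd = 0.1,
                    planted_de = data.frame(n_probesets = 20,
                                            fold_change = 6,
                                            direction = "up"),
                    planted_baseline_log2_mean = 7.5,
                    planted_baseline_log2_sd = 0.4, seed = 21)
  s <- simulate_expression_study(cfg)
  nm <- quantile_normalize(s$matrix)
  de <- run_differential_expression(nm, s$annotation, s$sample_sheet)
  te <- expression_threshold(s$matrix, s$annotation, s$sample_sheet)
  hi <- highly_expressed(s$matrix, s$sample_sheet, "SPB", te)
  panel <- build_panel(de, hi, s$annotation)
  expect_setequal(panel$gene, s$truth$panel_genes)
})

test_that("tightening either threshold never grows the panel", {
  s <- simulate_expression_study(sim_config(seed = 13))
  nm <- quantile_normalize(s$matrix)
  de1 <- run_differential_expression(nm, s$annotation, s$sample_sheet,
                                     threshold = 1.5)
  de2 <- run_differential_expression(nm, s$annotation, s$sample_sheet,
                                     threshold = 3.5)
  te <- expression_threshold(s$matrix, s$annotation, s$sample_sheet)
  hi1 <- highly_expressed(s$matrix, s$sample_sheet, "SPB", te)
  hi2 <- highly_expressed(s$matrix, s$sample_sheet, "SPB", te * 2)
  p11 <- build_panel(de1, hi1, s$annotation)
  p21 <- build_panel(de2, hi1, s$annotation)
  p12 <- build_panel(de1, hi2, s$annotation)
  expect_true(all(p21$gene %in% p11$gene))
  expect_true(all(p12$gene %in% p11$gene))
  # panel membership implied by its defining sets
  hitg <- de1$gene_symbol[de1$significant & de1$passes_fc]
  expect_true(all(p11$gene[p11$gene %in% de1$gene_symbol] %in% hitg))
})
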