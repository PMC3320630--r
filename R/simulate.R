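# Seeded synthetic-data generators emulating the study design: a two-group
# placental microarray experiment with spike-in controls and a reference
# probeset, category-structured GO annotation with one planted enriched term,
# qPCR calibrator dilution series, and a case/control plasma cohort.

#' Configuration for the synthetic expression study
#'
#' Defaults define the package's canonical synthetic study: 2000 probesets,
#' 8 samples per group (SPB cases vs STB controls), 20 spike-in controls
#' with no true difference, one reference probeset whose control-group
#' median signal sits at 408 linear intensity units, and 50 probesets
#' planted at a 6-fold up-regulation. Intensities follow a log-normal model:
#' log2 signal = probeset baseline ~ Normal(`baseline_log2_mean`,
#' `baseline_log2_sd`), plus per-observation noise Normal(0,
#' `noise_log2_sd`), plus log2(fold-change) in the case group for planted
#' probesets.
#'
#' @param n_probesets Number of regular probesets.
#' @param n_per_group Samples per group (cases and controls alike).
#' @param n_spike_ins Number of spike-in control probesets (zero true shift).
#' @param baseline_log2_mean,baseline_log2_sd Mean and sd of per-probeset
#'   baseline log2 intensity.
#' @param noise_log2_sd Per-observation technical noise sd on the log2 scale.
#' @param planted_de Data frame with columns `n_probesets`, `fold_change`
#'   (> 1) and `direction` (`"up"`/`"down"`): the blocks of truly
#'   differentially expressed probesets to plant.
#' @param planted_baseline_log2_mean,planted_baseline_log2_sd Baseline
#'   distribution of the planted probesets. Defaults place them in the
#'   middle of the intensity range so that their shifted case-group signals
#'   stay inside the bulk of the signal distribution: cross-array quantile
#'   normalization assumes near-identical per-array distributions, which
#'   holds in a genome-scale study where well under 1% of probesets change
#'   but must be preserved explicitly when the planted fraction is larger
#'   in a scaled-down simulation.
#' @param reference_signal Linear intensity at which the reference probe's
#'   control-group median is centred.
#' @param multiprobe_genes Named integer vector: `c("2" = 30, "3" = 10)`
#'   means 30 genes carry 2 probesets and 10 genes carry 3; all remaining
#'   regular probesets interrogate singleton genes.
#' @param frac_no_symbol Fraction of singleton probesets reported with an
#'   empty gene symbol (a transcribed locus with no approved symbol).
#' @param go_structure List controlling the simulated GO annotation:
#'   `terms_per_category` (named vector over BP/MF/CC), `genes_per_term`,
#'   `planted_term_size` and `planted_overlap` (how many of the planted
#'   term's genes are drawn from the planted up-regulated genes). The
#'   planted term is a BP term.
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_probesets = 2000,
                       n_per_group = 8,
                       n_spike_ins = 20,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       noise_log2_sd = 0.25,
                       planted_de = data.frame(n_probesets = 50,
                                               fold_change = 6,
                                               direction = "up"),
                       planted_baseline_log2_mean = 7,
                       planted_baseline_log2_sd = 1,
                       reference_signal = 408,
                       multiprobe_genes = c("2" = 30, "3" = 10),
                       frac_no_symbol = 0.05,
                       go_structure = list(
                         terms_per_category = c(BP = 30, MF = 20, CC = 20),
                         genes_per_term = 10,
                         planted_term_size = 10,
                         planted_overlap = 8),
                       seed = 1) {
  cfg <- list(n_probesets = n_probesets, n_per_group = n_per_group,
              n_spike_ins = n_spike_ins,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              noise_log2_sd = noise_log2_sd,
              planted_de = planted_de,
              planted_baseline_log2_mean = planted_baseline_log2_mean,
              planted_baseline_log2_sd = planted_baseline_log2_sd,
              reference_signal = reference_signal,
              multiprobe_genes = multiprobe_genes,
              frac_no_symbol = frac_no_symbol,
              go_structure = go_structure, seed = seed)
  if (n_probesets < 1 || n_per_group < 2 || n_spike_ins < 0)
    stop("counts must be positive (and n_per_group >= 2)", call. = FALSE)
  if (noise_log2_sd < 0 || baseline_log2_sd < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (nrow(planted_de) > 0) {
    if (any(planted_de$fold_change <= 1))
      stop("planted fold-changes must be > 1", call. = FALSE)
    if (!all(planted_de$direction %in% c("up", "down")))
      stop("planted direction must be 'up' or 'down'", call. = FALSE)
    if (sum(planted_de$n_probesets) > n_probesets)
      stop("more planted DE probesets than probesets", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-group placental expression study
#'
#' Draws a complete synthetic study from a [sim_config()]: a linear-scale
#' expression matrix (cases = SPB, controls = STB), a sample sheet, a
#' probeset annotation (regular probes, spike-ins, one reference probe), a
#' GO annotation with one planted enriched BP term, and the ground truth
#' needed for recovery tests.
#'
#' Spike-in probesets are drawn with zero true shift, so the spike-derived
#' fold-change threshold reflects technical noise only. The reference probe's
#' baseline is fixed at log2(`reference_signal`), making its control-group
#' median approximately `reference_signal` linear units.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study` with elements `matrix`
#'   ([expression_matrix()], linear scale), `sample_sheet`, `annotation`,
#'   `go`, `truth` (list: per-probeset data.frame `probes`, character
#'   vectors `panel_probesets` and `panel_genes`, `enriched_term_id`), and
#'   `config`.
#' @export
simulate_expression_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_probesets
  npg <- config$n_per_group

  reg_ids <- sprintf("PS%05d_at", seq_len(n))
  spike_ids <- if (config$n_spike_ins > 0)
    sprintf("AFFX-SPIKE-%02d_at", seq_len(config$n_spike_ins)) else character()
  ref_id <- "PSREF_at"

  # gene structure: multi-probeset genes first, then singletons
  gene_pool <- character(0)
  gi <- 0L
  for (m in names(config$multiprobe_genes)) {
    cnt <- config$multiprobe_genes[[m]]
    if (cnt == 0) next
    gs <- sprintf("GENE%04d", gi + seq_len(cnt))
    gi <- gi + cnt
    gene_pool <- c(gene_pool, rep(gs, each = as.integer(m)))
  }
  if (length(gene_pool) > n)
    stop("multiprobe_genes requires more probesets than available",
         call. = FALSE)
  n_single <- n - length(gene_pool)
  singles <- sprintf("GENE%04d", gi + seq_len(n_single))
  no_sym <- stats::rbinom(n_single, 1, config$frac_no_symbol) == 1
  singles[no_sym] <- ""
  genes <- sample(c(gene_pool, singles))  # random assignment to probesets

  ann <- data.frame(
    probeset_id = c(reg_ids, spike_ids, ref_id),
    gene_symbol = c(genes, rep("", length(spike_ids)), "PLAC4"),
    accession = c(sprintf("SIM%05d", seq_len(n)),
                  sprintf("SPIKE%02d", seq_along(spike_ids)), "SIMREF"),
    probe_class = c(rep("regular", n), rep("spike_in", length(spike_ids)),
                    "reference"),
    stringsAsFactors = FALSE)
  validate_probe_annotation(ann)

  all_ids <- ann$probeset_id
  n_all <- length(all_ids)
  baseline <- c(stats::rnorm(n, config$baseline_log2_mean,
                             config$baseline_log2_sd),
                stats::rnorm(length(spike_ids), config$baseline_log2_mean,
                             config$baseline_log2_sd),
                log2(config$reference_signal))

  shift <- numeric(n_all)
  true_dir <- rep(NA_character_, n_all)
  planted_idx <- integer(0)
  if (nrow(config$planted_de) > 0) {
    avail <- seq_len(n)
    for (b in seq_len(nrow(config$planted_de))) {
      k <- config$planted_de$n_probesets[b]
      idx <- sample(avail, k)
      avail <- setdiff(avail, idx)
      sgn <- if (config$planted_de$direction[b] == "up") 1 else -1
      shift[idx] <- sgn * log2(config$planted_de$fold_change[b])
      true_dir[idx] <- config$planted_de$direction[b]
      baseline[idx] <- stats::rnorm(k, config$planted_baseline_log2_mean,
                                    config$planted_baseline_log2_sd)
      planted_idx <- c(planted_idx, idx)
    }
  }

  samples <- c(sprintf("SPB_%02d", seq_len(npg)),
               sprintf("STB_%02d", seq_len(npg)))
  groups <- rep(c("SPB", "STB"), each = npg)
  is_case <- groups == "SPB"

  log2x <- matrix(baseline, n_all, 2 * npg) +
    outer(shift, as.numeric(is_case)) +
    matrix(stats::rnorm(n_all * 2 * npg, 0, config$noise_log2_sd),
           n_all, 2 * npg)
  dimnames(log2x) <- list(all_ids, samples)
  em <- expression_matrix(2^log2x, scale = "linear",
                          method = sprintf("simulated(seed=%d)", config$seed))

  sheet <- data.frame(
    sample_id = samples, group = groups,
    gest_week = round(ifelse(is_case, stats::runif(2 * npg, 25, 33),
                             stats::runif(2 * npg, 37, 41)), 1),
    stringsAsFactors = FALSE)

  # ground truth; panel truth = planted probesets whose noise-free case-group
  # median exceeds the reference signal
  true_case_med <- 2^(baseline + shift)
  probes <- data.frame(
    probeset_id = all_ids,
    gene_symbol = ann$gene_symbol,
    baseline_log2 = baseline,
    true_fold_change = 2^abs(shift),
    true_direction = true_dir,
    is_de = shift != 0,
    true_case_median_linear = true_case_med,
    stringsAsFactors = FALSE)
  panel_ps <- all_ids[shift != 0 & true_case_med > config$reference_signal]
  gene_label <- ifelse(nzchar(ann$gene_symbol), ann$gene_symbol,
                       ann$accession)
  panel_genes <- unique(gene_label[all_ids %in% panel_ps])

  up_genes <- unique(genes[seq_len(n) %in% planted_idx & nzchar(genes) &
                             shift[seq_len(n)] > 0])
  go <- simulate_go_annotation(
    universe = unique(genes[nzchar(genes)]),
    planted_genes = up_genes,
    structure = config$go_structure)

  structure(list(matrix = em, sample_sheet = sheet, annotation = ann,
                 go = go$annotation,
                 truth = list(probes = probes,
                              panel_probesets = panel_ps,
                              panel_genes = panel_genes,
                              enriched_term_id = go$planted_term_id),
                 config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Synthetic expression study (seed %d): %d probesets, %d vs %d samples\n",
              x$config$seed, nrow(x$matrix$intensities),
              sum(x$sample_sheet$group == "SPB"),
              sum(x$sample_sheet$group == "STB")))
  cat(sprintf("  planted DE probesets: %d; true panel genes: %d\n",
              sum(x$truth$probes$is_de), length(x$truth$panel_genes)))
  invisible(x)
}

# Internal: category-structured GO annotation with one planted enriched BP
# term whose genes overlap the planted up-regulated genes. Uses the current
# RNG stream (called from simulate_expression_study after set.seed).
simulate_go_annotation <- function(universe, planted_genes, structure) {
  tpc <- structure$terms_per_category
  gpt <- structure$genes_per_term
  rows <- list()
  planted_term_id <- NA_character_
  for (cat in c("BP", "MF", "CC")) {
    n_terms <- tpc[[cat]]
    for (t in seq_len(n_terms)) {
      tid <- sprintf("GO:%s%04d", cat, t)
      tname <- sprintf("simulated %s term %d", cat, t)
      if (cat == "BP" && t == 1L) {
        planted_term_id <- tid
        tname <- "simulated planted enriched process"
        k_in <- min(structure$planted_overlap, length(planted_genes))
        members <- c(sample(planted_genes, k_in),
                     sample(setdiff(universe, planted_genes),
                            structure$planted_term_size - k_in))
      } else {
        members <- sample(universe, min(gpt, length(universe)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_symbol = members, term_id = tid, term_name = tname,
        category = cat, stringsAsFactors = FALSE)
    }
  }
  annotation <- do.call(rbind, rows)
  validate_go_annotation(annotation)
  list(annotation = annotation, planted_term_id = planted_term_id)
}

#' Simulate a qPCR calibrator dilution series
#'
#' Generates replicate Cq values for serial 10-fold dilutions of a synthetic
#' calibrator, following the standard-curve model
#' `Cq = intercept_cq - log10(copies) / log10(1 + efficiency) + noise`.
#' With `efficiency = 1` (perfect doubling) the noise-free Cq spacing is
#' exactly `1/log10(2) = 3.3219` cycles per decade. Detection failures near
#' the bottom of the range follow a logistic dropout curve in log10 copies:
#' `P(detected) = plogis((log10(copies) - log10(mid)) / scale)`.
#'
#' @param efficiency Amplification efficiency as a fraction in (0, 1.1].
#' @param intercept_cq Cq at 1 copy per reaction.
#' @param dilution_log10_range Length-2 numeric `(lo, hi)`: calibrator levels
#'   are `10^(lo:hi)` copies per reaction.
#' @param replicates Replicates per level (>= 1).
#' @param cq_sd Replicate Cq noise sd, cycles.
#' @param dropout List with `mid_copies` (copies at 50% detection) and
#'   `scale` (logistic scale in log10 copies).
#' @param seed Integer seed.
#' @return Data frame with columns `copies`, `replicate`, `cq` (NA when the
#'   replicate dropped out) and `detected`.
#' @export
simulate_qpcr_calibration <- function(efficiency, intercept_cq = 40,
                                      dilution_log10_range = c(1, 5),
                                      replicates = 3, cq_sd = 0.2,
                                      dropout = list(mid_copies = 6.5,
                                                     scale = 0.15),
                                      seed = 1) {
  if (efficiency <= 0 || efficiency > 1.1)
    stop("efficiency must be in (0, 1.1]", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  lo <- dilution_log10_range[1]; hi <- dilution_log10_range[2]
  if (hi < lo) stop("empty dilution range", call. = FALSE)
  set.seed(seed)
  levels <- 10^seq(lo, hi, by = 1)
  df <- expand.grid(replicate = seq_len(replicates), copies = levels)[, 2:1]
  p_det <- stats::plogis((log10(df$copies) - log10(dropout$mid_copies)) /
                           dropout$scale)
  df$detected <- stats::runif(nrow(df)) < p_det
  cq <- intercept_cq - log10(df$copies) / log10(1 + efficiency) +
    stats::rnorm(nrow(df), 0, cq_sd)
  df$cq <- ifelse(df$detected, cq, NA_real_)
  df[, c("copies", "replicate", "cq", "detected")]
}

#' Simulate a case/control plasma detection cohort
#'
#' Each sample is assigned detected/undetected by an independent Bernoulli
#' draw at its group's detection probability; detected samples receive a
#' plasma concentration above the limit of detection (log-normal around
#' `mean_copies_detected`), undetected samples a concentration below it.
#' Defaults mirror a 10-case vs 27-control design with 60% vs 3.7%
#' detection.
#'
#' @param n_case,n_control Cohort sizes.
#' @param detect_prob_case,detect_prob_control Per-sample detection
#'   probabilities in `[0, 1]`.
#' @param mean_copies_detected Median copies/mL among detected samples.
#' @param lod_copies_per_ml Limit of detection, copies/mL plasma.
#' @param seed Integer seed.
#' @return List with `records` (sample_id, target, copies_per_ml, detected)
#'   and `cohort` (sample sheet: sample_id, group, gest_week).
#' @export
simulate_plasma_cohort <- function(n_case = 10, n_control = 27,
                                   detect_prob_case = 0.6,
                                   detect_prob_control = 0.037,
                                   mean_copies_detected = 200,
                                   lod_copies_per_ml = 20, seed = 1) {
  if (any(c(detect_prob_case, detect_prob_control) < 0) ||
      any(c(detect_prob_case, detect_prob_control) > 1))
    stop("detection probabilities must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  ids <- c(sprintf("PL_CASE_%02d", seq_len(n_case)),
           sprintf("PL_CTRL_%02d", seq_len(n_control)))
  grp <- rep(c("SPB", "TERM_NOLABOR"), c(n_case, n_control))
  det <- stats::runif(n_case + n_control) <
    ifelse(grp == "SPB", detect_prob_case, detect_prob_control)
  copies <- ifelse(
    det,
    pmax(lod_copies_per_ml,
         exp(stats::rnorm(length(ids), log(mean_copies_detected), 0.8))),
    stats::runif(length(ids), 0, lod_copies_per_ml * 0.99))
  cohort <- data.frame(sample_id = ids, group = grp,
                       gest_week = round(stats::runif(length(ids), 27, 33), 1),
                       stringsAsFactors = FALSE)
  records <- data.frame(sample_id = ids, target = "marker",
                        copies_per_ml = copies, detected = det,
                        stringsAsFactors = FALSE)
  list(records = records, cohort = cohort)
}

#' Simulate three-group placental concentration data
#'
#' Log-normal normalized concentrations (target/reference-gene copy ratio)
#' for the SPB / STB / TCS placental groups, with a planted fold-change in
#' the SPB group only — the "case-elevated, labor-unrelated" pattern.
#'
#' @param n_per_group Samples per group.
#' @param fold_case True SPB vs STB fold-change (STB and TCS share a null).
#' @param log2_sd Biological spread of log2 concentrations within a group.
#' @param base_concentration Median normalized concentration in STB/TCS.
#' @param seed Integer seed.
#' @return Named list of three numeric vectors (`SPB`, `STB`, `TCS`).
#' @export
simulate_group_concentrations <- function(n_per_group = 10, fold_case = 8,
                                          log2_sd = 1.2,
                                          base_concentration = 1, seed = 1) {
  set.seed(seed)
  base <- log2(base_concentration)
  list(SPB = 2^(base + log2(fold_case) +
                  stats::rnorm(n_per_group, 0, log2_sd)),
       STB = 2^(base + stats::rnorm(n_per_group, 0, log2_sd)),
       TCS = 2^(base + stats::rnorm(n_per_group, 0, log2_sd)))
}
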