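# End-to-end orchestration: simulate (or load) -> normalize -> differential
# expression -> marker panel -> GO enrichment -> qPCR calibration -> plasma
# cohort statistics, with one validated config and one seed.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with validated defaults.
#' All randomness is funnelled through `seed`. Inputs are either taken from
#' a [sim_config()] (synthetic study, the default) or read from the file
#' paths in `paths` (expression TSV, sample CSV, probe TSV, GO TSV).
#'
#' @param sim A [sim_config()] describing the synthetic study, or `NULL`
#'   when `paths` supplies real files.
#' @param paths Optional named list: `expression`, `samples`, `probes`,
#'   `go`.
#' @param alpha Significance level for adjusted p-values.
#' @param fdr_alpha FDR level for GO enrichment.
#' @param t_fc Explicit fold-change threshold, or `NULL` to derive it from
#'   the spike-ins.
#' @param case_group,control_group Expression contrast groups.
#' @param reference_group Group defining the expression threshold `T_expr`.
#' @param qpcr List of qPCR simulation/quantification constants:
#'   `efficiency`, `intercept_cq`, `replicates`, `cq_sd`, and the volume
#'   constants `elution_ul`, `rt_input_ul`, `plasma_ml` (1.6 mL plasma
#'   processed per sample by default).
#' @param cohort List passed to [simulate_plasma_cohort()] (sizes and
#'   detection probabilities).
#' @param seed Integer master seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            alpha = 0.05, fdr_alpha = 0.05, t_fc = NULL,
                            case_group = "SPB", control_group = "STB",
                            reference_group = "STB",
                            qpcr = list(efficiency = 0.95, intercept_cq = 40,
                                        replicates = 20, cq_sd = 0.25,
                                        elution_ul = 50, rt_input_ul = 10,
                                        plasma_ml = 1.6),
                            cohort = list(n_case = 10, n_control = 27,
                                          detect_prob_case = 0.6,
                                          detect_prob_control = 0.037),
                            seed = 1) {
  if (is.null(sim) && is.null(paths))
    stop("either a sim_config or input paths must be given", call. = FALSE)
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    stop("'sim' must be a sim_config", call. = FALSE)
  if (!is.null(paths)) {
    need <- c("expression", "samples", "probes", "go")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop("paths must name: ", paste(miss, collapse = ", "), call. = FALSE)
    gone <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(gone))
      stop("input file(s) not found: ", paste(gone, collapse = ", "),
           call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || fdr_alpha <= 0 || fdr_alpha >= 1)
    stop("alpha levels must lie in (0, 1)", call. = FALSE)
  if (!is.null(t_fc) && t_fc <= 1)
    stop("an explicit fold-change threshold must exceed 1", call. = FALSE)
  structure(list(sim = sim, paths = paths, alpha = alpha,
                 fdr_alpha = fdr_alpha, t_fc = t_fc,
                 case_group = case_group, control_group = control_group,
                 reference_group = reference_group, qpcr = qpcr,
                 cohort = cohort, seed = seed),
            class = "pipeline_config")
}

#' Run the full marker-discovery pipeline
#'
#' Executes every stage in order on one config: data acquisition
#' (simulation or file input), quantile normalization, spike-in threshold
#' derivation, differential expression, the highly-expressed/aberrantly-
#' expressed intersection panel, GO over-representation of the up- and
#' down-regulated gene lists, qPCR calibration with LOD estimation, and the
#' plasma cohort detection test. Every stage's result is returned; the
#' printed report summarizes the counts and derived thresholds. With a
#' fixed seed the whole run is deterministic.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements `data`,
#'   `normalized`, `threshold`, `de`, `t_expr`, `highly`, `panel`,
#'   `enrichment_up`, `enrichment_down`, `calibration`, `cohort`,
#'   `detection`, and `report` (named numeric summary).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  data <- stage("input", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- config$seed
      simulate_expression_study(sim)
    } else {
      list(matrix = read_expression_matrix(config$paths$expression),
           sample_sheet = read_sample_sheet(config$paths$samples),
           annotation = read_probe_annotation(config$paths$probes),
           go = read_go_annotation(config$paths$go),
           truth = NULL)
    }
  })

  normalized <- stage("normalize", quantile_normalize(data$matrix))
  threshold <- stage("spike_threshold", {
    if (!is.null(config$t_fc)) config$t_fc
    else derive_spike_threshold(normalized, data$annotation,
                                data$sample_sheet, config$case_group,
                                config$control_group)
  })
  de <- stage("diffexpr",
    run_differential_expression(normalized, data$annotation,
                                data$sample_sheet, config$case_group,
                                config$control_group, alpha = config$alpha,
                                threshold = threshold))
  t_expr <- stage("expression_threshold",
    expression_threshold(data$matrix, data$annotation, data$sample_sheet,
                         config$reference_group))
  highly <- stage("highly_expressed",
    highly_expressed(data$matrix, data$sample_sheet, config$case_group,
                     t_expr))
  panel <- stage("panel", build_panel(de, highly, data$annotation))

  background <- unique(data$annotation$gene_symbol[
    data$annotation$probe_class == "regular" &
      nzchar(data$annotation$gene_symbol)])
  hit <- de[de$significant & de$passes_fc, ]
  enrich_one <- function(dir) {
    genes <- unique(hit$gene_symbol[hit$direction == dir &
                                      nzchar(hit$gene_symbol)])
    if (length(genes) == 0) return(NULL)
    enrich_gene_list(genes, data$go, background,
                     alpha_fdr = config$fdr_alpha)
  }
  enrichment_up <- stage("enrich", enrich_one("up"))
  enrichment_down <- stage("enrich", enrich_one("down"))

  calibration <- stage("qpcr_calibrate", {
    cal <- simulate_qpcr_calibration(
      efficiency = config$qpcr$efficiency,
      intercept_cq = config$qpcr$intercept_cq,
      replicates = config$qpcr$replicates, cq_sd = config$qpcr$cq_sd,
      seed = config$seed + 1L)
    fit_calibration(cal, assay_id = "marker")
  })

  cohort <- stage("plasma_cohort", do.call(simulate_plasma_cohort,
    c(config$cohort, list(seed = config$seed + 2L))))
  detection <- stage("plasma_test", {
    det <- cohort$records$detected
    case <- cohort$cohort$group == config$case_group
    detection_table(sum(det & case), sum(!det & case),
                    sum(det & !case), sum(!det & !case))
  })

  report <- c(n_probesets = nrow(de),
              t_fc = if (inherits(threshold, "spike_threshold"))
                threshold$t_fc else threshold,
              t_expr = t_expr,
              n_significant = sum(de$significant),
              n_changed = sum(de$significant & de$passes_fc),
              n_highly_expressed = length(highly),
              panel_probesets = if (nrow(panel)) sum(panel$n_probesets) else 0L,
              panel_genes = nrow(panel),
              n_enriched_up = if (is.null(enrichment_up)) 0L
                else sum(enrichment_up$enriched),
              n_enriched_down = if (is.null(enrichment_down)) 0L
                else sum(enrichment_down$enriched),
              qpcr_efficiency = calibration$efficiency,
              lod_copies = if (is.null(calibration$lod)) NA_real_
                else calibration$lod$lod,
              detection_p = detection$p_two_sided,
              detection_rate_ratio = detection$rate_ratio)

  structure(list(data = data, normalized = normalized, threshold = threshold,
                 de = de, t_expr = t_expr, highly = highly, panel = panel,
                 enrichment_up = enrichment_up,
                 enrichment_down = enrichment_down,
                 calibration = calibration, cohort = cohort,
                 detection = detection, report = report,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("Marker-discovery pipeline report\n")
  cat(sprintf("  probesets tested: %d; T_fc = %.3f; T_expr = %.1f\n",
              as.integer(r["n_probesets"]), r["t_fc"], r["t_expr"]))
  cat(sprintf("  significant: %d; significant & > T_fc: %d; highly expressed: %d\n",
              as.integer(r["n_significant"]), as.integer(r["n_changed"]),
              as.integer(r["n_highly_expressed"])))
  cat(sprintf("  panel: %d gene(s) from %d probeset(s)\n",
              as.integer(r["panel_genes"]), as.integer(r["panel_probesets"])))
  cat(sprintf("  enriched GO terms (FDR < %g): %d up, %d down\n",
              x$config$fdr_alpha, as.integer(r["n_enriched_up"]),
              as.integer(r["n_enriched_down"])))
  cat(sprintf("  qPCR: efficiency %.3f, LOD %g copies\n",
              r["qpcr_efficiency"], r["lod_copies"]))
  cat(sprintf("  plasma detection: Fisher p = %.3g, rate ratio = %.3g\n",
              r["detection_p"], r["detection_rate_ratio"]))
  invisible(x)
}
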