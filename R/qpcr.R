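# MIQE-style RT-qPCR absolute quantification: calibration-curve fitting,
# amplification efficiency, empirical 95%-detection limit of detection,
# copies-per-reaction / copies-per-mL conversion, and detection calls.

#' Fit a qPCR calibration curve from a dilution series
#'
#' Least-squares fit of `Cq = m * log10(copies) + b` over the detected
#' calibrator replicates. The amplification efficiency is
#' `E = 10^(-1/m) - 1` (E = 1 is perfect doubling, slope -3.3219 cycles per
#' decade). The dynamic range is the span of calibrator levels with >= 95%
#' replicate detection. If enough replicates are available at the limiting
#' level, the empirical limit of detection and its Cq spread are attached
#' via [estimate_lod()].
#'
#' @param dilutions Data frame with columns `copies` and `cq` (NA = the
#'   replicate was not detected); an optional logical `detected` column
#'   overrides the NA rule. At least 3 distinct concentrations spanning
#'   >= 2 log10 decades are required.
#' @param assay_id Optional assay label carried through to the printout.
#' @return Object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `dynamic_range` (copies),
#'   `lod` (list with `lod`, `cq_mean`, `cq_sd`, or NULL when no level
#'   reaches 95% detection), `n_points`, `assay_id`.
#' @examples
#' d <- data.frame(copies = c(10, 100, 1000), cq = c(36.68, 33.36, 30.04))
#' fit_calibration(d)
#' @export
fit_calibration <- function(dilutions, assay_id = "assay") {
  need <- c("copies", "cq")
  if (!all(need %in% names(dilutions)))
    stop("dilutions need columns 'copies' and 'cq'", call. = FALSE)
  det <- if ("detected" %in% names(dilutions)) dilutions$detected
         else !is.na(dilutions$cq)
  obs <- dilutions[det & !is.na(dilutions$cq), , drop = FALSE]
  lv <- sort(unique(dilutions$copies))
  if (length(unique(obs$copies)) < 3)
    stop("at least 3 distinct calibrator concentrations are required",
         call. = FALSE)
  if (diff(range(log10(obs$copies))) < 2)
    stop("calibrators must span at least 2 log10 decades", call. = FALSE)
  fit <- stats::lm(cq ~ log10(copies), data = obs)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (m >= 0)
    stop("non-negative slope: assay failure (Cq must fall as input rises)",
         call. = FALSE)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noise-free fits are exact
  det_frac <- tapply(det, dilutions$copies, mean)
  ok <- as.numeric(names(det_frac))[det_frac >= 0.95]
  dr <- if (length(ok)) range(ok) else c(NA_real_, NA_real_)
  lod <- tryCatch(estimate_lod(dilutions), error = function(e) NULL)
  structure(list(assay_id = assay_id, slope = m, intercept = b,
                 r_squared = r2, efficiency = 10^(-1 / m) - 1,
                 dynamic_range = dr, lod = lod, n_points = nrow(obs),
                 levels = lv),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("qPCR calibration '%s' (%d detected points)\n", x$assay_id,
              x$n_points))
  cat(sprintf("  Cq = %.4f * log10(copies) + %.4f   (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  efficiency = %.3f; dynamic range = [%g, %g] copies\n",
              x$efficiency, x$dynamic_range[1], x$dynamic_range[2]))
  if (!is.null(x$lod))
    cat(sprintf("  LOD = %g copies (Cq %.1f +/- %.3f at LOD)\n",
                x$lod$lod, x$lod$cq_mean, x$lod$cq_sd))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted Cq for given input copies
#' @param object A `calibration_curve`.
#' @param copies Copies per reaction.
#' @param ... Unused.
#' @return Expected Cq values.
#' @export
predict.calibration_curve <- function(object, copies, ...) {
  object$slope * log10(copies) + object$intercept
}

#' @export
plot.calibration_curve <- function(x, ...) {
  cp <- 10^seq(log10(min(x$levels)), log10(max(x$levels)), length.out = 50)
  graphics::plot(log10(cp), predict(x, cp), type = "l",
                 xlab = "log10 copies/reaction", ylab = "Cq",
                 main = sprintf("%s: E = %.2f, R^2 = %.3f", x$assay_id,
                                x$efficiency, x$r_squared), ...)
  invisible(x)
}

#' Absolute quantification from a Cq value
#'
#' Inverts the calibration curve, `copies = 10^((cq - b) / m)`, and scales
#' the per-reaction copy number to the sample compartment: for plasma,
#' `copies/mL = copies/reaction * (elution_ul / rt_input_ul) / plasma_ml`;
#' for tissue RNA, `copies/ng = copies/reaction * (elution_ul /
#' rt_input_ul) / rna_ng`. Replicate Cq values are aggregated by their mean
#' before inversion. A missing/undetermined Cq yields zero copies and a
#' negative detection call. When replicate scatter exceeds `cq_sd_cap`
#' times the curve's Cq sd at LOD, the result is flagged indeterminate.
#'
#' @param cq Numeric vector of replicate Cq values (NA = undetermined).
#' @param curve A [fit_calibration()] result.
#' @param volumes List with `elution_ul` and `rt_input_ul`, plus either
#'   `plasma_ml` or `rna_ng` depending on the sample type.
#' @param sample_id,target Labels carried into the result.
#' @param cq_sd_cap Replicate-quality multiplier (default 3).
#' @return List of class `quant_result`: `sample_id`, `target`,
#'   `replicate_cqs`, `mean_cq`, `copies_per_reaction`, `copies_per_ml`
#'   and/or `copies_per_ng` (NA when the matching volume is absent),
#'   `indeterminate`.
#' @examples
#' d <- data.frame(copies = c(10, 100, 1000), cq = c(36.68, 33.36, 30.04))
#' cv <- fit_calibration(d)
#' quantify(33.36, cv, volumes = list(elution_ul = 50, rt_input_ul = 10,
#'                                    plasma_ml = 1.6))
#' @export
quantify <- function(cq, curve, volumes, sample_id = NA_character_,
                     target = NA_character_, cq_sd_cap = 3) {
  stopifnot(inherits(curve, "calibration_curve"))
  cq_ok <- cq[!is.na(cq)]
  if (length(cq_ok) == 0) {
    mean_cq <- NA_real_
    copies <- 0
  } else {
    mean_cq <- mean(cq_ok)
    copies <- 10^((mean_cq - curve$intercept) / curve$slope)
  }
  scale <- volumes$elution_ul / volumes$rt_input_ul
  per_ml <- if (!is.null(volumes$plasma_ml))
    copies * scale / volumes$plasma_ml else NA_real_
  per_ng <- if (!is.null(volumes$rna_ng))
    copies * scale / volumes$rna_ng else NA_real_
  indet <- FALSE
  if (length(cq_ok) >= 2 && !is.null(curve$lod) &&
      is.finite(curve$lod$cq_sd) && curve$lod$cq_sd > 0)
    indet <- stats::sd(cq_ok) > cq_sd_cap * curve$lod$cq_sd
  structure(list(sample_id = sample_id, target = target,
                 replicate_cqs = cq, mean_cq = mean_cq,
                 copies_per_reaction = copies, copies_per_ml = per_ml,
                 copies_per_ng = per_ng, indeterminate = indet),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("%s / %s: mean Cq %.2f -> %.3g copies/reaction",
              x$sample_id, x$target, x$mean_cq, x$copies_per_reaction))
  if (!is.na(x$copies_per_ml))
    cat(sprintf(" (%.3g copies/mL plasma)", x$copies_per_ml))
  if (!is.na(x$copies_per_ng))
    cat(sprintf(" (%.3g copies/ng RNA)", x$copies_per_ng))
  if (x$indeterminate) cat(" [indeterminate: replicate scatter]")
  cat("\n")
  invisible(x)
}

#' Empirical limit of detection by the 95%-detection rule
#'
#' The LOD is the lowest tested concentration at which at least 95% of
#' replicates are detected; twenty or more replicates at the candidate LOD
#' are recommended for a stable estimate. The mean and sd of Cq over the
#' detected replicates at that level are reported alongside.
#'
#' @param records Data frame with columns `copies` and `cq` (NA = not
#'   detected; an optional logical `detected` column overrides), covering
#'   at least 2 concentrations.
#' @return List with `lod` (copies), `cq_mean`, `cq_sd`, `detection_rates`
#'   (named vector per level).
#' @examples
#' rec <- data.frame(copies = rep(c(10, 20, 100), each = 20),
#'                   cq = c(ifelse(runif(20) < 0.8, 38, NA), rep(38, 40)))
#' @export
estimate_lod <- function(records) {
  if (!all(c("copies", "cq") %in% names(records)))
    stop("records need columns 'copies' and 'cq'", call. = FALSE)
  det <- if ("detected" %in% names(records)) records$detected
         else !is.na(records$cq)
  lv <- sort(unique(records$copies))
  if (length(lv) < 2)
    stop("at least 2 concentrations are required", call. = FALSE)
  rates <- vapply(lv, function(l) mean(det[records$copies == l]), numeric(1))
  names(rates) <- as.character(lv)
  ok <- lv[rates >= 0.95]
  if (!length(ok))
    stop(sprintf("no level reaches 95%% detection (best: %.0f%% at %g copies)",
                 100 * max(rates), lv[which.max(rates)]), call. = FALSE)
  lod <- min(ok)
  at <- records$copies == lod & det & !is.na(records$cq)
  list(lod = lod, cq_mean = mean(records$cq[at]),
       cq_sd = stats::sd(records$cq[at]), detection_rates = rates)
}

#' Detection call against the limit of detection
#'
#' A sample is called detected when its estimated concentration is at least
#' the LOD (a sample exactly at the LOD is positive). The comparison is
#' made in the units matching the sample type: `copies_per_ml` for plasma,
#' `copies_per_ng` for tissue; mixing units is an error. Indeterminate
#' quantifications return `NA`.
#'
#' @param result A [quantify()] result.
#' @param lod Limit of detection, in the units named by `units`.
#' @param units `"per_ml"` or `"per_ng"`.
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate).
#' @export
call_detection <- function(result, lod, units = c("per_ml", "per_ng")) {
  stopifnot(inherits(result, "quant_result"))
  units <- match.arg(units)
  value <- switch(units, per_ml = result$copies_per_ml,
                  per_ng = result$copies_per_ng)
  if (is.na(value))
    stop("quantification has no ", units,
         " value; was the matching volume supplied?", call. = FALSE)
  if (isTRUE(result$indeterminate)) return(NA)
  value >= lod
}
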