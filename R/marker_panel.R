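# Plasma-candidate marker panel: intersect "aberrantly expressed" with
# "highly expressed" probesets, anchored to the reference transcript, and
# collapse to the gene level.

#' Expression threshold anchored to the reference transcript
#'
#' The plasma-detectability threshold `T_expr` is the median linear signal
#' of the reference-class probeset (the PLAC4-like anchor, a transcript
#' known to be detectable in maternal plasma despite modest placental
#' expression) across the reference-group samples. Probesets above it are
#' plausibly detectable in plasma.
#'
#' @param em Linear-scale [expression_matrix()] of raw signals.
#' @param annotation Probe annotation with exactly one reference-class
#'   probeset.
#' @param sample_sheet Sample sheet data.frame.
#' @param reference_group Group whose samples define the median
#'   (default `"STB"`).
#' @return `T_expr`, a single linear intensity value.
#' @export
expression_threshold <- function(em, annotation, sample_sheet,
                                 reference_group = "STB") {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "linear")
    stop("expression_threshold works on the linear-scale matrix",
         call. = FALSE)
  validate_probe_annotation(annotation)
  ref <- annotation$probeset_id[annotation$probe_class == "reference"]
  if (length(ref) != 1 || !ref %in% probeset_ids(em))
    stop("exactly one reference-class probeset must be present in the matrix",
         call. = FALSE)
  samp <- sample_sheet$sample_id[sample_sheet$group == reference_group]
  if (length(samp) == 0)
    stop("reference group '", reference_group, "' has no samples",
         call. = FALSE)
  stats::median(em$intensities[ref, samp])
}

#' Probesets highly expressed in the case group
#'
#' Returns the ids of probesets whose median linear signal across the
#' case-group samples is strictly greater than the threshold `T_expr`; a
#' probeset sitting exactly at the threshold is excluded.
#'
#' @param em Linear-scale [expression_matrix()].
#' @param sample_sheet Sample sheet data.frame.
#' @param case_group Group defining the medians (default `"SPB"`).
#' @param t_expr Linear intensity threshold, typically from
#'   [expression_threshold()].
#' @return Character vector of probeset ids.
#' @export
highly_expressed <- function(em, sample_sheet, case_group = "SPB", t_expr) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "linear")
    stop("highly_expressed works on the linear-scale matrix", call. = FALSE)
  samp <- sample_sheet$sample_id[sample_sheet$group == case_group]
  if (length(samp) == 0)
    stop("case group '", case_group, "' has no samples", call. = FALSE)
  med <- apply(em$intensities[, samp, drop = FALSE], 1, stats::median)
  names(med)[med > t_expr]
}

#' Build the gene-level plasma-candidate panel
#'
#' Selects probesets that are aberrantly expressed (significant after
#' multiple-testing adjustment and above the fold-change threshold) and
#' highly expressed (member of `highly`), then collapses them by gene
#' symbol — falling back to the accession for transcripts with no approved
#' symbol. The intersection happens at the probeset level first; a probeset
#' must itself satisfy both criteria to carry its gene into the panel.
#' Multi-probeset genes report the arithmetic mean of their member
#' fold-change magnitudes. Genes whose member probesets disagree in
#' direction are excluded and returned in the `conflicts` attribute with a
#' warning.
#'
#' @param de A `de_table` from [run_differential_expression()].
#' @param highly Character vector of highly expressed probeset ids from
#'   [highly_expressed()].
#' @param annotation Probe annotation data.frame (supplies accessions for
#'   symbol-less transcripts).
#' @return Data frame of class `marker_panel`, sorted by descending
#'   `mean_fold_change`, with columns `gene`, `member_probesets`
#'   (semicolon-joined), `n_probesets`, `mean_fold_change`, `direction`.
#' @export
build_panel <- function(de, highly, annotation) {
  stopifnot(inherits(de, "de_table"))
  validate_probe_annotation(annotation)
  sel <- de[de$significant & de$passes_fc & de$probeset_id %in% highly, ,
            drop = FALSE]
  empty <- data.frame(gene = character(), member_probesets = character(),
                      n_probesets = integer(), mean_fold_change = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  if (nrow(sel) == 0)
    return(structure(empty, class = c("marker_panel", "data.frame"),
                     conflicts = character()))

  acc <- annotation$accession[match(sel$probeset_id, annotation$probeset_id)]
  gene <- ifelse(nzchar(sel$gene_symbol) & !is.na(sel$gene_symbol),
                 sel$gene_symbol, acc)
  parts <- split(sel, gene)
  rows <- lapply(names(parts), function(g) {
    p <- parts[[g]]
    if (length(unique(p$direction)) > 1) return(NULL)
    data.frame(gene = g,
               member_probesets = paste(p$probeset_id, collapse = ";"),
               n_probesets = nrow(p),
               mean_fold_change = mean(p$fold_change),
               direction = p$direction[1], stringsAsFactors = FALSE)
  })
  conflicts <- names(parts)[vapply(rows, is.null, logical(1))]
  if (length(conflicts))
    warning("gene(s) with conflicting probeset directions excluded: ",
            paste(conflicts, collapse = ", "), call. = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(-out$mean_fold_change), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("marker_panel", "data.frame"),
            conflicts = conflicts)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("Plasma-candidate marker panel: %d gene(s) from %d probeset(s)\n",
              nrow(x), if (nrow(x)) sum(x$n_probesets) else 0L))
  if (nrow(x)) print.data.frame(x, digits = 4, row.names = FALSE)
  confl <- attr(x, "conflicts")
  if (length(confl))
    cat("Excluded for direction conflict:", paste(confl, collapse = ", "),
        "\n")
  invisible(x)
}
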