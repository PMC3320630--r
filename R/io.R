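# Readers/writers for the plain-text formats the pipeline touches.
# Matrices and annotations travel as TSV, sample/cohort sheets as CSV;
# UTF-8, '.' decimal separator throughout.

#' Read an expression matrix from TSV
#'
#' Expects a header line `probeset_id<TAB>sample1<TAB>...` and one row per
#' probeset. Lines starting with `#` (provenance comments written by
#' [write_expression_matrix()]) are skipped.
#'
#' @param path Path to a tab-separated file.
#' @param scale Scale the stored values are on; raw signal files are linear.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = "linear") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (names(df)[1] != "probeset_id")
    stop("first column of an expression TSV must be 'probeset_id'",
         call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated probeset id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at probeset '%s', sample '%s'",
                 ids[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(vals))
  expression_matrix(num, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expr_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(em$method))
    writeLines(paste0("# method=", em$method), con)
  writeLines(paste(c("probeset_id", sample_ids(em)), collapse = "\t"), con)
  body <- apply(em$intensities, 1, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(probeset_ids(em), body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' Columns: `sample_id,group,gest_week`. Groups must come from the closed
#' set SPB / STB / TCS / TERM_NOLABOR.
#'
#' @param path Path to a CSV file.
#' @return A validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  validate_sample_sheet(df)
  df
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read probeset annotation from TSV
#'
#' Columns: `probeset_id, gene_symbol, accession, probe_class`. An empty
#' gene symbol encodes a transcribed locus with no approved symbol. At most
#' one probeset may carry class `reference` (the plasma-detectability
#' anchor); spike-in probes carry no gene symbol.
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  validate_probe_annotation(df)
  df
}

#' @rdname read_probe_annotation
#' @param ann Probe annotation data.frame.
#' @export
write_probe_annotation <- function(ann, path) {
  validate_probe_annotation(ann)
  utils::write.table(ann, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene-to-GO-term annotation from TSV
#'
#' Columns: `gene_symbol, term_id, term_name, category` with category one of
#' BP / MF / CC; (gene, term) pairs must be unique. The annotation is taken
#' flat, with no ancestor-term propagation.
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame.
#' @export
read_go_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  validate_go_annotation(df)
  df
}

#' @rdname read_go_annotation
#' @param go GO annotation data.frame.
#' @export
write_go_annotation <- function(go, path) {
  validate_go_annotation(go)
  utils::write.table(go, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
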