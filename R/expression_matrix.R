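#' Construct a probeset-by-sample expression matrix
#'
#' The central container of the pipeline: a numeric matrix of microarray
#' signals with probesets in rows and samples in columns, tagged with the
#' scale the values live on. Raw signals are linear "intensity units"; the
#' normalization stage returns a log2-scale matrix.
#'
#' @param intensities Numeric matrix with unique, non-empty rownames
#'   (probeset ids) and colnames (sample ids).
#' @param scale Either `"linear"` or `"log2"`.
#' @param method Optional provenance note (character) recording how the
#'   values were produced, e.g. `"quantile+log2(x+1)"`.
#' @return An object of class `expr_matrix`: a list with elements
#'   `intensities`, `scale` and `method`.
#' @examples
#' m <- matrix(c(2, 4, 6, 3, 5, 7), nrow = 3,
#'             dimnames = list(paste0("PS", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m)
#' dim(em)
#' @export
expression_matrix <- function(intensities, scale = c("linear", "log2"),
                              method = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix", call. = FALSE)
  rn <- rownames(intensities)
  cn <- colnames(intensities)
  if (is.null(rn) || is.null(cn))
    stop("expression matrix needs probeset ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rn))
    stop("duplicated probeset id(s): ",
         paste(unique(rn[duplicated(rn)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(cn))
    stop("duplicated sample id(s): ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "), call. = FALSE)
  if (anyNA(intensities))
    stop("expression matrix contains missing values", call. = FALSE)
  if (scale == "linear" && any(intensities < 0))
    stop("negative intensities are not allowed on the linear scale",
         call. = FALSE)
  structure(list(intensities = intensities, scale = scale, method = method),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$intensities)

#' Probeset ids of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of probeset ids.
#' @export
probeset_ids <- function(x) rownames(x$intensities)

#' Sample ids of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$intensities)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d probesets x %d samples (%s scale)\n",
              nrow(x$intensities), ncol(x$intensities), x$scale))
  if (!is.null(x$method)) cat("  method:", x$method, "\n")
  invisible(x)
}

# Internal: check a sample sheet data.frame against the closed group set and
# (optionally) the samples of a matrix.
VALID_GROUPS <- c("SPB", "STB", "TCS", "TERM_NOLABOR")

validate_sample_sheet <- function(sheet, em = NULL) {
  need <- c("sample_id", "group", "gest_week")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample id(s) in sample sheet", call. = FALSE)
  bad <- setdiff(unique(sheet$group), VALID_GROUPS)
  if (length(bad))
    stop("unknown group(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(VALID_GROUPS, collapse = ", "),
         call. = FALSE)
  if (!is.null(em)) {
    missing_ids <- setdiff(sample_ids(em), sheet$sample_id)
    if (length(missing_ids))
      stop("sample(s) in matrix absent from sheet: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  invisible(sheet)
}

VALID_PROBE_CLASSES <- c("regular", "spike_in", "reference")

validate_probe_annotation <- function(ann) {
  need <- c("probeset_id", "gene_symbol", "accession", "probe_class")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("probe annotation is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$probeset_id))
    stop("duplicated probeset id(s) in annotation", call. = FALSE)
  bad <- setdiff(unique(ann$probe_class), VALID_PROBE_CLASSES)
  if (length(bad))
    stop("unknown probe class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (sum(ann$probe_class == "reference") > 1)
    stop("more than one reference-class probeset; exactly one is allowed",
         call. = FALSE)
  spikes <- ann$probe_class == "spike_in"
  if (any(spikes & !is.na(ann$gene_symbol) & nzchar(ann$gene_symbol)))
    stop("spike-in probesets must not carry a gene symbol", call. = FALSE)
  invisible(ann)
}

VALID_GO_CATEGORIES <- c("BP", "MF", "CC")

validate_go_annotation <- function(go) {
  need <- c("gene_symbol", "term_id", "term_name", "category")
  miss <- setdiff(need, names(go))
  if (length(miss))
    stop("GO annotation is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(go$category), VALID_GO_CATEGORIES)
  if (length(bad))
    stop("unknown GO category: ", paste(bad, collapse = ", "),
         "; expected BP, MF or CC", call. = FALSE)
  if (anyDuplicated(go[, c("gene_symbol", "term_id")]))
    stop("duplicated (gene, term) pair(s) in GO annotation", call. = FALSE)
  invisible(go)
}
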