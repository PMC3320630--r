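# Gene-ontology over-representation: fold of enrichment, EASE-style
# modified Fisher exact test, and within-category FDR control.

#' Fold of enrichment of a term in a gene list
#'
#' The ratio between a term's frequency in the gene list and its frequency
#' in the background: `(k/n) / (K/N)`, where `k` of the `n` list genes and
#' `K` of the `N` background genes carry the term. Scale-invariant:
#' multiplying both pairs by a common factor leaves it unchanged.
#'
#' @param k Genes in the list annotated with the term.
#' @param n List size.
#' @param K Background genes annotated with the term.
#' @param N Background size.
#' @return The fold of enrichment.
#' @examples
#' fold_enrichment(4, 148, 15, 14116)   # 25.4
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (n <= 0 || K <= 0 || N <= 0)
    stop("n, K and N must be positive", call. = FALSE)
  if (k > n || K > N || k < 0)
    stop("counts must satisfy 0 <= k <= n and K <= N", call. = FALSE)
  (k / n) / (K / N)
}

#' EASE-style modified Fisher exact test for over-representation
#'
#' One-sided upper-tail hypergeometric probability of seeing at least `k`
#' list genes with the term given the 2x2 margins (n, N-n) x (K, N-K). The
#' default EASE variant penalizes small overlaps by removing one gene from
#' the overlap before computing the tail, `P[X >= k-1]`, so single-gene
#' overlaps (`k = 1`) are never significant (p = 1). The classic
#' (unpenalized) hypergeometric tail `P[X >= k]` is available via
#' `variant = "classic"`.
#'
#' @param k,n,K,N Counts as in [fold_enrichment()]; `k >= 1` for a
#'   meaningful test, `k = 0` returns 1 by convention.
#' @param variant `"ease"` (default) or `"classic"`.
#' @return One-sided p-value in (0, 1].
#' @examples
#' ease_p(3, 4, 3, 8, variant = "classic")  # 5/70
#' ease_p(1, 10, 5, 100)                    # 1: EASE penalization
#' @export
ease_p <- function(k, n, K, N, variant = c("ease", "classic")) {
  variant <- match.arg(variant)
  if (n <= 0 || K <= 0 || N <= 0 || k > n || K > N)
    stop("invalid counts", call. = FALSE)
  if (k == 0) return(1)
  k_eff <- if (variant == "ease") k - 1 else k
  # P[X >= k_eff], X ~ Hypergeometric(N balls, K white, n drawn)
  if (k_eff <= 0) return(1)
  stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO over-representation analysis of a gene list
#'
#' For each GO category (BP, MF, CC) independently: the effective list size
#' `n` is the number of list genes carrying at least one term of that
#' category, and the effective background `N` is likewise
#' category-specific — so the totals differ across categories, as they do
#' when a fraction of genes lacks annotation in a category. For every term,
#' the overlap `k`, background count `K`, fold of enrichment, modified
#' Fisher p and Benjamini-Hochberg FDR (within category) are reported,
#' sorted by descending fold of enrichment. Terms absent from the
#' background (`K = 0`) are skipped with a warning. The annotation is used
#' flat, with no ancestor-term propagation.
#'
#' @param list_genes Character vector of gene symbols (must be a subset of
#'   `background_genes`).
#' @param annotation GO annotation data.frame (see [read_go_annotation()]).
#' @param background_genes Character vector: all genes interrogated by the
#'   array.
#' @param alpha_fdr FDR level used for the `enriched` flag (default 0.05).
#' @param variant Test variant passed to [ease_p()].
#' @return Data frame of class `enrichment_table` with columns `term_id`,
#'   `term_name`, `category`, `k`, `n`, `K`, `N`, `fold_enrichment`, `p`,
#'   `fdr`, `enriched`, `member_genes` (semicolon-joined).
#' @export
enrich_gene_list <- function(list_genes, annotation, background_genes,
                             alpha_fdr = 0.05,
                             variant = c("ease", "classic")) {
  variant <- match.arg(variant)
  validate_go_annotation(annotation)
  list_genes <- unique(list_genes)
  background_genes <- unique(background_genes)
  extra <- setdiff(list_genes, background_genes)
  if (length(extra))
    stop("list genes absent from background: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  ann <- annotation[annotation$gene_symbol %in% background_genes, ,
                    drop = FALSE]

  out <- list()
  for (cat in VALID_GO_CATEGORIES) {
    ac <- ann[ann$category == cat, , drop = FALSE]
    if (nrow(ac) == 0) next
    genes_with_cat <- unique(ac$gene_symbol)
    n <- length(intersect(list_genes, genes_with_cat))
    N <- length(genes_with_cat)
    if (n == 0 || N == 0) next
    terms <- split(ac$gene_symbol, ac$term_id)
    recs <- lapply(names(terms), function(tid) {
      members_bg <- unique(terms[[tid]])
      K <- length(members_bg)
      members <- intersect(list_genes, members_bg)
      k <- length(members)
      data.frame(term_id = tid,
                 term_name = ac$term_name[match(tid, ac$term_id)],
                 category = cat, k = k, n = n, K = K, N = N,
                 fold_enrichment = fold_enrichment(k, n, K, N),
                 p = ease_p(k, n, K, N, variant = variant),
                 member_genes = paste(sort(members), collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, recs)
    tab$fdr <- benjamini_hochberg(tab$p)
    out[[cat]] <- tab
  }
  if (!length(out))
    stop("no annotated category overlaps the background", call. = FALSE)
  res <- do.call(rbind, out)
  res$enriched <- res$fdr < alpha_fdr
  res <- res[order(-res$fold_enrichment, res$p),
             c("term_id", "term_name", "category", "k", "n", "K", "N",
               "fold_enrichment", "p", "fdr", "enriched", "member_genes")]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_table", "data.frame"),
            alpha_fdr = alpha_fdr, variant = variant)
}

#' @export
print.enrichment_table <- function(x, n = 10, ...) {
  cat(sprintf("GO over-representation (%s variant): %d terms tested, %d enriched at FDR < %g\n",
              attr(x, "variant"), nrow(x), sum(x$enriched),
              attr(x, "alpha_fdr")))
  cols <- c("term_id", "category", "k", "n", "K", "N", "fold_enrichment",
            "p", "fdr")
  print.data.frame(utils::head(x[, cols], n), digits = 3, row.names = FALSE)
  invisible(x)
}
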