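#' Fisher exact functional enrichment of a gene cluster
#'
#' For every (annotation level, category) represented in the cluster,
#' builds the 2x2 table over the chosen gene universe
#' (in-cluster/in-category, in-cluster/out, out-cluster/in,
#' out-cluster/out) and computes the one-sided (greater) Fisher exact P:
#' the probability that at least the observed number of category genes
#' lands in the cluster by chance. Reported alongside are the percentage
#' of cluster genes carrying the category and the ratio of that
#' percentage to the category's percentage in the universe.
#'
#' Genes carrying several categories at one level are counted once per
#' category (each category is tested independently). No multiple-testing
#' correction is applied by default — rows are flagged significant at raw
#' \code{p < alpha} — but a Benjamini-Hochberg column can be requested.
#'
#' @param cluster_genes character vector of gene ids (subset of
#'   \code{universe_genes}).
#' @param annotations data frame with columns \code{gene}, \code{level}
#'   (one of \code{"main_role"}, \code{"subrole"}, \code{"subsystem"})
#'   and \code{category}.
#' @param universe_genes the gene universe: by convention the
#'   post-filter expressed gene set (the whole annotated genome may be
#'   supplied instead).
#' @param alpha significance threshold on the raw P (default 0.05).
#' @param adjust also compute a BH-adjusted P column.
#' @param min_overlap smallest in-cluster category count reported as a
#'   row (default 1; set 0 to also report absent categories, whose
#'   one-sided P is the whole support, 1).
#' @return data frame with one row per (level, category) present in the
#'   cluster: \code{level}, \code{category}, \code{overlap},
#'   \code{cluster_size}, \code{category_size}, \code{universe_size},
#'   \code{pct_genes}, \code{ratio}, \code{p_value}, \code{significant}
#'   (and \code{p_adjust} when requested), sorted by level then
#'   \code{p_value}. Categories absent from the universe are skipped and
#'   listed in attribute \code{"skipped"}.
#' @export
fisher_enrichment <- function(cluster_genes, annotations, universe_genes,
                              alpha = 0.05, adjust = FALSE,
                              min_overlap = 1L) {
  lv <- c("main_role", "subrole", "subsystem")
  stopifnot(all(c("gene", "level", "category") %in% names(annotations)),
            length(cluster_genes) > 0, length(universe_genes) > 0)
  if (!all(annotations$level %in% lv))
    stop("annotation levels must be one of: ", paste(lv, collapse = ", "))
  if (!all(cluster_genes %in% universe_genes))
    stop("cluster genes must be a subset of the universe")
  ann <- annotations[annotations$gene %in% universe_genes, , drop = FALSE]
  N <- length(unique(universe_genes))
  n_cl <- length(unique(cluster_genes))
  skipped <- character(0)
  rows <- list()
  cats <- unique(ann[, c("level", "category")])
  for (i in seq_len(nrow(cats))) {
    sel <- ann$level == cats$level[i] & ann$category == cats$category[i]
    cat_genes <- unique(ann$gene[sel])
    K <- length(cat_genes)
    if (K == 0) { skipped <- c(skipped, cats$category[i]); next }
    k <- length(intersect(cat_genes, cluster_genes))
    if (k < min_overlap) next
    tab <- matrix(c(k, n_cl - k, K - k, N - n_cl - (K - k)), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      level = cats$level[i], category = cats$category[i],
      overlap = k, cluster_size = n_cl, category_size = K,
      universe_size = N,
      pct_genes = 100 * k / n_cl,
      ratio = (k / n_cl) / (K / N),
      p_value = p)
  }
  if (!length(rows)) {
    out <- data.frame(level = character(0), category = character(0),
                      overlap = integer(0), cluster_size = integer(0),
                      category_size = integer(0), universe_size = integer(0),
                      pct_genes = numeric(0), ratio = numeric(0),
                      p_value = numeric(0), significant = logical(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  if (adjust) out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(match(out$level, lv), out$p_value, out$category), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Enrichment tables for every cluster
#'
#' Runs [fisher_enrichment()] for each cluster of a labelling and binds
#' the results with a leading \code{cluster} column, mirroring a
#' per-cluster functional-enrichment table.
#'
#' @param labels named cluster labels (gene -> cluster id).
#' @param annotations,alpha,adjust as in [fisher_enrichment()].
#' @param universe_genes defaults to the labelled (expressed) gene set.
#' @return data frame of enrichment rows across clusters.
#' @export
enrich_all_clusters <- function(labels, annotations,
                                universe_genes = names(labels),
                                alpha = 0.05, adjust = FALSE) {
  ids <- sort(unique(labels))
  res <- lapply(ids, function(cl) {
    r <- fisher_enrichment(names(labels)[labels == cl], annotations,
                           universe_genes, alpha = alpha, adjust = adjust)
    if (nrow(r)) cbind(cluster = cl, r) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
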