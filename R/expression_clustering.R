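# Coexpression analysis of a genes x conditions RPKM matrix: low-expression
# filtering, log2 + z standardization, hierarchical clustering, eigengenes.

#' Remove genes in the bottom expression quantile
#'
#' Per condition, the bottom \code{quantile} fraction of genes is found by
#' rank (ties broken by gene identifier, so the bottom set always has
#' exactly \code{floor(quantile * n)} members). A gene is removed when it
#' falls in the bottom set at every condition (\code{policy = "all"},
#' default) or at any condition (\code{policy = "any"}).
#'
#' @param mat numeric matrix, genes x conditions, rownames = gene ids.
#' @param quantile fraction in (0,1); default 0.20.
#' @param policy \code{"all"} or \code{"any"}.
#' @return list: \code{matrix} (survivors), \code{removed} (gene ids).
#' @export
filter_low_expression <- function(mat, quantile = 0.20,
                                  policy = c("all", "any")) {
  policy <- match.arg(policy)
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0,1)")
  stopifnot(is.matrix(mat), nrow(mat) >= 2, ncol(mat) >= 1,
            !is.null(rownames(mat)))
  n_bottom <- floor(quantile * nrow(mat))
  in_bottom <- matrix(FALSE, nrow(mat), ncol(mat),
                      dimnames = dimnames(mat))
  for (j in seq_len(ncol(mat))) {
    ord <- order(mat[, j], rownames(mat))
    in_bottom[ord[seq_len(n_bottom)], j] <- TRUE
  }
  drop <- if (policy == "all") rowSums(in_bottom) == ncol(mat)
          else rowSums(in_bottom) > 0
  list(matrix = mat[!drop, , drop = FALSE],
       removed = rownames(mat)[drop])
}

#' Log2-transform and standardize expression per gene
#'
#' \code{z = (log2(RPKM + pseudocount) - mean) / sd} across conditions,
#' using the population standard deviation so every output row has mean
#' exactly 0 and sd exactly 1. Genes constant across conditions (sd = 0)
#' cannot be standardized and are excluded and reported, not zeroed.
#'
#' @param mat non-negative RPKM matrix, genes x conditions.
#' @param pseudocount added before log2 (default 1 RPKM).
#' @return list: \code{matrix} (standardized), \code{excluded}
#'   (constant gene ids).
#' @export
transform_standardize <- function(mat, pseudocount = 1) {
  stopifnot(is.matrix(mat), all(mat >= 0), pseudocount >= 0)
  lg <- log2(mat + pseudocount)
  mu <- rowMeans(lg)
  sd_pop <- sqrt(rowMeans((lg - mu)^2))
  constant <- sd_pop == 0
  z <- (lg[!constant, , drop = FALSE] - mu[!constant]) / sd_pop[!constant]
  list(matrix = z, excluded = rownames(mat)[constant])
}

#' Hierarchical clustering of standardized expression profiles
#'
#' Agglomerative clustering (Euclidean distance, average linkage by
#' default) of gene profiles, with the tree cut to exactly \code{k}
#' clusters. Rows are ordered by gene identifier before the distance
#' computation so the result is deterministic regardless of input order.
#' Cluster ids are relabelled by decreasing cluster size (1 = largest).
#'
#' @param z standardized matrix from [transform_standardize()].
#' @param k number of clusters (>= 2, <= number of genes).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list of class \code{"cluster_result"}: \code{labels} (named
#'   integer vector in input row order), \code{k}, \code{sizes},
#'   \code{tree} (the hclust object), \code{linkage}, \code{metric}.
#' @export
cluster_genes <- function(z, k, linkage = "average") {
  stopifnot(is.matrix(z), k >= 2, !is.null(rownames(z)))
  if (k > nrow(z)) stop("k exceeds the number of genes")
  ord <- order(rownames(z))
  zs <- z[ord, , drop = FALSE]
  tree <- stats::hclust(stats::dist(zs, method = "euclidean"),
                        method = linkage)
  raw <- stats::cutree(tree, k = k)
  # relabel by decreasing size, ties by first appearance
  tab <- sort(table(raw), decreasing = TRUE)
  remap <- stats::setNames(seq_along(tab), names(tab))
  lab_sorted <- unname(remap[as.character(raw)])
  names(lab_sorted) <- rownames(zs)
  labels <- lab_sorted[rownames(z)]
  structure(list(labels = labels, k = k,
                 sizes = as.integer(table(labels)),
                 tree = tree, linkage = linkage, metric = "euclidean"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: ", x$k, " clusters over ", length(x$labels),
      " genes (", x$metric, ", ", x$linkage, " linkage)\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Per-cluster eigengenes (first principal components)
#'
#' The eigengene of a cluster is the first right singular vector of its
#' genes x conditions submatrix: the unit-norm condition profile
#' capturing the largest share of the cluster's variance. Its sign is
#' chosen so it correlates non-negatively with the cluster's mean
#' profile.
#'
#' @param z standardized matrix.
#' @param labels cluster labels named by gene (as from [cluster_genes()]).
#' @return list: \code{eigengenes} (clusters x conditions matrix, unit
#'   rows), \code{variance_explained} (fraction per cluster),
#'   \code{flagged} (clusters with a singular submatrix).
#' @export
compute_eigengenes <- function(z, labels) {
  stopifnot(is.matrix(z), !is.null(names(labels)),
            all(names(labels) %in% rownames(z)))
  ids <- sort(unique(labels))
  E <- matrix(NA_real_, length(ids), ncol(z),
              dimnames = list(as.character(ids), colnames(z)))
  ve <- stats::setNames(rep(NA_real_, length(ids)), as.character(ids))
  flagged <- character(0)
  for (i in seq_along(ids)) {
    sub <- z[names(labels)[labels == ids[i]], , drop = FALSE]
    sv <- svd(sub)  # a singleton cluster is the exact rank-1 case
    if (sv$d[1] == 0) { flagged <- c(flagged, as.character(ids[i])); next }
    e <- sv$v[, 1]
    m <- colMeans(sub)
    if (sum(e * m) < 0) e <- -e
    E[i, ] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = E, variance_explained = ve, flagged = flagged)
}

#' Correlate an eigengene with a phenotype profile
#'
#' Pearson correlation between a cluster eigengene and a per-condition
#' phenotype (e.g. specific growth rate across the irradiance series).
#'
#' @param eigengene numeric condition profile.
#' @param phenotype numeric vector of equal length (>= 3).
#' @return Pearson r; \code{NA} with a warning if either input has zero
#'   variance.
#' @export
correlate_eigengene <- function(eigengene, phenotype) {
  stopifnot(length(eigengene) == length(phenotype),
            length(eigengene) >= 3)
  if (stats::sd(eigengene) == 0 || stats::sd(phenotype) == 0) {
    warning("zero-variance input: correlation undefined")
    return(NA_real_)
  }
  stats::cor(eigengene, phenotype)
}

#' Merge clusters with near-identical eigengenes
#'
#' Repeatedly merges the pair of clusters whose eigengenes correlate
#' above \code{r_threshold} (highest correlation first), recomputing
#' eigengenes after each merge, until no pair exceeds the threshold.
#' Used to reduce an over-segmented profile set (e.g. six profiles) to
#' its major clusters.
#'
#' @param z standardized matrix.
#' @param labels cluster labels named by gene.
#' @param r_threshold eigengene correlation above which two clusters are
#'   considered the same profile (default 0.8).
#' @return relabelled named integer vector (ids renumbered by decreasing
#'   size).
#' @export
merge_clusters <- function(z, labels, r_threshold = 0.8) {
  stopifnot(r_threshold > 0, r_threshold < 1)
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) < 2) break
    eg <- compute_eigengenes(z, labels)$eigengenes
    C <- stats::cor(t(eg))
    diag(C) <- -Inf
    if (max(C, na.rm = TRUE) <= r_threshold) break
    ij <- which(C == max(C, na.rm = TRUE), arr.ind = TRUE)[1, ]
    keep <- ids[min(ij)]; drop <- ids[max(ij)]
    labels[labels == drop] <- keep
  }
  tab <- sort(table(labels), decreasing = TRUE)
  remap <- stats::setNames(seq_along(tab), names(tab))
  out <- unname(remap[as.character(labels)])
  names(out) <- names(labels)
  out
}

#' Full coexpression workflow: filter, standardize, cluster, eigengenes
#'
#' Convenience wrapper chaining [filter_low_expression()],
#' [transform_standardize()], [cluster_genes()] at \code{k} profiles, an
#' optional [merge_clusters()] step down to the major clusters, and
#' [compute_eigengenes()].
#'
#' @param rpkm RPKM matrix, genes x conditions.
#' @param k number of profiles to cut (default 6).
#' @param merge_r eigengene-correlation merge threshold for reducing
#'   profiles to major clusters; \code{NULL} disables merging.
#' @param quantile,policy,pseudocount passed to the filtering and
#'   standardization steps.
#' @return list: \code{labels} (major-cluster labels), \code{profiles}
#'   (pre-merge labels), \code{eigengenes}, \code{variance_explained},
#'   \code{z}, \code{removed}, \code{excluded}.
#' @export
cluster_expression <- function(rpkm, k = 6, merge_r = 0.8,
                               quantile = 0.20, policy = "all",
                               pseudocount = 1) {
  fl <- filter_low_expression(rpkm, quantile = quantile, policy = policy)
  st <- transform_standardize(fl$matrix, pseudocount = pseudocount)
  cl <- cluster_genes(st$matrix, k = k)
  labels <- cl$labels
  if (!is.null(merge_r)) labels <- merge_clusters(st$matrix, labels, merge_r)
  eg <- compute_eigengenes(st$matrix, labels)
  list(labels = labels, profiles = cl$labels,
       eigengenes = eg$eigengenes,
       variance_explained = eg$variance_explained,
       z = st$matrix, removed = fl$removed, excluded = st$excluded)
}
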