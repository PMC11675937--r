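# Multivariate views of codon usage: PCA of the amino-acid-normalized
# frequency matrix, k-means with elbow-based model selection, hierarchical
# leaf ordering for heatmap-style output, and tAI_gene pattern groups.

#' PCA of amino-acid-normalized codon usage
#'
#' Columns are centered (and optionally z-scored); component signs are fixed
#' so the largest-magnitude loading of each component is positive, making
#' results deterministic. Explained-variance fractions are relative to total
#' variance.
#'
#' @param matrix genes x features numeric matrix (e.g. from
#'   [aa_normalized_frequencies()]).
#' @param n_components components to retain (default `min(dim)`).
#' @param scale. z-score columns before PCA (default FALSE).
#' @return List: `scores` (genes x k), `loadings` (features x k),
#'   `explained_variance` (fractions, non-increasing).
#' @export
pca_codon_usage <- function(matrix, n_components = NULL, scale. = FALSE) {
  if (nrow(matrix) < 2 || ncol(matrix) < 2) stop("need >= 2 genes and >= 2 features")
  k_max <- min(dim(matrix))
  n_components <- n_components %||% k_max
  if (n_components > k_max) stop("n_components exceeds min(genes, features)")
  if (scale.) {
    keep <- apply(matrix, 2, stats::sd) > 0
    matrix <- matrix[, keep, drop = FALSE]
  }
  p <- stats::prcomp(matrix, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(p$rotation))
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, "*")
  loadings <- sweep(loadings, 2, flip, "*")
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, loadings = loadings,
       explained_variance = ev[seq_len(k)])
}

#' k-means clustering with elbow selection of k
#'
#' Runs k-means over `k_range` with `n_restarts` restarts per k and picks k
#' at the point of maximal curvature of the inertia (total within-cluster
#' sum of squares) curve: the largest second difference
#' inertia\[k-1\] - 2 inertia\[k\] + inertia\[k+1\] over interior k. The full
#' inertia trace is returned so the choice can be overridden.
#'
#' @param matrix genes x features numeric matrix.
#' @param k_range candidate k values (default 2:10, clipped to n - 1).
#' @param seed RNG seed (labels are seed-reproducible).
#' @param n_restarts `nstart` for [stats::kmeans()] (default 10).
#' @return List: `labels` (named cluster assignment, values in 0..k-1), `k`,
#'   `inertia` (named per candidate k), `trace` (data.frame with second
#'   differences), `seed`, `centers`.
#' @export
kmeans_elbow <- function(matrix, k_range = 2:10, seed = 1, n_restarts = 10) {
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2) stop("k_range must start at >= 2")
  if (max(k_range) >= nrow(matrix)) stop("fewer genes than max k")
  set.seed(seed)
  fits <- lapply(k_range, function(k) {
    stats::kmeans(matrix, centers = k, nstart = n_restarts, iter.max = 100)
  })
  inertia <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  names(inertia) <- k_range
  n <- length(k_range)
  if (n >= 3) {
    curv <- inertia[1:(n - 2)] - 2 * inertia[2:(n - 1)] + inertia[3:n]
    names(curv) <- k_range[2:(n - 1)]
    chosen <- k_range[which.max(curv) + 1]
  } else {
    curv <- numeric(0)
    chosen <- k_range[which.min(inertia)]
  }
  fit <- fits[[match(chosen, k_range)]]
  labels <- fit$cluster - 1L
  names(labels) <- rownames(matrix)
  d2 <- rep(NA_real_, n)
  if (n >= 3) d2[2:(n - 1)] <- unname(curv)
  trace <- data.frame(k = k_range, inertia = unname(inertia),
                      second_difference = d2)
  list(labels = labels, k = chosen, inertia = inertia, trace = trace,
       seed = seed, centers = fit$centers)
}

#' Hierarchical clustering with deterministic leaf order
#'
#' Euclidean distance with average linkage by default; the dendrogram is
#' also serialized to newick for diffable output.
#'
#' @param matrix items x features numeric matrix (rows are clustered).
#' @param method linkage method for [stats::hclust()] (default "average").
#' @param metric distance metric for [stats::dist()] (default "euclidean").
#' @return List: `order` (leaf order, row indices), `labels` (row names in
#'   leaf order), `hclust`, `newick`.
#' @export
hierarchical_order <- function(matrix, method = "average", metric = "euclidean") {
  if (nrow(matrix) < 2) stop("need >= 2 items")
  bad <- rownames(matrix)[!stats::complete.cases(matrix)]
  if (length(bad)) stop("rows with missing values: ", paste(bad, collapse = ", "))
  hc <- stats::hclust(stats::dist(matrix, method = metric), method = method)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(order = hc$order, labels = hc$labels[hc$order], hclust = hc,
       newick = nwk)
}

#' Group genes by two-condition tAI_gene pattern
#'
#' Default mode cuts a hierarchical clustering of the two-column tAI_gene
#' matrix into blocks and labels each block by its centroid relative to the
#' cohort quantile thresholds; threshold mode labels each gene directly.
#' Labels: `shared_high` (both high), `shared_low` (both low), `neuron_up`
#' (condition b high, condition a not), `other`.
#'
#' @param tai_a,tai_b named per-gene tAI_gene vectors (condition a = e.g.
#'   progenitor, condition b = e.g. differentiated).
#' @param mode `"hclust"` (default) or `"threshold"`.
#' @param thresholds length-2 quantile levels (a, b) splitting low from high
#'   (default c(0.5, 0.5)).
#' @param k number of hierarchical blocks in hclust mode (default 4).
#' @return data.frame: `gene_id`, `tai_a`, `tai_b`, `group`; attribute
#'   `group_sizes`.
#' @export
tai_gene_groups <- function(tai_a, tai_b, mode = c("hclust", "threshold"),
                            thresholds = c(0.5, 0.5), k = 4) {
  mode <- match.arg(mode)
  common <- intersect(names(tai_a), names(tai_b))
  if (!length(common)) stop("no genes with both condition values")
  a <- tai_a[common]; b <- tai_b[common]
  qa <- stats::quantile(a, thresholds[1])
  qb <- stats::quantile(b, thresholds[2])
  label_point <- function(x, y) {
    if (x >= qa && y >= qb) "shared_high"
    else if (x < qa && y < qb) "shared_low"
    else if (y >= qb && x < qa) "neuron_up"
    else "other"
  }
  if (mode == "threshold") {
    grp <- mapply(label_point, a, b)
  } else {
    m <- cbind(a = a, b = b)
    hc <- stats::hclust(stats::dist(m), method = "ward.D2")
    blocks <- stats::cutree(hc, k = min(k, length(common)))
    cent <- vapply(sort(unique(blocks)), function(bl) colMeans(m[blocks == bl, , drop = FALSE]),
                   numeric(2))
    block_label <- vapply(seq_len(ncol(cent)),
                          function(i) label_point(cent[1, i], cent[2, i]),
                          character(1))
    grp <- block_label[blocks]
  }
  out <- data.frame(gene_id = common, tai_a = unname(a), tai_b = unname(b),
                    group = unname(grp), stringsAsFactors = FALSE)
  attr(out, "group_sizes") <- table(out$group)
  out
}
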