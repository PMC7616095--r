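#' First two principal components of a PSTH matrix
#'
#' Columns (time bins) are mean-centered — not variance-scaled, since PSTHs
#' already share the z scale — and the matrix decomposed by SVD. Scores on the
#' two leading components are returned with a deterministic sign convention:
#' each component is flipped so its largest-magnitude loading is positive.
#'
#' @param m units x bins matrix (no missing values), >= 3 units.
#' @return units x 2 score matrix with attributes `loadings` (bins x 2),
#'   `var_explained` (proportions for all components), and row names of `m`.
#' @export
extract_pcs <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("at least 3 units required")
  if (anyNA(m)) stop("missing values in PSTH matrix")
  x <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(x)
  if (length(sv$d) < 2 || sv$d[2] <= sv$d[1] * 1e-10) {
    stop("PSTH matrix has rank < 2")
  }
  flip <- vapply(1:2, function(k) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2]), 2, flip, `*`)
  rownames(scores) <- rownames(m)
  colnames(scores) <- c("PC1", "PC2")
  attr(scores, "loadings") <- sweep(sv$v[, 1:2, drop = FALSE], 2, flip, `*`)
  attr(scores, "var_explained") <- sv$d^2 / sum(sv$d^2)
  scores
}

#' Average-linkage hierarchical clustering on Euclidean distances
#'
#' Agglomerative clustering where the distance between clusters is the mean
#' pairwise Euclidean distance (UPGMA), as used for grouping population
#' PSTHs in PC space.
#'
#' @param scores points x dims matrix (typically the PC scores).
#' @return an `hclust` object.
#' @export
hcluster_average_euclidean <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("at least 2 points required")
  stats::hclust(stats::dist(scores, method = "euclidean"), method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' @param d an `hclust` object.
#' @param k number of clusters (1..n).
#' @return named integer vector of cluster ids (exactly `k` non-empty).
#' @export
cut_dendrogram <- function(d, k) {
  n <- length(d$order)
  if (k < 1 || k > n) stop("k must be between 1 and the number of units")
  stats::cutree(d, k = k)
}

#' Population composition of each cluster
#'
#' @param assignment cluster ids per unit (named or aligned with `labels`).
#' @param labels population label per unit.
#' @return a list: `fractions` (clusters x populations matrix of within-
#'   cluster fractions, rows summing to 1), `modal_cluster` (per population,
#'   the cluster holding its largest share) and `modal_fraction` (that share
#'   of the population).
#' @export
population_enrichment <- function(assignment, labels) {
  if (length(assignment) != length(labels)) {
    stop("assignment and labels differ in length")
  }
  tab <- table(cluster = assignment, population = labels)
  fractions <- prop.table(tab, margin = 1)
  by_pop <- prop.table(tab, margin = 2) # share of each population per cluster
  modal_idx <- apply(by_pop, 2, which.max)
  modal_cluster <- rownames(tab)[modal_idx]
  modal_fraction <- vapply(seq_along(modal_idx),
                           function(j) by_pop[modal_idx[j], j], numeric(1))
  names(modal_cluster) <- names(modal_fraction) <- colnames(tab)
  list(fractions = as.matrix(fractions), modal_cluster = modal_cluster,
       modal_fraction = modal_fraction)
}

#' Export a dendrogram to Newick
#'
#' @param d an `hclust` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(d, path) {
  phy <- ape::as.phylo(d)
  ape::write.tree(phy, file = path)
  invisible(path)
}
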