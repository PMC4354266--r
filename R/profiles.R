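#' Compress a texture block into a one-dimensional texture index
#'
#' Each column is min-max scaled, then the block is compressed by principal
#' component analysis: the score on the first PC is the texture index. The
#' sign of the PC is fixed so the index correlates positively with the mean
#' scaled texture magnitude (PCA signs are otherwise arbitrary).
#'
#' @param data Data frame or matrix whose columns are the texture features
#'   (20 for a full suite; any number >= 1 works).
#' @param scale Min-max scale the columns first (the usual case for raw
#'   texture features).
#' @return Numeric vector of first-PC scores, one per row; attributes
#'   `var_explained` (share of variance on PC1) and `rotation`.
#' @export
texture_index <- function(data, scale = TRUE) {
  x <- as.matrix(data)
  stopifnot(is.numeric(x), nrow(x) >= 2)
  if (scale) x <- apply(x, 2, scale_unit)
  sds <- apply(x, 2, stats::sd)
  if (all(sds < 1e-12)) {
    stop("Texture block is constant; the first PC is undefined.",
         call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  ref <- rowMeans(x)
  flip <- if (stats::sd(ref) > 1e-12 && !is.na(stats::cor(scores, ref))) {
    stats::cor(scores, ref) < 0
  } else {
    pc$rotation[which.max(abs(pc$rotation[, 1])), 1] < 0
  }
  if (flip) { scores <- -scores; pc$rotation[, 1] <- -pc$rotation[, 1] }
  structure(as.numeric(scores),
            var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
            rotation = pc$rotation[, 1])
}

#' Z-score the columns of a profile matrix
#'
#' Standard normalization (`(x - mean) / sd`, sample sd) per column so all
#' features are on the same scale before distance-based analysis.
#'
#' @param data Data frame; non-numeric columns are passed through untouched.
#' @param cols Columns to scale; default all numeric columns.
#' @return A tibble with scaled columns and attribute `scaling = "zscore"`.
#' @export
zscore <- function(data, cols = NULL) {
  out <- tibble::as_tibble(data)
  if (is.null(cols)) {
    cols <- names(out)[vapply(out, is.numeric, logical(1))]
  }
  stopifnot(nrow(out) >= 2)
  for (cl in cols) {
    s <- stats::sd(out[[cl]])
    if (s < 1e-12) {
      stop("Column is constant and cannot be z-scored: ", cl, call. = FALSE)
    }
    out[[cl]] <- (out[[cl]] - mean(out[[cl]])) / s
  }
  attr(out, "scaling") <- "zscore"
  out
}

#' Hierarchical clustering of phenotype profiles
#'
#' Agglomerative clustering with Euclidean distance and average linkage
#' (UPGMA), cut into `k` flat clusters. Input should be z-scored so every
#' feature contributes on the same scale.
#'
#' @param data Data frame of profiles; numeric columns are used.
#' @param k Number of flat clusters, `2 <= k <= n`.
#' @return A `pheno_hclust` object: list with the `hclust` tree,
#'   `assignment` (integer vector), `k`, and the feature column names.
#' @export
hcluster <- function(data, k) {
  df <- tibble::as_tibble(data)
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  num <- setdiff(num, c("sample_id", "archetype", "cluster"))
  x <- as.matrix(df[num])
  n <- nrow(x)
  if (!(k >= 2 && k <= n)) {
    stop("`k` must be between 2 and the number of samples (", n, ").",
         call. = FALSE)
  }
  tree <- stats::hclust(stats::dist(x, method = "euclidean"),
                        method = "average")
  assignment <- stats::cutree(tree, k = k)
  structure(list(tree = tree, assignment = as.integer(assignment), k = k,
                 features = num, n = n),
            class = "pheno_hclust")
}

#' @export
print.pheno_hclust <- function(x, ...) {
  cat("<pheno_hclust> UPGMA/Euclidean, n = ", x$n, ", k = ", x$k, "\n",
      sep = "")
  print(table(cluster = x$assignment))
  invisible(x)
}

#' @method tidy pheno_hclust
#' @export
tidy.pheno_hclust <- function(x, ...) {
  tibble::tibble(sample = seq_len(x$n), cluster = x$assignment)
}

#' @method glance pheno_hclust
#' @export
glance.pheno_hclust <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k,
                 height = max(x$tree$height),
                 n_features = length(x$features))
}

#' Per-cluster mean profiles
#'
#' Column means of the supplied profile table within each cluster — the
#' profiles rendered as one glyph per cluster. Pass the table on the
#' plotting scale (jointly scaled dimensions, 0-1 features), not the
#' z-scored table used for clustering: the two normalizations coexist.
#'
#' @param result A `pheno_hclust`.
#' @param data Profile table with the same row order used for clustering.
#' @return A tibble: `cluster`, `n`, then the per-cluster feature means.
#' @export
cluster_profile_means <- function(result, data) {
  stopifnot(inherits(result, "pheno_hclust"),
            nrow(data) == result$n)
  df <- tibble::as_tibble(data)
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  num <- setdiff(num, c("sample_id", "archetype", "cluster"))
  df$cluster <- result$assignment
  dplyr::summarise(
    dplyr::group_by(df, .data$cluster),
    n = dplyr::n(),
    dplyr::across(dplyr::all_of(num), mean),
    .groups = "drop"
  )
}

#' Project profiles onto the first two principal components
#'
#' PCA of the (z-scored) profile matrix; samples are placed at their scores
#' on the first two PCs, the layout used to position glyphs in a
#' two-dimensional plane. Signs are fixed so the largest-magnitude loading
#' of each PC is positive.
#'
#' @param data Data frame of profiles; numeric feature columns are used.
#' @return A tibble with `PC1`, `PC2`; attributes `var_explained`
#'   (length-2) and `rotation`.
#' @export
pca_project <- function(data) {
  df <- tibble::as_tibble(data)
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  num <- setdiff(num, c("sample_id", "archetype", "cluster"))
  x <- as.matrix(df[num])
  if (nrow(x) < 3) stop("Need at least 3 samples.", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12) {
    stop("Profile matrix has rank < 2; no 2D projection.", call. = FALSE)
  }
  rot <- pc$rotation[, 1:2, drop = FALSE]
  sc <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j]
    }
  }
  structure(tibble::tibble(PC1 = sc[, 1], PC2 = sc[, 2]),
            var_explained = pc$sdev[1:2]^2 / sum(pc$sdev^2),
            rotation = rot)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings: 1 for identical
#' partitions, ~0 for random agreement.
#'
#' @param a,b Integer/factor label vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
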