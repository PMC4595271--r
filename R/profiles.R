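#' Row-wise z-score scaling
#'
#' Centers and scales each row to mean 0 and sample SD 1 (n-1 denominator),
#' the normalization behind the developmental heatmaps. Constant rows map to
#' all zeros with a warning.
#'
#' @param m numeric matrix (rows = genes or compounds, columns = condition
#'   cells); every row needs >= 2 non-missing values.
#' @return matrix of the same shape.
#' @export
#' @examples
#' row_scale(rbind(a = c(1, 2, 3)))
row_scale <- function(m) {
  stopifnot(is.matrix(m))
  n_ok <- rowSums(is.finite(m))
  if (any(n_ok < 2)) stop("rows with fewer than 2 detected values: ",
                          paste(rownames(m)[n_ok < 2], collapse = ", "))
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, sd, na.rm = TRUE)
  const <- s == 0
  if (any(const)) {
    warning("constant rows scaled to zero: ",
            paste(rownames(m)[const], collapse = ", "))
    s[const] <- 1
  }
  out <- (m - mu) / s
  out[const, ] <- 0
  out
}

# Newick string from an hclust object with node depth equal to merge height
# (branch length = parent height - child height; leaves at depth 0)
hclust_to_newick <- function(h) {
  labs <- h$labels
  rec <- function(node, parent_height) {
    if (node < 0) {  # leaf
      sprintf("%s:%.10g", labs[-node], parent_height)
    } else {
      hh <- h$height[node]
      sprintf("(%s,%s):%.10g",
              rec(h$merge[node, 1], hh), rec(h$merge[node, 2], hh),
              parent_height - hh)
    }
  }
  root <- nrow(h$merge)
  sprintf("(%s,%s):0;", rec(h$merge[root, 1], h$height[root]),
          rec(h$merge[root, 2], h$height[root]))
}

#' Agglomerative clustering of profiles with Newick export
#'
#' Hierarchically clusters matrix rows (Euclidean distance, complete linkage
#' by default, both configurable) and exports the dendrogram as a Newick
#' string in which each internal node sits at its merge height (so branch
#' lengths are height differences and leaves are at depth zero).
#'
#' @param m numeric matrix, usually the output of [row_scale()].
#' @param distance distance measure passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with elements `hclust`, `order` (leaf labels in dendrogram
#'   order), `newick`.
#' @export
hierarchical_cluster <- function(m, distance = "euclidean",
                                 linkage = "complete") {
  stopifnot(is.matrix(m), nrow(m) >= 2)
  if (any(!is.finite(m))) stop("non-finite values in profile matrix")
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  h <- hclust(dist(m, method = distance), method = linkage)
  list(hclust = h, order = h$labels[h$order], newick = hclust_to_newick(h))
}

# k-means++ seeding (squared-distance weighted); deterministic under a seed
kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(NA_real_, k, ncol(m))
  idx <- sample.int(n, 1)
  centers[1, ] <- m[idx, ]
  d2 <- colSums((t(m) - centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = prob)
    centers[j, ] <- m[idx, ]
    d2 <- pmin(d2, colSums((t(m) - centers[j, ])^2))
  }
  centers
}

#' K-means clustering of developmental trends
#'
#' Clusters scaled profiles with Lloyd's algorithm from k-means++ seeding
#' under a fixed seed, then marks a cluster as "upward" when the Pearson
#' correlation of its centroid with the stage index is at least `r_up`. Used
#' to pick gene-family members (e.g. UGTs) whose expression rises in
#' parallel with glycoside accumulation.
#'
#' @param m scaled profile matrix (rows clustered).
#' @param k number of clusters, `2 <= k <= nrow(m)` (with `k == nrow(m)`
#'   each row is its own cluster).
#' @param seed RNG seed for the initialization.
#' @param stage_index numeric developmental covariate per column (default:
#'   column position).
#' @param r_up upward-trend correlation threshold (default 0.7).
#' @return list with `labels` (named cluster ids), `centers`, `upward`
#'   (upward cluster ids) and `upward_members` (row ids in upward clusters).
#' @export
kmeans_trends <- function(m, k, seed = 1, stage_index = seq_len(ncol(m)),
                          r_up = 0.7) {
  stopifnot(is.matrix(m))
  if (k < 2 || k > nrow(m)) stop("k must be in [2, nrow(m)]")
  stopifnot(length(stage_index) == ncol(m))
  fit <- with_seed(seed, {
    init <- kmeanspp_init(m, k)
    init <- init + 0  # distinct matrix
    kmeans(m, centers = init, algorithm = "Lloyd", iter.max = 100)
  })
  centers <- fit$centers
  r_cent <- apply(centers, 1, function(ct)
    if (sd(ct) == 0 || sd(stage_index) == 0) 0 else cor(ct, stage_index))
  upward <- which(r_cent >= r_up)
  labels <- fit$cluster
  names(labels) <- rownames(m)
  list(labels = labels, centers = centers, upward = upward,
       upward_members = rownames(m)[labels %in% upward],
       withinss = fit$withinss)
}

#' Classify a developmental trend over ordered stages
#'
#' Reproduces the categorical trend classes used for pathway tables:
#' `"ND"` (not detected / absent from the annotation source), `"NC"`
#' (detected at two or fewer stages, not classifiable), otherwise the
#' Pearson correlation of the profile with the stage ranks decides
#' `"increased"` (r >= `r_trend`), `"decreased"` (r <= -`r_trend`) or
#' `"stable"`. Independently, a peaked subtype is flagged when the maximum
#' sits at an interior stage and is at least `peak_fold`-fold above both
#' ends.
#'
#' @param profile numeric vector over ordered stages (one value per stage).
#' @param detected logical detection mask (default: finite profile values).
#' @param annotated FALSE marks the row as absent from the annotation
#'   source, returning class `"ND"`.
#' @param r_trend trend correlation threshold (default 0.7).
#' @param peak_fold interior-peak fold threshold (default 2).
#' @return list with `class` and logical `peaked`.
#' @export
#' @examples
#' classify_trend(c(1, 2, 3, 4))$class   # "increased"
#' classify_trend(c(1, 5, 4, 1))         # stable, peaked
classify_trend <- function(profile, detected = is.finite(profile),
                           annotated = TRUE, r_trend = 0.7, peak_fold = 2) {
  if (!annotated)
    return(list(class = "ND", peaked = FALSE))
  if (sum(detected) <= 2)
    return(list(class = "NC", peaked = FALSE))
  ranks <- seq_along(profile)
  x <- profile[detected]
  r <- if (sd(x) == 0) 0 else cor(x, ranks[detected])
  cls <- if (r >= r_trend) "increased" else if (r <= -r_trend) "decreased"
         else "stable"
  imax <- which.max(profile)
  n <- length(profile)
  peaked <- imax > 1 && imax < n &&
    profile[imax] >= peak_fold * profile[1] &&
    profile[imax] >= peak_fold * profile[n]
  list(class = cls, peaked = peaked)
}

#' Condition-cell means of an expression matrix
#'
#' Averages replicate libraries into one value per region x year x stage
#' cell, the per-condition convention used for heatmaps, correlation and
#' network profiles.
#'
#' @param m matrix, rows x libraries.
#' @param libraries data.frame with `library` and `cell` columns matching
#'   the columns of `m`.
#' @return matrix, rows x cells (cell order of first appearance).
#' @export
cell_means <- function(m, libraries) {
  stopifnot(ncol(m) == nrow(libraries))
  cells <- unique(libraries$cell)
  out <- vapply(cells, function(cl)
    rowMeans(m[, libraries$cell == cl, drop = FALSE]),
    numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m),
                                       dimnames = list(rownames(m), cells))
  out
}

#' Heatmap of scaled developmental profiles
#'
#' Minimal clustered heatmap (base graphics) of a scaled profile matrix,
#' using the same distance/linkage defaults as [hierarchical_cluster()].
#'
#' @param m scaled matrix.
#' @param ... passed to [stats::heatmap()].
#' @return invisibly, the heatmap return value.
#' @export
plot_profile_heatmap <- function(m, ...) {
  invisible(stats::heatmap(m, Colv = NA, scale = "none",
                           hclustfun = function(d) hclust(d, "complete"), ...))
}
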