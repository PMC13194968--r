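#' Z-score standardization of metal concentrations
#'
#' Centers and scales every metal column to mean 0 and sample SD 1 (n-1
#' denominator), removing scale differences between elements before
#' clustering or PCA.
#'
#' @param table A [sample_table()] (or numeric matrix) with >= 2 rows.
#' @return Numeric matrix, samples x metals.
#' @export
zscore_metals <- function(table) {
  x <- if (inherits(table, "sample_table")) {
    as.matrix(as.data.frame(table)[, table_metals(table), drop = FALSE])
  } else {
    as.matrix(table)
  }
  if (nrow(x) < 2) stop("at least 2 samples are required")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Ward hierarchical clustering of metals
#'
#' Agglomerative clustering of the metals (variables, not samples) on their
#' standardized concentration profiles, using Euclidean distance and Ward's
#' minimum-variance linkage: each merge is the pair of clusters whose
#' fusion least increases the total within-cluster sum of squares. Merge
#' heights are on the `"ward.D2"` scale (the square root of twice the
#' within-cluster variance increase), so heights are non-decreasing along
#' the merge sequence.
#'
#' @param x Standardized matrix from [zscore_metals()] (samples x metals),
#'   with >= 3 metals.
#' @return List of class `"metal_dendrogram"`: `hclust` (the stats::hclust
#'   object over metals), `labels`, `merge`, `height`.
#' @export
#' @examples
#' tab <- generate_site(default_site_spec(seed = 4))
#' dend <- ward_cluster(zscore_metals(tab))
#' cut_metals(dend, k = 4)
ward_cluster <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("at least 3 metals are required")
  hc <- stats::hclust(stats::dist(t(x), method = "euclidean"),
                      method = "ward.D2")
  structure(list(hclust = hc, labels = hc$labels, merge = hc$merge,
                 height = hc$height), class = "metal_dendrogram")
}

#' Cut a metal dendrogram into clusters
#'
#' With `k = NULL` the number of clusters is chosen by the largest increase
#' in the fusion coefficient (merge height): the tree is cut just below the
#' merge whose height gain over the previous merge is largest.
#'
#' @param dend A [ward_cluster()] result.
#' @param k Number of clusters, or `NULL` for the automatic rule.
#' @return Named integer vector of cluster memberships (one per metal).
#' @export
cut_metals <- function(dend, k = NULL) {
  stopifnot(inherits(dend, "metal_dendrogram"))
  h <- dend$height
  if (is.null(k)) {
    if (length(h) < 2) {
      k <- 1L
    } else {
      gains <- diff(h)
      # perform merges up to the one preceding the largest height gain;
      # with m merges over m+1 leaves, stopping after merge i leaves
      # m + 1 - i clusters
      k <- length(h) + 1L - which.max(gains)
      k <- max(2L, k)
    }
  }
  stats::cutree(dend$hclust, k = k)
}

#' @export
print.metal_dendrogram <- function(x, ...) {
  cat("<metal_dendrogram> Ward/Euclidean over",
      length(x$labels), "metals\n")
  cat("merge heights:", paste(round(x$height, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Newick text form of a metal dendrogram
#'
#' Nested-parenthesis representation with merge heights, writable as a
#' plain-text artifact.
#'
#' @param dend A [ward_cluster()] result.
#' @return Single Newick string (terminated by `;`).
#' @export
dendrogram_newick <- function(dend) {
  stopifnot(inherits(dend, "metal_dendrogram"))
  merge <- dend$merge; height <- dend$height; labels <- dend$labels
  node_height <- function(i) if (i < 0) 0 else height[i]
  build <- function(i) {
    kids <- merge[i, ]
    parts <- vapply(kids, function(kid) {
      if (kid < 0) {
        sprintf("%s:%.6g", labels[-kid], height[i])
      } else {
        sprintf("%s:%.6g", build(kid), height[i] - node_height(kid))
      }
    }, character(1))
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  paste0(build(nrow(merge)), ";")
}

#' Principal component analysis with Kaiser retention and varimax rotation
#'
#' Eigendecomposition of the correlation matrix of the standardized data;
#' components with eigenvalue > 1 are retained (Kaiser criterion) and their
#' loadings varimax-rotated for interpretability. Communalities are
#' invariant under the rotation. Each loading column's sign is flipped so
#' its largest-magnitude entry is positive (rotation/reflection
#' indeterminacy).
#'
#' @param x Standardized matrix from [zscore_metals()] (samples x metals).
#' @param kaiser_cutoff Eigenvalue retention threshold (default 1).
#' @param rotate Apply varimax to the retained loadings (default TRUE;
#'   with a single retained component no rotation is possible).
#' @return List of class `"pca_result"`: `loadings` (rotated, metals x
#'   retained components), `unrotated`, `eigenvalues`, `var_explained`
#'   (fraction per unrotated component), `communality`, `n_retained`,
#'   `rotation`.
#' @export
pca_varimax <- function(x, kaiser_cutoff = 1, rotate = TRUE) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2) stop("at least 2 metals are required")
  if (nrow(x) <= p) {
    warning("fewer samples than metals + 1; loadings will be unstable")
  }
  r <- stats::cor(x)
  eig <- eigen(r, symmetric = TRUE)
  ev <- eig$values
  n_retained <- sum(ev > kaiser_cutoff)
  if (n_retained == 0) n_retained <- 1
  keep <- seq_len(n_retained)
  load_full <- eig$vectors %*% diag(sqrt(pmax(ev, 0)), p)
  dimnames(load_full) <- list(colnames(x), paste0("PC", seq_len(p)))
  unrot <- load_full[, keep, drop = FALSE]
  rotation <- "none"
  loadings <- unrot
  if (rotate && n_retained >= 2) {
    vm <- stats::varimax(unrot)
    loadings <- unrot %*% vm$rotmat
    dimnames(loadings) <- dimnames(unrot)
    rotation <- "varimax"
  }
  # sign convention: largest-magnitude entry of each column positive
  for (j in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
    }
  }
  structure(list(
    loadings = loadings, unrotated = unrot, eigenvalues = ev,
    var_explained = ev / p,
    communality = rowSums(unrot^2),
    n_retained = n_retained, rotation = rotation
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d component(s) retained (Kaiser), rotation = %s\n",
              x$n_retained, x$rotation))
  cat("eigenvalues:", paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Qualitative interpretation of loadings
#'
#' Labels |loading| > 0.5 as `"strong"` and 0.3-0.5 as `"moderate"`, the
#' conventional reading thresholds for rotated loadings.
#'
#' @param pca A [pca_varimax()] result.
#' @return Long data.frame `metal`, `component`, `loading`, `strength`
#'   (`"strong"`, `"moderate"` or `"weak"`).
#' @export
loading_interpretation <- function(pca) {
  stopifnot(inherits(pca, "pca_result"))
  l <- pca$loadings
  out <- data.frame(
    metal = rep(rownames(l), times = ncol(l)),
    component = rep(colnames(l), each = nrow(l)),
    loading = as.vector(l),
    stringsAsFactors = FALSE
  )
  a <- abs(out$loading)
  out$strength <- ifelse(a > 0.5, "strong",
                         ifelse(a >= 0.3, "moderate", "weak"))
  out
}
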