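#' Circular (sin/cos) encoding of torsion angles
#'
#' Maps each torsion angle onto the unit circle, giving features that are
#' continuous across the -180/+180 wrap. Columns are ordered
#' `(sin t1, cos t1, sin t2, cos t2, ...)`.
#'
#' @param angles numeric matrix `frames x torsions`, degrees.
#' @return Numeric matrix `frames x (2 * torsions)`.
#' @export
encode_circular <- function(angles) {
  angles <- as.matrix(angles)
  if (any(!is.finite(angles))) stopf("angles must be finite")
  rad <- angles * pi / 180
  nt <- ncol(rad)
  out <- matrix(NA_real_, nrow(rad), 2L * nt)
  out[, 2L * seq_len(nt) - 1L] <- sin(rad)
  out[, 2L * seq_len(nt)] <- cos(rad)
  lab <- colnames(angles)
  if (is.null(lab)) lab <- paste0("T", seq_len(nt))
  colnames(out) <- as.vector(rbind(paste0("sin_", lab), paste0("cos_", lab)))
  out
}

#' Principal component analysis of (circular-encoded) torsion features
#'
#' Eigendecomposition of the covariance of mean-centered features,
#' optionally weighted by per-frame statistical weights. By default the
#' model is fitted unweighted on all frames and the density on the PC
#' plane is reweighted afterwards, so ensembles and trajectory halves can
#' be compared on fixed axes.
#'
#' Component signs follow a deterministic convention: the largest-
#' magnitude entry of each component is positive.
#'
#' @param features numeric matrix `frames x p` (see [encode_circular()]).
#' @param weights optional per-frame weights for a weighted fit.
#' @return An object of class `dpca_model` with elements `mean`
#'   (length-p), `components` (orthonormal eigenvectors as rows, by
#'   decreasing eigenvalue) and `eigenvalues`.
#' @export
fit_pca <- function(features, weights = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) stopf("PCA needs at least 2 frames")
  if (is.null(weights)) {
    mu <- colMeans(features)
    xc <- sweep(features, 2, mu)
    cv <- crossprod(xc) / (n - 1)
  } else {
    w <- check_weights(weights, n)
    mu <- colSums(features * w)
    xc <- sweep(features, 2, mu)
    # unbiased weighted covariance; reduces to the sample covariance for
    # uniform weights
    cv <- crossprod(xc * sqrt(w)) / (1 - sum(w^2))
  }
  if (sum(diag(cv)) < 1e-12)
    stopf("degenerate model: features have zero total variance")
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- t(eig$vectors)
  # sign convention: largest-|entry| of each component positive
  for (i in seq_len(nrow(vecs))) {
    j <- which.max(abs(vecs[i, ]))
    if (vecs[i, j] < 0) vecs[i, ] <- -vecs[i, ]
  }
  structure(list(mean = mu, components = vecs, eigenvalues = vals,
                 weighted = !is.null(weights)),
            class = "dpca_model")
}

#' @export
print.dpca_model <- function(x, ...) {
  ev <- x$eigenvalues
  expl <- 100 * ev / sum(ev)
  cat(sprintf("dpca_model: %d features, %sweighted fit\n",
              length(x$mean), if (x$weighted) "" else "un"))
  cat(sprintf("  PC1..PC%d explain %s%% of variance\n",
              min(4, length(ev)),
              paste(sprintf("%.1f", utils::head(expl, 4)), collapse = " + ")))
  invisible(x)
}

#' @export
summary.dpca_model <- function(object, ...) {
  ev <- object$eigenvalues
  data.frame(component = seq_along(ev), eigenvalue = ev,
             proportion = ev / sum(ev), cumulative = cumsum(ev) / sum(ev))
}

#' Project features onto principal components
#'
#' @param features numeric matrix `frames x p` on the model's feature
#'   space.
#' @param model a [fit_pca()] model.
#' @param n number of leading components to keep.
#' @return Numeric matrix `frames x n` of PC coordinates.
#' @export
project_pca <- function(features, model, n = 2) {
  features <- matrix(as.numeric(features), ncol = length(model$mean))
  if (n > nrow(model$components))
    stopf("requested %d components but model holds %d", n,
          nrow(model$components))
  xc <- sweep(features, 2, model$mean)
  scores <- xc %*% t(model$components[seq_len(n), , drop = FALSE])
  colnames(scores) <- paste0("PC", seq_len(n))
  scores
}

#' @describeIn project_pca `predict` method delegating to `project_pca`.
#' @param object,newdata,... model, feature matrix and `n` for the
#'   `predict` method.
#' @export
predict.dpca_model <- function(object, newdata, n = 2, ...) {
  project_pca(newdata, object, n = n)
}

#' K-means clustering in PC space
#'
#' Lloyd iterations (via [stats::kmeans()]) from a k-means++-style seeded
#' initialization; deterministic for a fixed seed. Clusters are relabeled
#' by decreasing population (cluster 1 is the most populated), and a
#' representative frame — the member closest to its centroid, ties broken
#' by lowest frame index — is reported per cluster.
#'
#' @param coords numeric matrix `frames x d` of PC coordinates.
#' @param k number of clusters (default 6).
#' @param seed integer RNG seed for the initialization.
#' @param iter_max maximum Lloyd iterations.
#' @return An object of class `cluster_result` with `labels` (1..k per
#'   frame), `centroids` (k x d), `sizes`, and `representative_frames`.
#' @export
kmeans_cluster <- function(coords, k = 6, seed = 1, iter_max = 500) {
  coords <- as.matrix(coords)
  nf <- nrow(coords)
  if (k < 1 || k > nf) stopf("k must be in 1..%d (got %d)", nf, k)
  centers <- with_seed(seed, kmeanspp_init(coords, k))
  km <- suppressWarnings(stats::kmeans(coords, centers = centers,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd"))
  ord <- order(km$size, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- NULL
  res <- structure(list(labels = labels, centroids = centroids,
                        sizes = km$size[ord], k = k,
                        withinss = sum(km$withinss)),
                   class = "cluster_result")
  res$representative_frames <- representative_frames(coords, res)
  res
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_init <- function(coords, k) {
  nf <- nrow(coords)
  centers <- matrix(NA_real_, k, ncol(coords))
  idx <- sample.int(nf, 1)
  centers[1, ] <- coords[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(coords, 2, centers[1, ])^2)
    for (i in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / nf, nf)
      idx <- sample.int(nf, 1, prob = prob)
      centers[i, ] <- coords[idx, ]
      d2 <- pmin(d2, rowSums(sweep(coords, 2, centers[i, ])^2))
    }
  }
  # duplicate seeds break stats::kmeans; nudge exact duplicates apart
  while (anyDuplicated(centers)) {
    dup <- which(duplicated(centers))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(stats::rnorm(length(dup) * ncol(coords), sd = 1e-8),
             nrow = length(dup))
  }
  centers
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d over %d frames\n", x$k, length(x$labels)))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("  representatives:", paste(x$representative_frames, collapse = ", "), "\n")
  invisible(x)
}

#' Representative frame of each cluster
#'
#' For each cluster, the member frame with minimum Euclidean distance to
#' the cluster centroid; ties are broken by lowest frame index. Empty
#' clusters get `NA`.
#'
#' @param coords numeric matrix `frames x d`.
#' @param result a [kmeans_cluster()] result.
#' @return Integer vector of frame indices, one per cluster.
#' @export
representative_frames <- function(coords, result) {
  coords <- as.matrix(coords)
  vapply(seq_len(result$k), function(cl) {
    members <- which(result$labels == cl)
    if (!length(members)) return(NA_integer_)
    d2 <- rowSums(sweep(coords[members, , drop = FALSE], 2,
                        result$centroids[cl, ])^2)
    members[which.min(d2)]  # which.min takes the first (lowest index) on ties
  }, integer(1))
}

#' Match an external reference point to a cluster representative
#'
#' Finds the cluster whose centroid is nearest a reference point in PC
#' space (e.g. a representative conformation from another solvent's
#' ensemble projected on shared axes). If no centroid lies within
#' `radius`, the single nearest *frame* is returned instead and flagged
#' as a frame fallback.
#'
#' @param coords numeric matrix `frames x d` of the ensemble being
#'   searched.
#' @param result its [kmeans_cluster()] result.
#' @param reference_point length-d numeric PC coordinates.
#' @param radius maximum centroid distance before falling back to the
#'   nearest frame (default `Inf`: never fall back).
#' @return List with `cluster` (NA on fallback), `frame`,
#'   `frame_fallback` (logical) and `distance`.
#' @export
match_external_representative <- function(coords, result, reference_point,
                                          radius = Inf) {
  coords <- as.matrix(coords)
  dc <- sqrt(rowSums(sweep(result$centroids, 2, reference_point)^2))
  best <- which.min(dc)
  if (dc[best] <= radius) {
    list(cluster = best, frame = result$representative_frames[best],
         frame_fallback = FALSE, distance = dc[best])
  } else {
    df <- sqrt(rowSums(sweep(coords, 2, reference_point)^2))
    fr <- which.min(df)
    list(cluster = NA_integer_, frame = fr, frame_fallback = TRUE,
         distance = df[fr])
  }
}
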