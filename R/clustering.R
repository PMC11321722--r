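#' Normalized scalar product between two synergy vectors
#'
#' Dot product of the l2-normalized vectors; 1 for identical shapes, 0 for
#' disjoint support.
#'
#' @param w1,w2 nonnegative numeric vectors of equal length.
#' @return scalar in `[0, 1]` for nonnegative inputs.
#' @export
scalar_product <- function(w1, w2) {
  if (length(w1) != length(w2)) stop("vectors must have equal length")
  n1 <- sqrt(sum(w1^2)); n2 <- sqrt(sum(w2^2))
  if (n1 == 0 || n2 == 0) stop("scalar product undefined for a zero vector")
  sum(w1 * w2) / (n1 * n2)
}

# mean silhouette under squared-Euclidean distance (the k-means metric)
mean_silhouette <- function(X, cluster) {
  n <- nrow(X)
  k <- length(unique(cluster))
  if (k < 2) return(NA_real_)
  d2 <- as.matrix(stats::dist(X))^2
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(d2[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(unique(cluster), cluster[i]),
                    function(cl) mean(d2[i, cluster == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Cluster synergy vectors by k-means with silhouette-selected k
#'
#' l2-normalizes the synergy vectors, runs squared-Euclidean k-means with
#' many random starts for each candidate cluster count, and selects the
#' count maximizing the mean silhouette value.
#'
#' @param W matrix of synergies, muscles x n (columns are synergy vectors),
#'   or a list of such matrices which are column-bound.
#' @param k_range candidate cluster counts; default `2:min(25, n - 1)`.
#' @param n_replicates random k-means starts per candidate k (default 5000).
#' @param seed integer seed; clustering is deterministic under it.
#' @return A `ClusterSolution`: list with `assignments`, `centroids`
#'   (muscles x k), `k`, `silhouette_by_k`, `n_replicates`.
#' @export
cluster_synergies <- function(W, k_range = NULL, n_replicates = 5000L,
                              seed = 1L) {
  if (is.list(W)) W <- do.call(cbind, W)
  n <- ncol(W)
  if (n < 2) stop("need at least 2 synergies to cluster")
  X <- t(apply(W, 2, function(v) {
    s <- sqrt(sum(v^2))
    if (s == 0) stop("cannot cluster a zero synergy vector")
    v / s
  }))
  if (is.null(k_range)) k_range <- 2:min(25L, n - 1L)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range is empty")
  n_distinct <- nrow(unique(round(X, 12)))
  if (n_distinct == 1) {
    warning("all synergy vectors identical; returning a single-cluster solution")
    return(structure(list(assignments = rep(1L, n),
                          centroids = matrix(X[1, ], ncol = 1,
                                             dimnames = list(rownames(W), NULL)),
                          k = 1L, silhouette_by_k = stats::setNames(NA_real_, "1"),
                          n_replicates = n_replicates),
                     class = "ClusterSolution"))
  }
  k_range <- k_range[k_range <= n_distinct]
  set.seed(seed)
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  sols <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    km <- stats::kmeans(X, centers = k_range[i], nstart = n_replicates,
                        iter.max = 100L)
    sols[[i]] <- km
    sil[i] <- mean_silhouette(X, km$cluster)
  }
  best <- which.max(sil)
  km <- sols[[best]]
  centroids <- t(km$centers)
  rownames(centroids) <- colnames(X)
  structure(list(assignments = unname(km$cluster), centroids = centroids,
                 k = k_range[best], silhouette_by_k = sil,
                 n_replicates = n_replicates),
            class = "ClusterSolution")
}

#' @export
print.ClusterSolution <- function(x, ...) {
  cat(sprintf("ClusterSolution: k = %d (mean silhouette %.3f), %d synergies\n",
              x$k, x$silhouette_by_k[as.character(x$k)],
              length(x$assignments)))
  invisible(x)
}

#' Match two centroid sets by best scalar product
#'
#' Greedy one-to-one pairing in descending scalar-product order. Pairs whose
#' scalar product does not exceed the threshold are reported unmatched, as
#' are leftover centroids when the sets differ in size. Greedy pairing
#' follows the best-matching convention; it can differ from the globally
#' optimal assignment on adversarial inputs.
#'
#' @param A,B centroid matrices, muscles x kA and muscles x kB.
#' @param threshold minimum scalar product for a pair to count as matched
#'   (default 0.8, strict).
#' @return list with `pairs` (data frame: `a`, `b`, `sp`), `unmatched_a`,
#'   `unmatched_b`.
#' @export
match_centroids <- function(A, B, threshold = 0.8) {
  kA <- ncol(A); kB <- ncol(B)
  sp <- matrix(0, kA, kB)
  for (i in seq_len(kA)) for (j in seq_len(kB))
    sp[i, j] <- scalar_product(A[, i], B[, j])
  pairs <- data.frame(a = integer(0), b = integer(0), sp = numeric(0))
  freeA <- rep(TRUE, kA); freeB <- rep(TRUE, kB)
  repeat {
    m <- sp * outer(freeA, freeB)
    if (!any(freeA) || !any(freeB)) break
    idx <- arrayInd(which.max(m), dim(m))
    i <- idx[1]; j <- idx[2]
    if (!freeA[i] || !freeB[j]) break
    pairs <- rbind(pairs, data.frame(a = i, b = j, sp = sp[i, j]))
    freeA[i] <- FALSE; freeB[j] <- FALSE
  }
  matched <- pairs$sp > threshold
  list(pairs = pairs[matched, , drop = FALSE],
       below_threshold = pairs[!matched, , drop = FALSE],
       unmatched_a = which(freeA), unmatched_b = which(freeB))
}

#' Flag clusters overlapping a normative centroid set
#'
#' A cluster is flagged when its best scalar product against any normative
#' centroid strictly exceeds the threshold; flagged clusters are the ones a
#' pathology-specific analysis excludes as indistinct from normal.
#'
#' @param centroids muscles x k matrix of cluster centroids under test.
#' @param normative_centroids muscles x m matrix of normative centroids.
#' @param threshold scalar-product threshold (default 0.8, strict).
#' @return logical vector of length k, with attribute `best_sp`.
#' @export
flag_normative_overlap <- function(centroids, normative_centroids,
                                   threshold = 0.8) {
  best <- apply(centroids, 2, function(w)
    max(apply(normative_centroids, 2, function(v) scalar_product(w, v))))
  structure(best > threshold, best_sp = best)
}
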