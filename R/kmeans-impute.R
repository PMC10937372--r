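#' k-means clustering with iterative imputation of missing z-scores
#'
#' Hard k-means (Lloyd's algorithm) on a z-score matrix with missing
#' entries, imputed iteratively. Iteration 1 draws each missing entry at
#' random from the phenotype's marginal empirical distribution (resampling
#' observed values); later iterations redraw missing entries from the
#' empirical distribution of the entry's phenotype within the SNV's current
#' cluster (falling back to the marginal when the cluster has no observed
#' value for that phenotype), so between-phenotype correlation enters
#' through the cluster conditioning. A penalty on imputed values decays
#' linearly from 1 at iteration 1 to 0 at iteration `n_end`: imputed values
#' are multiplied by `1 - penalty` when computing distances and centroids,
#' so early iterations down-weight them and the final iterations
#' (`n_end..n_iter`, penalty zero) use them at full value. The first
#' iteration takes the best of `n_start` k-means++ restarts by
#' within-cluster sum of squares; each outer iteration runs Lloyd's
#' algorithm to convergence from the previous centroids. After the outer
#' loop, a few penalty-free stabilization passes re-assign each SNV to its
#' nearest centroid measured on its *observed* coordinates only (mean
#' squared distance over non-missing phenotypes), re-impute conditional on
#' that assignment, and recompute centroids — removing the assignment
#' noise a single random imputation draw would otherwise inject. With no
#' missing entries the whole procedure reduces exactly to plain Lloyd
#' k-means (best of `n_start` k-means++ starts) under the same seed.
#'
#' @param Z Matrix (SNV x phenotype) with NAs for missing entries, e.g. an
#'   `mx_zmatrix`.
#' @param k Number of clusters (>= 1).
#' @param n_iter Outer iterations (default 10).
#' @param n_end Iterations over which the imputation penalty decays to zero
#'   (default 8, must be <= `n_iter`).
#' @param seed Integer seed for initialization and imputation draws.
#' @param n_start k-means++ restarts in the first iteration (default 5).
#' @param n_stabilize Final observed-coordinate stabilization passes
#'   (default 3).
#' @return An `mx_cluster_model`: list with `k`, `assignment` (named
#'   integer), `centroids` (k x phenotype), `imputed` (fully imputed
#'   matrix), `withinss`, `tot_withinss`, `distances` (SNV x cluster
#'   Euclidean distances, see [centroid_distances()]).
#' @export
impute_kmeans <- function(Z, k, n_iter = 10, n_end = 8, seed = 1,
                          n_start = 5, n_stabilize = 3) {
  Z <- unclass(Z)
  n <- nrow(Z)
  if (k < 1) abort("k must be >= 1")
  if (k > n) abort("k exceeds the number of SNVs")
  if (n_end > n_iter) abort("n_end must be <= n_iter")
  miss <- is.na(Z)
  set.seed(as.integer(seed))

  draw_marginal <- function(M) {
    for (j in which(colSums(miss) > 0)) {
      obs <- Z[!miss[, j], j]
      if (length(obs) == 0) abort(sprintf("phenotype %d has no observed value", j))
      M[miss[, j], j] <- sample(obs, sum(miss[, j]), replace = TRUE)
    }
    M
  }
  draw_conditional <- function(M, assignment) {
    for (j in which(colSums(miss) > 0)) {
      marg <- Z[!miss[, j], j]
      for (cl in unique(assignment[miss[, j]])) {
        rows <- which(miss[, j] & assignment == cl)
        obs <- Z[!miss[, j] & assignment == cl, j]
        pool <- if (length(obs) > 0) obs else marg
        M[rows, j] <- sample(pool, length(rows), replace = TRUE)
      }
    }
    M
  }

  centers <- NULL
  assignment <- NULL
  imp <- Z
  for (t in seq_len(n_iter)) {
    imp <- if (t == 1 || is.null(assignment)) draw_marginal(Z) else draw_conditional(Z, assignment)
    penalty <- if (n_end <= 1) 0 else max(0, 1 - (t - 1) / (n_end - 1))
    X <- imp
    X[miss] <- imp[miss] * (1 - penalty)
    if (is.null(centers)) {
      fit <- NULL
      for (s in seq_len(n_start)) {
        init <- X[kmeanspp_init(X, k), , drop = FALSE]
        cand <- lloyd_kmeans(X, init, iter_max = 100L)
        if (is.null(fit) || sum(cand$withinss) < sum(fit$withinss)) fit <- cand
      }
    } else {
      fit <- lloyd_kmeans(X, centers, iter_max = 100L)
    }
    centers <- fit$centers
    assignment <- fit$cluster
  }

  # stabilization: assignment by observed-coordinate distance, penalty-free
  if (any(miss) && n_stabilize > 0) {
    for (s in seq_len(n_stabilize)) {
      a2 <- vapply(seq_len(n), function(i) {
        ok <- !miss[i, ]
        d2 <- colSums((t(centers)[ok, , drop = FALSE] - Z[i, ok])^2) / sum(ok)
        which.min(d2)
      }, integer(1))
      imp <- draw_conditional(imp, a2)
      imp[!miss] <- Z[!miss]
      for (j in seq_len(k)) {
        rows <- a2 == j
        if (!any(rows)) next
        centers[j, ] <- colMeans(imp[rows, , drop = FALSE])
      }
      assignment <- a2
    }
    d2 <- sapply(seq_len(k), function(j) {
      rowSums((imp - matrix(centers[j, ], n, ncol(imp), byrow = TRUE))^2)
    })
    d2 <- matrix(d2, n, k)
    fit <- list(cluster = assignment, centers = centers,
                withinss = vapply(seq_len(k),
                                  function(j) sum(d2[assignment == j, j]),
                                  numeric(1)))
  }

  centroids <- fit$centers
  rownames(centroids) <- paste0("cluster_", seq_len(k))
  names(assignment) <- rownames(Z)
  model <- structure(list(
    k = k,
    assignment = assignment,
    centroids = centroids,
    imputed = imp,
    withinss = fit$withinss,
    tot_withinss = sum(fit$withinss),
    n_missing = sum(miss)
  ), class = "mx_cluster_model")
  model$distances <- centroid_distances(model)
  model
}

# k-means++ seeding: returns row indices of the initial centers
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k == 1) return(idx)
  d2 <- rowSums((X - matrix(X[idx[1], ], n, ncol(X), byrow = TRUE))^2)
  for (i in 2:k) {
    prob <- if (sum(d2) == 0) rep(1, n) else d2
    idx[i] <- sample.int(n, 1, prob = prob)
    d2_new <- rowSums((X - matrix(X[idx[i], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  idx
}

# plain Lloyd's algorithm; empty clusters are re-seeded at the point
# farthest from its assigned center (logged)
lloyd_kmeans <- function(X, centers, iter_max = 100L) {
  k <- nrow(centers)
  n <- nrow(X)
  prev <- rep(0L, n)
  for (it in seq_len(iter_max)) {
    d2 <- sapply(seq_len(k), function(j) {
      rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
    })
    d2 <- matrix(d2, n, k)
    cl <- max.col(-d2, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(cl))
    for (e in empty) {
      far <- which.max(d2[cbind(seq_len(n), cl)])
      cl[far] <- e
      mx_log("re-seeded empty cluster %d at the farthest point", e)
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[cl == j, , drop = FALSE])
    }
    if (identical(cl, prev)) break
    prev <- cl
  }
  d2 <- sapply(seq_len(k), function(j) {
    rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
  })
  d2 <- matrix(d2, n, k)
  withinss <- vapply(seq_len(k), function(j) sum(d2[cl == j, j]), numeric(1))
  list(cluster = cl, centers = centers, withinss = withinss)
}

#' @export
print.mx_cluster_model <- function(x, ...) {
  cat("<mx_cluster_model> k =", x$k, ";",
      length(x$assignment), "SNVs; sizes:",
      paste(tabulate(x$assignment, x$k), collapse = "/"),
      "; tot within-SS =", round(x$tot_withinss, 2), "\n")
  invisible(x)
}

#' Euclidean distances from each SNV to each cluster centroid
#'
#' `delta_jk = sqrt(sum_i (Z_ij - mu_ik)^2)` over phenotypes `i`, computed
#' on the fully imputed z-score matrix.
#'
#' @param model An `mx_cluster_model`.
#' @return Matrix (SNV x cluster) of distances.
#' @export
centroid_distances <- function(model) {
  X <- model$imputed
  d <- vapply(seq_len(model$k), function(j) {
    unname(sqrt(rowSums((X - matrix(model$centroids[j, ], nrow(X), ncol(X),
                                    byrow = TRUE))^2)))
  }, numeric(nrow(X)))
  d <- matrix(d, nrow = nrow(X), ncol = model$k,
              dimnames = list(rownames(X),
                              paste0("cluster_", seq_len(model$k))))
  d
}
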