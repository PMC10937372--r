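#' Choose the number of clusters by majority vote of validity indices
#'
#' Runs [impute_kmeans()] for each candidate `k` and scores the resulting
#' partitions with a battery of cluster-validity indices, each voting for
#' its optimal `k` by its native rule:
#'
#' * Calinski-Harabasz (max), silhouette width (max), Davies-Bouldin (min),
#'   Dunn (max), C-index (min), gap statistic (Tibshirani one-SE rule),
#'   Hartigan (smallest `k` with statistic <= 10), Krzanowski-Lai (max).
#'
#' The modal vote wins; ties break to the smaller `k`. A single-element
#' `k_range` is returned as-is (degenerate vote).
#'
#' @param Z Z-score matrix with possible NAs.
#' @param k_range Integer vector of candidate cluster counts (within
#'   `[2, nrow(Z) - 1]`).
#' @param seed Integer seed shared by every `k`'s fit.
#' @param n_iter,n_end Passed to [impute_kmeans()].
#' @param n_gap_ref Reference datasets for the gap statistic (default 20).
#' @return List: `k` (chosen), `votes` (tibble index, k), `models` (named
#'   list of fitted `mx_cluster_model`s for each candidate `k`).
#' @export
select_k <- function(Z, k_range, seed = 1, n_iter = 10, n_end = 8,
                     n_gap_ref = 20) {
  if (length(k_range) == 0) abort("empty k_range")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > nrow(Z) - 1) {
    abort("k_range must lie within [2, n_SNVs - 1]")
  }
  if (length(k_range) == 1) {
    model <- impute_kmeans(Z, k_range, n_iter, n_end, seed)
    return(list(k = k_range, votes = tibble::tibble(index = "degenerate",
                                                    k = k_range),
                models = setNames(list(model), k_range)))
  }
  # fit over an extended range so difference-based indices (Hartigan,
  # Krzanowski-Lai, gap one-SE) have their neighbours available
  k_ext <- sort(unique(c(k_range, max(2, min(k_range) - 1), max(k_range) + 1)))
  k_ext <- k_ext[k_ext <= nrow(Z) - 1]
  models <- lapply(k_ext, function(k) impute_kmeans(Z, k, n_iter, n_end, seed))
  names(models) <- k_ext

  W <- vapply(models, function(m) m$tot_withinss, numeric(1))
  X_by_k <- lapply(models, function(m) m$imputed)

  score_tbl <- purrr::map_dfr(as.character(k_range), function(kc) {
    m <- models[[kc]]
    validity_indices(m$imputed, m$assignment, m$centroids)
  })
  score_tbl$k <- k_range

  vote <- list()
  vote$calinski_harabasz <- k_range[which.max(score_tbl$calinski_harabasz)]
  vote$silhouette <- k_range[which.max(score_tbl$silhouette)]
  vote$davies_bouldin <- k_range[which.min(score_tbl$davies_bouldin)]
  vote$dunn <- k_range[which.max(score_tbl$dunn)]
  vote$c_index <- k_range[which.min(score_tbl$c_index)]
  vote$hartigan <- hartigan_vote(W, k_range, n = nrow(Z))
  vote$krzanowski_lai <- kl_vote(W, k_range, p = ncol(Z))
  vote$gap <- gap_vote(X_by_k, models, k_range, n_gap_ref, seed)

  votes <- tibble::tibble(index = names(vote), k = unlist(vote))
  tab <- table(votes$k)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k = min(winners), votes = votes,
       models = models[as.character(k_range)])
}

# one row of internal validity indices for a hard partition
validity_indices <- function(X, cl, centroids) {
  n <- nrow(X)
  k <- nrow(centroids)
  grand <- colMeans(X)
  sizes <- tabulate(cl, k)
  wss <- sum(vapply(seq_len(k), function(j) {
    sum(sweep(X[cl == j, , drop = FALSE], 2, centroids[j, ])^2)
  }, numeric(1)))
  bss <- sum(sizes * rowSums(sweep(centroids, 2, grand)^2))
  ch <- (bss / (k - 1)) / (wss / (n - k))

  d <- as.matrix(stats::dist(X))
  sil <- mean(cluster::silhouette(cl, dmatrix = d)[, "sil_width"])

  # Davies-Bouldin
  s <- vapply(seq_len(k), function(j) {
    mean(sqrt(rowSums(sweep(X[cl == j, , drop = FALSE], 2, centroids[j, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(centroids))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (s[i] + s[j]) / cd[i, j], numeric(1)))
  }, numeric(1)))

  # Dunn: min between-cluster point distance / max within-cluster diameter
  same <- outer(cl, cl, "==")
  diag(d) <- NA
  min_between <- min(d[!same], na.rm = TRUE)
  max_within <- max(d[same & !is.na(d)], na.rm = TRUE)
  dunn <- min_between / max_within

  # C-index: (S - Smin)/(Smax - Smin) over within-cluster pairs
  dv <- d[upper.tri(d)]
  within <- same[upper.tri(same)]
  nw <- sum(within)
  S <- sum(dv[within])
  ds <- sort(dv)
  smin <- sum(ds[seq_len(nw)])
  smax <- sum(ds[seq.int(length(ds) - nw + 1L, length(ds))])
  cindex <- (S - smin) / (smax - smin)

  tibble::tibble(calinski_harabasz = ch, silhouette = sil,
                 davies_bouldin = db, dunn = dunn, c_index = cindex)
}

# H(k) = (W_k / W_{k+1} - 1)(n - k - 1); classic rule: smallest k with
# H(k) <= 10, else the k minimizing H
hartigan_vote <- function(W, k_range, n) {
  ks <- as.integer(names(W))
  h <- vapply(k_range, function(k) {
    if (!((k + 1) %in% ks)) return(Inf)
    (W[as.character(k)] / W[as.character(k + 1)] - 1) * (n - k - 1)
  }, numeric(1))
  ok <- which(h <= 10)
  if (length(ok) > 0) k_range[min(ok)] else k_range[which.min(h)]
}

kl_vote <- function(W, k_range, p) {
  ks <- as.integer(names(W))
  diffk <- function(k) {
    if (!((k - 1) %in% ks) || !(k %in% ks)) return(NA_real_)
    (k - 1)^(2 / p) * W[as.character(k - 1)] - k^(2 / p) * W[as.character(k)]
  }
  kl <- vapply(k_range, function(k) {
    d1 <- diffk(k); d2 <- diffk(k + 1)
    if (is.na(d1) || is.na(d2) || d2 == 0) return(NA_real_)
    abs(d1) / abs(d2)
  }, numeric(1))
  if (all(is.na(kl))) return(min(k_range))
  k_range[which.max(kl)]
}

gap_vote <- function(X_by_k, models, k_range, n_ref, seed) {
  # gap statistic with uniform reference over the bounding box of the
  # imputed data at the smallest k; one-SE rule
  X <- X_by_k[[as.character(min(k_range))]]
  rng <- apply(X, 2, range)
  set.seed(derive_seed(seed, "gap"))
  logW_ref <- matrix(NA_real_, n_ref, length(k_range))
  for (b in seq_len(n_ref)) {
    Xb <- apply(rng, 2, function(r) runif(nrow(X), r[1], r[2]))
    for (i in seq_along(k_range)) {
      fit <- lloyd_kmeans(Xb, Xb[kmeanspp_init(Xb, k_range[i]), , drop = FALSE],
                          iter_max = 25L)
      logW_ref[b, i] <- log(sum(fit$withinss))
    }
  }
  logW <- log(vapply(as.character(k_range),
                     function(kc) models[[kc]]$tot_withinss, numeric(1)))
  gap <- colMeans(logW_ref) - logW
  se <- apply(logW_ref, 2, stats::sd) * sqrt(1 + 1 / n_ref)
  for (i in seq_along(k_range)[-length(k_range)]) {
    if (gap[i] >= gap[i + 1] - se[i + 1]) return(k_range[i])
  }
  k_range[length(k_range)]
}
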