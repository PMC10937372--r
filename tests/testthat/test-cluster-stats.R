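fit_planted_model <- function(seed = 81, missing = 0.1, n = 150) {
  cents <- rbind(c(3, 0, -3, 0, 0), c(-3, 3, 0, 0, 0), c(0, -3, 3, 0, 0))
  cfg <- sim_config(n_clusters_true = 3, cluster_centroids = cents,
                    missing_rate = missing, seed = seed)
  zs <- simulate_phenotype_zscores(cfg, n_index = n)
  model <- impute_kmeans(zs$zmatrix, k = 3, seed = 1)
  list(zs = zs, model = model, cents = cents)
}

test_that("gamma equals the within-cluster mean (no-intercept indicator identity)", {
  f <- fit_planted_model()
  prof <- cluster_phenotype_association(f$model)
  for (i in seq_len(ncol(f$model$imputed))) {
    for (k in 1:3) {
      g <- prof$gamma[prof$phenotype == colnames(f$model$imputed)[i] &
                        prof$cluster == k]
      expect_equal(g, mean(f$model$imputed[f$model$assignment == k, i]),
                   tolerance = 1e-10)
    }
  }
  # matches the OLS oracle (lm on indicators)
  i <- 2
  z <- f$model$imputed[, i]
  cl <- factor(f$model$assignment)
  o <- summary(stats::lm(z ~ 0 + cl))$coefficients
  sub <- prof[prof$phenotype == colnames(f$model$imputed)[i], ]
  expect_equal(sub$gamma, unname(o[, 1]), tolerance = 1e-10)
  expect_equal(sub$p, unname(o[, 4]), tolerance = 1e-10)
  # temperature convention
  expect_equal(sub$temperature, sign(sub$gamma) * (-log10(sub$p)))
})

test_that("k = 1 profile returns the overall mean; all-zero matrix gives zero temperatures", {
  Z <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("p", 1:3)))
  m1 <- impute_kmeans(Z, k = 1, seed = 1)
  prof <- cluster_phenotype_association(m1)
  expect_equal(prof$gamma, unname(colMeans(Z)), tolerance = 1e-10)

  Z0 <- matrix(0, 30, 2, dimnames = list(NULL, c("a", "b")))
  m0 <- impute_kmeans(Z0, k = 1, seed = 1)
  p0 <- cluster_phenotype_association(m0)
  expect_equal(p0$gamma, c(0, 0))
  expect_true(all(p0$temperature == 0 | is.na(p0$temperature)))
})

test_that("centroid distances are exact Euclidean distances", {
  f <- fit_planted_model(seed = 82)
  d <- centroid_distances(f$model)
  # direct-summation oracle
  for (j in sample(nrow(d), 10)) {
    for (k in 1:3) {
      expect_equal(d[j, k],
                   sqrt(sum((f$model$imputed[j, ] - f$model$centroids[k, ])^2)),
                   tolerance = 1e-12)
    }
  }
  # an SNV placed exactly at a centroid has distance 0
  m <- f$model
  m$imputed[1, ] <- m$centroids[2, ]
  expect_equal(centroid_distances(m)[1, 2], 0)
  # one phenotype, z = 3 vs centroid 1 -> delta = 2
  m2 <- list(imputed = matrix(3, 1, 1), centroids = matrix(1, 1, 1), k = 1)
  expect_equal(unname(centroid_distances(m2)[1, 1]), 2)
})

test_that("disparity PCA conserves variance and matches eigendecomposition up to sign", {
  f <- fit_planted_model(seed = 83)
  pca <- disparity_pca(f$model)
  expect_equal(sum(pca$variance_explained), 1, tolerance = 1e-12)

  X <- scale(f$model$imputed, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)
  scores_oracle <- X %*% ev$vectors
  for (cmp in 1:3) {
    got <- pca$scores[[paste0("PC", cmp)]]
    expect_true(isTRUE(all.equal(got, scores_oracle[, cmp], tolerance = 1e-8,
                                 check.attributes = FALSE)) ||
                  isTRUE(all.equal(got, -scores_oracle[, cmp], tolerance = 1e-8,
                                   check.attributes = FALSE)))
  }

  # rank-1 matrix: PC1 explains everything
  u <- rnorm(50); v <- rnorm(4)
  m_r1 <- list(imputed = outer(u, v), k = 1,
               assignment = rep(1, 50), centroids = matrix(0, 1, 4))
  p1 <- disparity_pca(m_r1)
  expect_equal(p1$variance_explained[1], 1, tolerance = 1e-8)
})

test_that("cluster disease-effect heterogeneity is zero for equal betas and matches the WLS oracle", {
  f <- fit_planted_model(seed = 84)
  n <- length(f$model$assignment)
  eq <- cluster_t2d_effects(rep(0.04, n), rep(0.004^2, n), f$model)
  expect_lt(eq$heterogeneity$chisq, 1e-10)
  expect_equal(eq$heterogeneity$p, 1)

  set.seed(84)
  betas <- abs(rnorm(n, 0.03, 0.01))
  vars <- runif(n, 0.003, 0.005)^2
  r <- cluster_t2d_effects(betas, vars, f$model)
  X <- stats::model.matrix(~ 0 + factor(f$model$assignment))
  o <- wls_oracle(betas, sqrt(vars), X)
  o0 <- wls_oracle(betas, sqrt(vars), matrix(1, n, 1))
  expect_equal(r$effects$gamma, unname(o$coef), tolerance = 1e-10)
  expect_equal(r$effects$se, unname(o$se), tolerance = 1e-10)
  expect_equal(r$heterogeneity$chisq, o0$rss - o$rss, tolerance = 1e-8)

  one <- f$model; one$assignment[] <- 1L
  expect_error(cluster_t2d_effects(betas, vars, one), "one cluster")
})

test_that("a planted difference in cluster mean ORs is detected and recovered", {
  # two clusters with mean ORs 1.033 vs 1.028 at realistic precision
  set.seed(85)
  n_per <- 650
  b1 <- rnorm(n_per, log(1.033), 0.002)
  b2 <- rnorm(n_per, log(1.028), 0.002)
  betas <- c(b1, b2)
  vars <- rep(0.004^2, 2 * n_per)
  model <- list(k = 2, assignment = rep(1:2, each = n_per),
                imputed = matrix(0, 2 * n_per, 1),
                centroids = matrix(0, 2, 1))
  class(model) <- "mx_cluster_model"
  flags <- rep(c(TRUE, FALSE), each = n_per)
  r <- cluster_t2d_effects(betas, vars, model, reported_flags = flags)
  diff_true <- log(1.033) - log(1.028)
  est_diff <- r$effects$gamma[1] - r$effects$gamma[2]
  se_diff <- sqrt(sum(r$effects$se^2))
  expect_lt(abs(est_diff - diff_true), 2 * se_diff)
  expect_lt(r$heterogeneity$p, 0.05)
  # the two-group contrast sees the same difference
  con <- r$contrast[r$contrast$term == "greported", ]
  expect_lt(abs(con$estimate - est_diff), 1e-10)
})

test_that("axis ANOVA is calibrated under the null and powered under a shift", {
  model3 <- function(assignment) {
    structure(list(k = 3, assignment = assignment,
                   imputed = matrix(0, length(assignment), 1),
                   centroids = matrix(0, 3, 1)),
              class = "mx_cluster_model")
  }
  set.seed(86)
  n_rep <- 400
  assignment <- rep(1:3, each = 50)
  p_null <- vapply(seq_len(n_rep), function(i) {
    z <- matrix(rnorm(150), ncol = 1, dimnames = list(NULL, "z_axis1"))
    cluster_axis_anova(z, model3(assignment))$p
  }, numeric(1))
  rej <- mean(p_null < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
  expect_gt(suppressWarnings(stats::ks.test(p_null, "punif")$p.value), 0.01)

  assignment2 <- rep(1:2, each = 100)
  p_shift <- vapply(1:50, function(i) {
    z <- matrix(c(rnorm(100, 1), rnorm(100, 0)), ncol = 1,
                dimnames = list(NULL, "z_axis1"))
    m <- model3(assignment2); m$k <- 2
    cluster_axis_anova(z, m)$p
  }, numeric(1))
  expect_gte(mean(p_shift < 1e-6), 0.95)

  m1 <- model3(rep(1, 10)); m1$k <- 1
  expect_error(cluster_axis_anova(matrix(rnorm(10), ncol = 1), m1),
               "2 clusters")
})
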