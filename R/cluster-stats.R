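#' Cluster-phenotype association profiles
#'
#' Per phenotype, regresses the imputed z-scores on the cluster indicator
#' variables without an intercept, so each coefficient `gamma_ik` equals
#' the within-cluster mean of the imputed z for that phenotype. P values
#' come from the coefficient t-test; the heat-map temperature is
#' `sign(gamma) * (-log10 P)`. Clusters with fewer than two members keep
#' their coefficient but have P (and temperature) set missing.
#'
#' @param model An `mx_cluster_model` from [impute_kmeans()].
#' @return An `mx_cluster_profile` tibble: phenotype, cluster, gamma, se,
#'   p, temperature.
#' @export
cluster_phenotype_association <- function(model) {
  X <- model$imputed
  cl <- factor(model$assignment, levels = seq_len(model$k))
  sizes <- as.integer(table(cl))
  out <- purrr::map_dfr(seq_len(ncol(X)), function(i) {
    fit <- if (model$k == 1) {
      stats::lm(X[, i] ~ 1)  # intercept-only: gamma = overall mean
    } else {
      stats::lm(X[, i] ~ 0 + cl)
    }
    sm <- summary(fit)$coefficients
    tibble::tibble(
      phenotype = colnames(X)[i] %||% paste0("phen_", i),
      cluster = seq_len(model$k),
      gamma = unname(sm[, 1]),
      se = ifelse(sizes < 2, NA_real_, unname(sm[, 2])),
      p = ifelse(sizes < 2, NA_real_, unname(sm[, 4]))
    )
  })
  out <- dplyr::mutate(out, temperature = sign(.data$gamma) * (-log10(.data$p)))
  class(out) <- c("mx_cluster_profile", class(out))
  out
}

#' Principal components of the imputed z-score matrix
#'
#' Column-centres the fully imputed z-score matrix and decomposes it, to
#' display cluster disparity in a low-dimensional projection.
#'
#' @param model An `mx_cluster_model`.
#' @param n_components Components to return (default all).
#' @return List: `scores` (tibble snv, cluster, PC columns),
#'   `variance_explained` (fractions summing to 1 over all components),
#'   `rotation`.
#' @export
disparity_pca <- function(model, n_components = NULL) {
  pc <- stats::prcomp(model$imputed, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  nc <- n_components %||% ncol(pc$x)
  scores <- tibble::tibble(
    snv = rownames(model$imputed) %||% as.character(seq_len(nrow(model$imputed))),
    cluster = unname(model$assignment)
  ) %>%
    dplyr::bind_cols(tibble::as_tibble(pc$x[, seq_len(nc), drop = FALSE]))
  list(scores = scores, variance_explained = ve,
       rotation = pc$rotation)
}

#' Cluster-specific disease effects of index SNVs
#'
#' Weighted regression (weights = inverse variance of the allelic effect)
#' of risk-allele-aligned log-ORs on the cluster indicators without an
#' intercept; heterogeneity in cluster effects is tested by the deviance
#' difference against the intercept-only weighted fit, chi-square on
#' `k - 1` df. When `reported_flags` is given, a two-group contrast
#' replaces the indicators with a reported/novel flag.
#'
#' @param betas Risk-allele-aligned log-ORs per index SNV.
#' @param variances Variances of the allelic effects.
#' @param model An `mx_cluster_model` (defines the partition; SNV order
#'   must match `betas`).
#' @param reported_flags Optional logical vector: SNV maps to a previously
#'   reported locus.
#' @return List: `effects` (tibble cluster, gamma, se, p),
#'   `heterogeneity` (one-row tibble chisq, df, p), and `contrast`
#'   (reported-vs-novel tibble, when flags are given).
#' @export
cluster_t2d_effects <- function(betas, variances, model, reported_flags = NULL) {
  if (any(variances <= 0)) abort("variances must be positive")
  cl <- factor(model$assignment, levels = seq_len(model$k))
  if (length(unique(cl)) < 2) {
    abort("heterogeneity is undefined with all SNVs in one cluster")
  }
  w <- 1 / variances

  fit_full <- stats::lm(betas ~ 0 + cl, weights = w)
  fit_null <- stats::lm(betas ~ 1, weights = w)
  rss_full <- sum(w * stats::residuals(fit_full)^2)
  rss_null <- sum(w * stats::residuals(fit_null)^2)
  chisq <- rss_null - rss_full
  df <- model$k - 1
  sm <- summary(fit_full)$coefficients
  # SEs on the known-weights (inverse-variance) scale, not rescaled by the
  # residual dispersion
  se_known <- sqrt(diag(chol2inv(chol(crossprod(
    sqrt(w) * stats::model.matrix(fit_full))))))
  gamma <- unname(sm[, 1])
  eff <- tibble::tibble(
    cluster = seq_len(model$k),
    gamma = gamma,
    se = se_known,
    p = 2 * pnorm(-abs(gamma / se_known))
  )
  out <- list(
    effects = eff,
    heterogeneity = tibble::tibble(
      chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE)
    )
  )
  if (!is.null(reported_flags)) {
    g <- factor(ifelse(reported_flags, "reported", "novel"),
                levels = c("novel", "reported"))
    fit_c <- stats::lm(betas ~ g, weights = w)
    Xc <- stats::model.matrix(fit_c)
    se_c <- sqrt(diag(chol2inv(chol(crossprod(sqrt(w) * Xc)))))
    cf <- stats::coef(fit_c)
    out$contrast <- tibble::tibble(
      term = names(cf), estimate = unname(cf), se = se_c,
      p = 2 * pnorm(-abs(cf / se_c))
    )
  }
  out
}

#' ANOVA of axis z-scores across clusters
#'
#' For each ancestry axis, compares the intercept-only linear model of the
#' per-SNV axis z-score against the cluster-indicator model by F-test,
#' asking whether ancestry-correlated heterogeneity differs between
#' mechanistic clusters.
#'
#' @param axis_zscores Tibble from [axis_association_zscores()] (columns
#'   `z_axis*`, rows matching the model's SNV order) or a numeric matrix.
#' @param model An `mx_cluster_model` with at least 2 clusters.
#' @return Tibble: axis, f, df1, df2, p.
#' @export
cluster_axis_anova <- function(axis_zscores, model) {
  if (model$k < 2) abort("at least 2 clusters required")
  zcols <- if (is.matrix(axis_zscores)) {
    as.data.frame(axis_zscores)
  } else {
    axis_zscores[grep("^z_axis", names(axis_zscores), value = TRUE)]
  }
  cl <- factor(model$assignment, levels = seq_len(model$k))
  purrr::map_dfr(seq_along(zcols), function(i) {
    z <- zcols[[i]]
    a <- stats::anova(stats::lm(z ~ 1), stats::lm(z ~ cl))
    tibble::tibble(
      axis = names(zcols)[i] %||% paste0("axis", i),
      f = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
      p = a$`Pr(>F)`[2]
    )
  })
}
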