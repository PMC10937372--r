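#' Variant QC filter for polygenic scoring
#'
#' Retains an index SNV iff MAF >= 1%, imputation r-squared >= 0.7, and
#' Hardy-Weinberg exact P >= 1e-6. Exclusions are returned with a reason
#' (first failing rule in that order) and logged. The filter is idempotent.
#'
#' @param variant_stats Tibble: snv, maf, info_r2, hwe_p (NA in a column
#'   means the rule is not applied to that SNV, e.g. array data without
#'   imputation quality).
#' @param maf_min,info_min,hwe_min Rule thresholds (inclusive retention
#'   boundaries).
#' @return List: `retained` (tibble of passing rows), `excluded` (tibble
#'   with a `reason` column).
#' @export
qc_filter_snvs <- function(variant_stats, maf_min = 0.01, info_min = 0.7,
                           hwe_min = 1e-6) {
  vs <- variant_stats %>%
    dplyr::mutate(
      reason = dplyr::case_when(
        !is.na(.data$maf) & .data$maf < maf_min ~ "MAF < 1%",
        !is.na(.data$info_r2) & .data$info_r2 < info_min ~ "imputation r2 < 0.7",
        !is.na(.data$hwe_p) & .data$hwe_p < hwe_min ~ "HWE P < 1e-6",
        TRUE ~ NA_character_
      )
    )
  excluded <- dplyr::filter(vs, !is.na(.data$reason))
  if (nrow(excluded) > 0) {
    mx_log("excluded %d SNVs from the PS (%s)", nrow(excluded),
           paste(sprintf("%s: %d", names(table(excluded$reason)),
                         table(excluded$reason)), collapse = "; "))
  }
  list(
    retained = dplyr::select(dplyr::filter(vs, is.na(.data$reason)), -"reason"),
    excluded = excluded
  )
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test: given the allele counts, sums the probabilities
#' of all heterozygote counts whose conditional probability does not
#' exceed that of the observed count. Probabilities follow the standard
#' recurrence over heterozygote counts of the same parity.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return Exact P value (1 for monomorphic samples).
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) abort("total genotype count must be positive")
  n_a <- 2 * n_aa + n_Aa  # minor-ish allele count (use the rarer one)
  if (n_a > n) {
    # swap homozygote roles so n_a is the rarer allele count
    tmp <- n_AA; n_AA <- n_aa; n_aa <- tmp
    n_a <- 2 * n_aa + n_Aa
  }
  if (n_a == 0) return(1)
  # possible heterozygote counts share the parity of the rare allele count
  het_values <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  # unnormalized log probabilities via the conditional hypergeometric form
  logp <- vapply(het_values, function(h) {
    hom_rare <- (n_a - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_rare + 1) -
      lgamma(hom_common + 1) + h * log(2)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[het_values == n_Aa]
  min(1, sum(prob[prob <= p_obs + 1e-12]))
}

#' Compute overall and cluster-partitioned polygenic scores
#'
#' Raw cluster score of individual *i* = `sum_{j in cluster} w_j d_ij`
#' with the dosage aligned to the risk allele; the raw overall score is
#' the sum over all SNVs, so by construction it equals the sum of the raw
#' cluster scores. Each score is then standardized to mean zero and unit
#' variance within the analysis cohort. Missing dosages are mean-imputed
#' per SNV before scoring.
#'
#' @param cohort An `mx_cohort` (or list with `dosages`, `snvs`, `samples`).
#' @param ps_model Tibble: snv, risk_allele, cluster, weight — weights are
#'   the ancestry-specific fixed-effects pooled log-ORs.
#' @return Tibble: sample_id, `overall`, one `cluster_<id>` column per
#'   cluster (standardized); attribute `raw` holds the unstandardized
#'   matrix.
#' @export
compute_partitioned_ps <- function(cohort, ps_model) {
  idx <- match(ps_model$snv, colnames(cohort$dosages))
  if (anyNA(idx)) abort("ps_model contains SNVs absent from the cohort dosages")
  dos <- cohort$dosages[, idx, drop = FALSE]
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    for (j in seq_len(ncol(dos))) dos[is.na(dos[, j]), j] <- mu[j]
  }
  ea <- cohort$snvs$ea[match(ps_model$snv, cohort$snvs$snv)]
  flip <- ps_model$risk_allele != ea
  dos[, flip] <- 2 - dos[, flip, drop = FALSE]

  clusters <- sort(unique(as.character(ps_model$cluster)))
  raw <- sapply(clusters, function(cl) {
    j <- which(as.character(ps_model$cluster) == cl)
    drop(dos[, j, drop = FALSE] %*% ps_model$weight[j])
  })
  raw <- cbind(overall = rowSums(raw), raw)
  colnames(raw) <- c("overall", paste0("cluster_", clusters))
  sds <- apply(raw, 2, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance score: %s",
                  paste(colnames(raw)[sds == 0], collapse = ", ")))
  }
  std <- scale(raw)
  out <- tibble::tibble(sample_id = cohort$samples$sample_id) %>%
    dplyr::bind_cols(tibble::as_tibble(std))
  attr(out, "raw") <- raw
  out
}

#' Associate polygenic scores with an outcome
#'
#' Generalized linear model (logistic for binary outcomes, linear for
#' quantitative ones such as age of onset) of the outcome on each
#' cluster-specific score in turn, adjusted for the overall score (when
#' `adjust_overall`) and covariates; an `overall` row fits the overall
#' score without cluster terms. Scores are standardized, so effects are
#' per SD. Under complete separation the logistic fit falls back to Firth
#' bias-reduced regression, flagged in the output.
#'
#' @param scores Tibble from [compute_partitioned_ps()].
#' @param cohort An `mx_cohort` providing the outcome and covariates.
#' @param outcome Column name in `cohort$samples`.
#' @param family `"binomial"` or `"gaussian"`.
#' @param covariates Character vector of covariate columns (default age,
#'   sex).
#' @param adjust_overall Adjust cluster terms for the overall score
#'   (default TRUE).
#' @return Tibble of `mx_ps_result` rows: outcome, score, estimate, se, p,
#'   n, method.
#' @export
associate_outcome <- function(scores, cohort, outcome,
                              family = c("binomial", "gaussian"),
                              covariates = c("age", "sex"),
                              adjust_overall = TRUE) {
  family <- match.arg(family)
  df <- dplyr::left_join(scores, cohort$samples, by = "sample_id")
  y <- df[[outcome]]
  if (length(unique(stats::na.omit(y))) < 2) abort("outcome is constant")
  score_cols <- setdiff(grep("^cluster_", names(scores), value = TRUE), "overall")

  fit_one <- function(cols) {
    X <- as.matrix(df[, unique(c(cols, covariates)), drop = FALSE])
    if (qr(cbind(1, X))$rank < ncol(X) + 1) abort("rank-deficient design")
    dat <- data.frame(y = y, X, check.names = FALSE)
    fm <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", colnames(X)),
                                               collapse = " + ")))
    method <- "glm"
    fit <- stats::glm(fm, data = dat, family = family)
    est <- summary(fit)$coefficients
    if (family == "binomial" &&
        (!fit$converged || any(abs(est[-1, 1]) > 15))) {
      # separation fallback: Firth bias-reduced fit
      ff <- firth_logistic(y, cbind(`(Intercept)` = 1, X))
      est <- cbind(ff$coef, ff$se, ff$coef / ff$se,
                   2 * pnorm(-abs(ff$coef / ff$se)))
      method <- "firth"
    }
    tibble::tibble(
      score = cols[1],
      estimate = est[cols[1], 1],
      se = est[cols[1], 2],
      p = est[cols[1], 4],
      n = sum(!is.na(y)),
      method = method
    )
  }

  rows <- purrr::map_dfr(score_cols, function(sc) {
    fit_one(c(sc, if (adjust_overall) "overall"))
  })
  rows <- dplyr::bind_rows(fit_one("overall"), rows)
  dplyr::mutate(rows, outcome = outcome, family = family, .before = 1)
}

#' Random-effects meta-analysis across ancestry groups
#'
#' DerSimonian-Laird: Cochran's Q from fixed-effects weights,
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`, and
#' the pooled estimate re-weighted by `1 / (se^2 + tau2)`.
#'
#' @param estimates,ses Per-group effect estimates and SEs.
#' @return One-row tibble: estimate, se, z, p, tau2, q, df_q, p_q,
#'   n_groups.
#' @export
random_effects_meta <- function(estimates, ses) {
  if (length(estimates) < 1) abort("at least one group required")
  if (any(ses <= 0)) abort("SEs must be positive")
  w <- 1 / ses^2
  fixed <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - fixed)^2)
  df_q <- length(estimates) - 1
  c_w <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (df_q > 0 && c_w > 0) max(0, (q - df_q) / c_w) else 0
  w_star <- 1 / (ses^2 + tau2)
  est <- sum(w_star * estimates) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  z <- est / se
  tibble::tibble(
    estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z)),
    tau2 = tau2, q = q, df_q = df_q,
    p_q = if (df_q > 0) pchisq(q, df_q, lower.tail = FALSE) else NA_real_,
    n_groups = length(estimates)
  )
}
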