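#' Meta-regression of one SNV's allelic effects on ancestry axes
#'
#' Aggregates inverse-variance-weighted allelic effects across studies by
#' weighted least squares of the per-study log-ORs on an intercept, the
#' axes of genetic variation, and optional extra covariates, with weights
#' `1/se^2`. Letting `RSS(M)` be the weighted residual sum of squares of
#' model `M`, three chi-square tests partition the total weighted variation:
#'
#' * association: `sum(w b^2) - RSS(full)`, df = number of fitted
#'   coefficients (intercept + covariates);
#' * ancestry-correlated heterogeneity: `RSS(baseline) - RSS(full)` where
#'   the baseline holds the intercept and the extra covariates but not the
#'   axes, df = number of axes;
#' * residual heterogeneity: `RSS(full)`, df = K - 1 - covariates.
#'
#' The two heterogeneity statistics sum to Cochran's Q of the intercept-only
#' weighted fit when there are no extra covariates. Standard errors are
#' taken as fixed (known-weights convention).
#'
#' @param betas,ses Numeric vectors of per-study log-ORs and standard errors.
#' @param axes Numeric matrix (study x axis) of ancestry-axis coordinates,
#'   or `NULL` for none.
#' @param extra_covariates Numeric matrix of additional study-level
#'   covariates entering both the baseline and the full model (e.g. mean
#'   BMI), or `NULL`.
#' @return A one-row tibble: coefficients and SEs (list-columns `coef`,
#'   `coef_se`), `chisq_assoc`/`df_assoc`/`p_assoc`,
#'   `chisq_anc_het`/`df_anc_het`/`p_anc_het`,
#'   `chisq_res_het`/`df_res_het`/`p_res_het`, `n_studies`.
#' @export
meta_regress_snv <- function(betas, ses, axes = NULL, extra_covariates = NULL) {
  k <- length(betas)
  if (any(ses <= 0)) abort("all standard errors must be positive")
  ax <- if (is.null(axes)) matrix(0, k, 0) else as.matrix(axes)
  ex <- if (is.null(extra_covariates)) matrix(0, k, 0) else as.matrix(extra_covariates)
  n_cov <- ncol(ax) + ncol(ex)
  if (k < n_cov + 3) {
    abort("need at least two more studies than fitted coefficients")
  }
  w <- 1 / ses^2

  X_full <- cbind(`(Intercept)` = 1, ex, ax)
  X_base <- cbind(`(Intercept)` = 1, ex)
  qrf <- qr(X_full * sqrt(w))
  if (qrf$rank < ncol(X_full)) {
    abort("singular design: collinear axes/covariates")
  }

  wls_rss <- function(X) {
    fit <- stats::lm.wfit(X, betas, w)
    sum(w * fit$residuals^2)
  }
  fit_full <- stats::lm.wfit(X_full, betas, w)
  rss_full <- sum(w * fit_full$residuals^2)
  rss_base <- wls_rss(X_base)
  total <- sum(w * betas^2)

  xtwx_inv <- chol2inv(qr.R(qrf))
  coef_se <- sqrt(diag(xtwx_inv))
  names(coef_se) <- colnames(X_full)

  chisq_assoc <- max(total - rss_full, 0)
  df_assoc <- 1 + n_cov
  chisq_anc <- max(rss_base - rss_full, 0)
  df_anc <- ncol(ax)
  chisq_res <- max(rss_full, 0)
  df_res <- k - 1 - n_cov

  tibble::tibble(
    coef = list(fit_full$coefficients),
    coef_se = list(coef_se),
    chisq_assoc = chisq_assoc, df_assoc = df_assoc,
    p_assoc = pchisq(chisq_assoc, df_assoc, lower.tail = FALSE),
    chisq_anc_het = chisq_anc, df_anc_het = df_anc,
    p_anc_het = if (df_anc > 0) pchisq(chisq_anc, df_anc, lower.tail = FALSE) else NA_real_,
    chisq_res_het = chisq_res, df_res_het = df_res,
    p_res_het = if (df_res > 0) pchisq(chisq_res, df_res, lower.tail = FALSE) else NA_real_,
    n_studies = k
  )
}

#' BMI-adjusted meta-regression of one SNV
#'
#' Adds study-level mean BMI in controls and in cases as covariates of the
#' meta-regression baseline, so the ancestry-correlated heterogeneity test
#' compares (intercept + BMI) against (intercept + BMI + axes) with df equal
#' to the number of axes.
#'
#' @inheritParams meta_regress_snv
#' @param bmi_controls,bmi_cases Per-study mean BMI (kg/m^2) in controls and
#'   cases; required for every contributing study.
#' @return As [meta_regress_snv()].
#' @export
bmi_adjusted_meta <- function(betas, ses, axes, bmi_controls, bmi_cases) {
  if (anyNA(bmi_controls) || anyNA(bmi_cases)) {
    abort("BMI values must be present for all contributing studies")
  }
  meta_regress_snv(betas, ses, axes,
                   extra_covariates = cbind(bmi_controls = bmi_controls,
                                            bmi_cases = bmi_cases))
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-study log-ORs with weights `1/se^2`: pooled beta
#' `= sum(w b)/sum(w)`, pooled SE `= 1/sqrt(sum(w))`, and Cochran's
#' `Q = sum(w (b - pooled)^2)` on `K - 1` df.
#'
#' @param betas,ses Numeric vectors of per-study effects and SEs.
#' @return One-row tibble: beta, se, z, p, q, df_q, p_q, n_studies.
#' @export
fixed_effects_meta <- function(betas, ses) {
  if (length(betas) < 1) abort("at least one study required")
  if (any(ses <= 0)) abort("all standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  q <- sum(w * (betas - beta)^2)
  df_q <- length(betas) - 1
  tibble::tibble(
    beta = beta, se = se, z = z,
    p = 2 * pnorm(-abs(z)),
    q = q, df_q = df_q,
    p_q = if (df_q > 0) pchisq(q, df_q, lower.tail = FALSE) else NA_real_,
    n_studies = length(betas)
  )
}

#' Run the meta-regression across all SNVs of a study set
#'
#' Vectorized driver: aligns alleles to a common reference, joins the axis
#' coordinates, keeps SNVs reported in at least `min_studies` studies
#' (degrees of freedom track the per-SNV contributing-study count), and
#' fits [meta_regress_snv()] (or [bmi_adjusted_meta()]) per SNV. SNVs with
#' singular designs are skipped with a logged reason.
#'
#' @param studies An `mx_study_set` or long summary tibble.
#' @param axes An `mx_axes` tibble from [compute_axes()].
#' @param min_studies Minimum number of contributing studies per SNV
#'   (default 5).
#' @param bmi Include mean-BMI covariates (requires an `mx_study_set` with
#'   study metadata, or `study_meta`).
#' @param study_meta Optional per-study metadata tibble (study,
#'   mean_bmi_controls, mean_bmi_cases) when `studies` is a bare tibble.
#' @return Tibble with one row per retained SNV: snv, chr, pos, ea, nea,
#'   axis slopes and SEs as unpacked columns (`b_axis1`, `se_axis1`, ...),
#'   plus the statistic/df/P triples of [meta_regress_snv()].
#' @export
run_meta_regression <- function(studies, axes, min_studies = 5,
                                bmi = FALSE, study_meta = NULL) {
  summ <- if (inherits(studies, "mx_study_set")) studies$summaries else studies
  meta <- if (inherits(studies, "mx_study_set")) studies$studies else study_meta
  if (bmi && is.null(meta)) abort("BMI adjustment needs study metadata")
  aligned <- align_to_reference(summ)
  axmat <- as.matrix(axes[, grep("^axis", names(axes)), drop = FALSE])
  rownames(axmat) <- axes$study

  aligned <- aligned %>%
    dplyr::group_by(.data$snv) %>%
    dplyr::filter(dplyr::n() >= min_studies) %>%
    dplyr::ungroup()

  n_skipped <- 0L
  res <- aligned %>%
    dplyr::group_by(.data$snv, .data$chr, .data$pos, .data$ea, .data$nea) %>%
    dplyr::group_modify(function(df, key) {
      ax <- axmat[df$study, , drop = FALSE]
      row <- tryCatch({
        if (bmi) {
          bm <- meta[match(df$study, meta$study), ]
          bmi_adjusted_meta(df$beta, df$se, ax,
                            bm$mean_bmi_controls, bm$mean_bmi_cases)
        } else {
          meta_regress_snv(df$beta, df$se, ax)
        }
      }, error = function(e) {
        n_skipped <<- n_skipped + 1L
        NULL
      })
      if (is.null(row)) return(tibble::tibble())
      unpack_coefs(row, n_axes = ncol(axmat))
    }) %>%
    dplyr::ungroup()
  if (n_skipped > 0) mx_log("skipped %d SNVs (singular design or too few studies)", n_skipped)
  res
}

# spread the coef/coef_se list-columns of a meta_regress_snv row into
# b_intercept, b_axis1, ..., se_axis1, ... scalar columns
unpack_coefs <- function(row, n_axes) {
  cf <- row$coef[[1]]
  se <- row$coef_se[[1]]
  nm <- names(cf)
  nm[nm == "(Intercept)"] <- "intercept"
  out <- row %>% dplyr::select(-"coef", -"coef_se")
  for (i in seq_along(cf)) {
    out[[paste0("b_", nm[i])]] <- unname(cf[i])
    out[[paste0("se_", nm[i])]] <- unname(se[i])
  }
  out
}

#' Fixed-effects meta-analysis across all SNVs (optionally within a group)
#'
#' @param studies An `mx_study_set` or long summary tibble.
#' @param group Optional ancestry label to restrict to (per-ancestry pooled
#'   results); `NULL` pools every study.
#' @param min_studies Minimum contributing studies per SNV (default 1).
#' @return Tibble: snv, chr, pos, ea, nea, beta, se, z, p, q, df_q, p_q,
#'   n_studies (+ `ancestry` when `group` is given).
#' @export
run_fixed_effects <- function(studies, group = NULL, min_studies = 1) {
  summ <- if (inherits(studies, "mx_study_set")) studies$summaries else studies
  if (!is.null(group)) summ <- dplyr::filter(summ, .data$ancestry == group)
  if (nrow(summ) == 0) abort("no studies after group filtering")
  aligned <- align_to_reference(summ)
  out <- aligned %>%
    dplyr::group_by(.data$snv, .data$chr, .data$pos, .data$ea, .data$nea) %>%
    dplyr::filter(dplyr::n() >= min_studies) %>%
    dplyr::group_modify(~ fixed_effects_meta(.x$beta, .x$se)) %>%
    dplyr::ungroup()
  if (!is.null(group)) out$ancestry <- group
  out
}
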