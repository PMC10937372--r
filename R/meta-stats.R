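#' Genomic-control inflation factor
#'
#' Converts each P value to a 1-df chi-square quantile and reports the
#' median relative to the null 1-df chi-square median (`qchisq(0.5, 1)`,
#' approximately 0.456). Values are rounded to 3 decimals; multi-df tests
#' are placed on the 1-df scale through their P values.
#'
#' @param pvalues Numeric vector of P values in `(0, 1]`.
#' @return Scalar lambda (3 decimals).
#' @export
genomic_control_lambda <- function(pvalues) {
  if (length(pvalues) == 0) abort("empty P value vector")
  if (any(pvalues <= 0 | pvalues > 1)) abort("P values must lie in (0, 1]")
  chisq <- qchisq(pvalues, df = 1, lower.tail = FALSE)
  round(stats::median(chisq) / qchisq(0.5, df = 1), 3)
}

#' Per-axis association z-scores, aligned to the risk allele
#'
#' For each SNV, `z_t = slope_t / se_t` for each ancestry axis, sign-flipped
#' when the stored effect allele is not the risk allele (the allele with a
#' positive fixed-effects pooled log-OR). The strongest axis is the one
#' with the greatest `|z|`; ties break to the lowest axis index.
#'
#' @param meta_result Tibble from [run_meta_regression()] (columns
#'   `b_axis*`, `se_axis*`).
#' @param fe_result Tibble from [run_fixed_effects()] supplying the pooled
#'   beta whose sign defines the risk allele, joined on `snv`.
#' @return Tibble: snv, one `z_axis*` column per axis, `strongest_axis`
#'   (integer), `strongest_z`.
#' @export
axis_association_zscores <- function(meta_result, fe_result) {
  slope_cols <- grep("^b_axis", names(meta_result), value = TRUE)
  se_cols <- sub("^b_", "se_", slope_cols)
  if (any(unlist(meta_result[se_cols]) == 0)) abort("zero axis-slope SE")
  joined <- dplyr::left_join(
    meta_result, dplyr::select(fe_result, "snv", fe_beta = "beta"), by = "snv"
  )
  flip <- ifelse(joined$fe_beta >= 0, 1, -1)  # align to risk allele
  z <- as.matrix(joined[slope_cols]) / as.matrix(joined[se_cols]) * flip
  colnames(z) <- sub("^b_", "z_", slope_cols)
  strongest <- apply(abs(z), 1, which.max)  # first max = lowest axis index
  tibble::tibble(snv = joined$snv) %>%
    dplyr::bind_cols(tibble::as_tibble(z)) %>%
    dplyr::mutate(
      strongest_axis = as.integer(strongest),
      strongest_z = z[cbind(seq_len(nrow(z)), strongest)]
    )
}

#' Bonferroni significance threshold
#'
#' `alpha / n_tests`, with a presentation rounding to two significant
#' figures (ties away from zero) for reports; `digits = NULL` returns the
#' raw value.
#'
#' @param alpha Family-wise error rate in `(0, 1)`.
#' @param n_tests Number of tests (>= 1).
#' @param digits Significant figures for presentation (default 2);
#'   `NULL` for the unrounded threshold.
#' @return Scalar threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests, digits = 2) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  stopifnot_count(n_tests, "n_tests")
  thr <- alpha / n_tests
  if (is.null(digits)) thr else signif2(thr, digits)
}

#' One-sided binomial enrichment test
#'
#' Exact upper-tail probability `P(X >= n_significant)` for
#' `X ~ Binomial(n_total, per_test_alpha)`, with the expected count
#' `n_total * per_test_alpha`. Used to ask whether more tests pass a
#' Bonferroni threshold than chance allows.
#'
#' @param n_significant Observed number of significant tests.
#' @param n_total Total number of tests.
#' @param per_test_alpha Per-test significance level in `(0, 1)`.
#' @return One-row tibble: n_significant, n_total, expected, p.
#' @export
binomial_enrichment_test <- function(n_significant, n_total, per_test_alpha) {
  if (per_test_alpha <= 0 || per_test_alpha >= 1) abort("`per_test_alpha` must lie in (0, 1)")
  if (n_significant < 0 || n_significant > n_total) {
    abort("`n_significant` must lie in [0, n_total]")
  }
  p <- stats::pbinom(n_significant - 1, n_total, per_test_alpha,
                     lower.tail = FALSE)
  tibble::tibble(
    n_significant = n_significant, n_total = n_total,
    expected = n_total * per_test_alpha, p = p
  )
}
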