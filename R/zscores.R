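#' Sample-size-corrected trait z-scores aligned to the risk allele
#'
#' For each index SNV and phenotype, `Z = beta / (sqrt(N) * se)` after
#' sign-aligning the trait effect to the disease risk allele, where `N` is
#' the maximum reported sample size of the phenotype's GWAS. The
#' correction places traits with different study sizes on a comparable
#' scale. Pairs with no reported statistics — or whose risk allele matches
#' neither trait-file allele — are set missing (the latter with a log).
#'
#' @param trait_stats Long tibble: snv, phenotype, ea, nea, beta, se.
#' @param risk_alleles Tibble: snv, risk_allele (the disease risk allele
#'   from the fixed-effects meta-analysis).
#' @param sample_sizes Named numeric: maximum sample size per phenotype.
#' @return An `mx_zmatrix` (SNV x phenotype matrix, NA = missing) with
#'   attribute `n_phen`.
#' @export
compute_zscores <- function(trait_stats, risk_alleles, sample_sizes) {
  if (any(trait_stats$se <= 0, na.rm = TRUE)) abort("trait SEs must be positive")
  if (any(sample_sizes <= 0)) abort("sample sizes must be positive")
  df <- trait_stats %>%
    dplyr::left_join(risk_alleles, by = "snv") %>%
    dplyr::mutate(
      sign = dplyr::case_when(
        .data$ea == .data$risk_allele ~ 1,
        .data$nea == .data$risk_allele ~ -1,
        TRUE ~ NA_real_
      )
    )
  n_bad <- sum(is.na(df$sign))
  if (n_bad > 0) {
    mx_log("set %d trait records missing: risk allele matches neither reported allele", n_bad)
  }
  df <- df %>%
    dplyr::mutate(
      z = .data$sign * .data$beta /
        (sqrt(sample_sizes[.data$phenotype]) * .data$se)
    )
  snvs <- unique(trait_stats$snv)
  phens <- names(sample_sizes)
  Z <- matrix(NA_real_, length(snvs), length(phens),
              dimnames = list(snvs, phens))
  ok <- !is.na(df$z)
  Z[cbind(match(df$snv[ok], snvs), match(df$phenotype[ok], phens))] <- df$z[ok]
  structure(Z, class = c("mx_zmatrix", "matrix", "array"),
            n_phen = sample_sizes)
}
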