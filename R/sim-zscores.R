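#' Simulate cardiometabolic trait z-scores with planted cluster structure
#'
#' Assigns each index SNV to one of `n_clusters_true` planted clusters and
#' draws its sample-size-corrected trait z-scores
#' `Z_ij ~ Normal(centroid[cluster(j), i], 1)`, then masks entries missing
#' completely at random at `missing_rate`. Alongside the z-score matrix the
#' generator emits an equivalent long table of raw trait summary statistics
#' (effect allele, other allele, beta, SE) with per-phenotype maximum
#' sample sizes, so that [compute_zscores()] can be exercised on the same
#' planted truth: `beta = Z * sqrt(N) * se` with SE and N drawn at
#' realistic scales.
#'
#' @param config An [sim_config()] object.
#' @param index_snvs Tibble of index SNVs (columns snv, ea, nea); when
#'   `NULL`, generic SNV ids and A/G alleles are invented.
#' @param n_index Number of index SNVs when `index_snvs` is `NULL`.
#' @return List with `zmatrix` (an `mx_zmatrix`: numeric matrix SNV x
#'   phenotype with NAs for missing entries and attributes `n_phen`
#'   (per-phenotype max sample size)), `trait_stats` (long tibble),
#'   `risk_alleles` (tibble snv, risk_allele), and `truth` (assignment
#'   vector and centroid matrix).
#' @export
simulate_phenotype_zscores <- function(config, index_snvs = NULL, n_index = 200L) {
  stopifnot(inherits(config, "mx_sim_config"))
  if (config$missing_rate >= 1) abort("`missing_rate` must be < 1")
  set.seed(derive_seed(config$seed, "zscores"))
  mu <- config$cluster_centroids
  n_phen <- ncol(mu)
  if (is.null(index_snvs)) {
    index_snvs <- tibble::tibble(
      snv = sprintf("idx_%04d", seq_len(n_index)),
      ea = "A", nea = "G"
    )
  }
  n <- nrow(index_snvs)
  assignment <- sort(rep_len(seq_len(config$n_clusters_true), n))
  assignment <- sample(assignment)  # shuffle so order carries no signal
  Z <- mu[assignment, , drop = FALSE] +
    matrix(rnorm(n * n_phen), n, n_phen)
  dimnames(Z) <- list(index_snvs$snv, sprintf("phen_%02d", seq_len(n_phen)))

  mask <- matrix(runif(n * n_phen) < config$missing_rate, n, n_phen)
  Z_obs <- Z
  Z_obs[mask] <- NA_real_

  n_phen_sizes <- round(runif(n_phen, 5e4, 5e5))
  names(n_phen_sizes) <- colnames(Z)

  # raw trait summary statistics consistent with the z-scores:
  # Z = beta / (sqrt(N) * se)  =>  beta = Z * sqrt(N) * se
  trait_stats <- tidyr::expand_grid(
    snv = index_snvs$snv, phenotype = colnames(Z)
  ) %>%
    dplyr::left_join(index_snvs, by = "snv") %>%
    dplyr::mutate(
      se = runif(dplyr::n(), 0.005, 0.02),
      N = n_phen_sizes[.data$phenotype],
      z = as.vector(t(Z_obs))[dplyr::row_number()],
      beta = .data$z * sqrt(.data$N) * .data$se
    ) %>%
    dplyr::filter(!is.na(.data$z)) %>%
    dplyr::select("snv", "phenotype", ea = "ea", nea = "nea", "beta", "se")

  zmat <- structure(Z_obs, class = c("mx_zmatrix", "matrix", "array"),
                    n_phen = n_phen_sizes)
  list(
    zmatrix = zmat,
    trait_stats = trait_stats,
    risk_alleles = tibble::tibble(snv = index_snvs$snv,
                                  risk_allele = index_snvs$ea),
    truth = list(assignment = assignment, centroids = mu)
  )
}

#' @export
print.mx_zmatrix <- function(x, ...) {
  cat("<mx_zmatrix>", nrow(x), "SNVs x", ncol(x), "phenotypes;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x))))
  invisible(x)
}
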