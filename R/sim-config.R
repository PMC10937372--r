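#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator into a validated list.
#' The generator emulates the statistical structure the downstream analysis
#' assumes: Balding-Nichols allele-frequency divergence between ancestry
#' groups, per-study allelic effects linear in latent ancestry axes (and
#' optionally in study-level mean BMI), sampling noise driven by effective
#' sample size, planted trait-z-score cluster structure with missingness,
#' planted open-chromatin peak enrichment, and cohorts whose outcome risk
#' loads on cluster-specific polygenic scores.
#'
#' @param n_snvs Number of simulated SNVs (one chromosome, 1-based positions).
#' @param n_studies_per_group Named integer vector: studies per ancestry group.
#' @param group_fst Named numeric vector of Balding-Nichols divergence
#'   parameters (unitless, in `[0, 1)`), one per ancestry group.
#' @param n_axes_true Number of latent ancestry axes generating effect
#'   heterogeneity.
#' @param axis_effects Slopes of the true per-study allelic effect on the
#'   latent axes (log-OR per unit axis coordinate); recycled/truncated to
#'   `n_axes_true`.
#' @param b0 Baseline log-OR shared by all studies.
#' @param causal_fraction Fraction of SNVs carrying the effect structure;
#'   the rest are strictly null (no association, no heterogeneity), giving
#'   the pipeline non-associated SNVs to serve as null pools.
#' @param bmi_effects Length-2 numeric: slopes on study-level mean BMI in
#'   controls and cases (log-OR per kg/m^2). Zero disables BMI confounding.
#' @param n_clusters_true Number of planted mechanistic clusters.
#' @param cluster_centroids Matrix (cluster x phenotype) of planted z-score
#'   centroids; `NULL` uses a default well-separated pattern.
#' @param missing_rate Fraction of z-score entries masked missing completely
#'   at random.
#' @param peak_overlap_probs Length-2 numeric `c(p_index, p_null)`: peak
#'   overlap probabilities for index and null SNVs in the enriched cell type.
#' @param block_size SNVs per LD block in the haplotype panels.
#' @param ld_within Mosaic-copy probability within a block: each haplotype
#'   copies the block's latent ancestral haplotype with this probability,
#'   giving within-block correlation; blocks are mutually independent.
#' @param n_haplotypes Haplotypes per ancestry-group reference panel.
#' @param neff_range Length-2 numeric: per-study effective sample sizes are
#'   drawn uniformly from this range (the source analyses do not state a
#'   distribution; this default is configurable).
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#'
#' @return An object of class `mx_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_snvs = 200, seed = 1)
#' names(cfg)
sim_config <- function(n_snvs = 500,
                       n_studies_per_group = c(EUR = 4L, EAS = 3L, AFA = 3L,
                                               HIS = 3L, SAS = 3L),
                       group_fst = c(EUR = 0.02, EAS = 0.12, AFA = 0.15,
                                     HIS = 0.08, SAS = 0.06),
                       n_axes_true = 2L,
                       axis_effects = c(0.5, 0),
                       b0 = 0,
                       causal_fraction = 1,
                       bmi_effects = c(0, 0),
                       n_clusters_true = 3L,
                       cluster_centroids = NULL,
                       missing_rate = 0.1,
                       peak_overlap_probs = c(0.5, 0.1),
                       block_size = 10L,
                       ld_within = 0.9,
                       n_haplotypes = 500L,
                       neff_range = c(5e3, 5e4),
                       seed = 1L) {
  stopifnot_count(n_snvs, "n_snvs")
  stopifnot_count(n_studies_per_group, "n_studies_per_group")
  stopifnot_count(block_size, "block_size")
  stopifnot_count(n_haplotypes, "n_haplotypes")
  stopifnot_count(n_clusters_true, "n_clusters_true")
  stopifnot_prob(group_fst, "group_fst")
  stopifnot_prob(missing_rate, "missing_rate")
  stopifnot_prob(causal_fraction, "causal_fraction")
  if (missing_rate >= 1) abort("`missing_rate` must be < 1")
  stopifnot_prob(peak_overlap_probs, "peak_overlap_probs")
  stopifnot_prob(ld_within, "ld_within")
  if (is.null(names(n_studies_per_group)) || is.null(names(group_fst)) ||
      !setequal(names(n_studies_per_group), names(group_fst))) {
    abort("`n_studies_per_group` and `group_fst` must be named by the same ancestry groups")
  }
  if (length(bmi_effects) != 2L) abort("`bmi_effects` must have length 2 (controls, cases)")
  axis_effects <- rep_len(axis_effects, n_axes_true)
  if (is.null(cluster_centroids)) {
    # default: block sign pattern, 10 phenotypes, +/-2 z units apart
    n_phen <- 10L
    cluster_centroids <- matrix(0, n_clusters_true, n_phen)
    for (k in seq_len(n_clusters_true)) {
      idx <- ((k - 1L) * 3L) %% n_phen + 0:2
      cluster_centroids[k, (idx %% n_phen) + 1L] <- 2 * (-1)^k
    }
  }
  cluster_centroids <- as.matrix(cluster_centroids)
  if (nrow(cluster_centroids) != n_clusters_true) {
    abort("`cluster_centroids` must have `n_clusters_true` rows")
  }
  structure(list(
    n_snvs = as.integer(n_snvs),
    n_studies_per_group = setNames(as.integer(n_studies_per_group),
                                   names(n_studies_per_group)),
    group_fst = group_fst,
    n_axes_true = as.integer(n_axes_true),
    axis_effects = axis_effects,
    b0 = b0,
    causal_fraction = causal_fraction,
    bmi_effects = bmi_effects,
    n_clusters_true = as.integer(n_clusters_true),
    cluster_centroids = cluster_centroids,
    missing_rate = missing_rate,
    peak_overlap_probs = peak_overlap_probs,
    block_size = as.integer(block_size),
    ld_within = ld_within,
    n_haplotypes = as.integer(n_haplotypes),
    neff_range = neff_range,
    seed = as.integer(seed)
  ), class = "mx_sim_config")
}

#' @export
print.mx_sim_config <- function(x, ...) {
  cat("<mx_sim_config>\n")
  cat("  SNVs:", x$n_snvs, " groups:",
      paste0(names(x$n_studies_per_group), "(", x$n_studies_per_group, ")",
             collapse = " "), "\n")
  cat("  latent axes:", x$n_axes_true,
      " clusters:", x$n_clusters_true,
      " missing rate:", x$missing_rate, " seed:", x$seed, "\n")
  invisible(x)
}
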