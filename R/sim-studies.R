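#' Simulate per-study GWAS summary statistics
#'
#' Builds one summary-statistic table per study. Each study's effect-allele
#' frequencies sit near its ancestry group's panel frequencies (small
#' between-study noise); the study's latent ancestry-axis coordinates are
#' the classical multidimensional-scaling coordinates of the realized
#' study-by-study mean absolute EAF distance matrix, so planted axis slopes
#' are recoverable by the meta-regression without rotation ambiguity. The
#' true allelic effect of study *k* is
#' `b_k = b0 + sum_t axis_effects[t] * x_tk (+ BMI terms)`, identical across
#' SNVs; the observed effect is `b_k` plus Gaussian noise with standard
#' error `1/sqrt(2 f (1-f) N_eff)`. Monomorphic SNVs (EAF 0 or 1) are
#' dropped from a study's table with a logged count.
#'
#' @param config An [sim_config()] object.
#' @param panels Output of [simulate_haplotype_panels()].
#' @return An `mx_study_set`: list with `summaries` (long tibble: study,
#'   ancestry, snv, chr, pos, ea, nea, eaf, beta, se, n_case, n_control,
#'   info), `studies` (per-study metadata incl. mean BMI and effective
#'   sample size), and `truth` (latent axis coordinates and true effects).
#' @export
simulate_study_summaries <- function(config, panels) {
  stopifnot(inherits(config, "mx_sim_config"))
  set.seed(derive_seed(config$seed, "studies"))
  groups <- names(config$n_studies_per_group)
  snvs <- panels[[1]]$snvs

  studies <- tidyr::expand_grid(
    ancestry = groups
  ) %>%
    dplyr::mutate(n = config$n_studies_per_group[.data$ancestry]) %>%
    tidyr::uncount(.data$n, .id = "rep") %>%
    dplyr::mutate(study = sprintf("%s_%02d", .data$ancestry, .data$rep)) %>%
    dplyr::select("study", "ancestry")

  n_study <- nrow(studies)
  neff <- runif(n_study, config$neff_range[1], config$neff_range[2])
  studies <- studies %>%
    dplyr::mutate(
      n_eff = neff,
      n_case = round(neff / 2), n_control = round(neff / 2),
      mean_bmi_controls = rnorm(n_study, 27, 1.5),
      mean_bmi_cases = rnorm(n_study, 31, 1.5)
    )

  # per-study EAF: group panel frequency plus small between-study noise
  eaf <- sapply(seq_len(n_study), function(k) {
    f <- panels[[studies$ancestry[k]]]$freqs
    pmin(pmax(f + rnorm(length(f), 0, 0.01), 0), 1)
  })  # SNV x study

  # latent axes = classical MDS of the realized EAF distance matrix
  d <- matrix(0, n_study, n_study)
  for (i in seq_len(n_study - 1)) {
    for (j in (i + 1):n_study) {
      d[i, j] <- d[j, i] <- mean(abs(eaf[, i] - eaf[, j]))
    }
  }
  x <- stats::cmdscale(d, k = config$n_axes_true)
  colnames(x) <- paste0("axis", seq_len(config$n_axes_true))

  b_true <- config$b0 +
    drop(x %*% config$axis_effects) +
    config$bmi_effects[1] * studies$mean_bmi_controls +
    config$bmi_effects[2] * studies$mean_bmi_cases
  causal <- runif(nrow(snvs)) < config$causal_fraction

  n_dropped <- 0L
  summaries <- purrr::map_dfr(seq_len(n_study), function(k) {
    f <- eaf[, k]
    keep <- f > 0 & f < 1
    n_dropped <<- n_dropped + sum(!keep)
    se <- 1 / sqrt(2 * f[keep] * (1 - f[keep]) * studies$n_eff[k])
    tibble::tibble(
      study = studies$study[k], ancestry = studies$ancestry[k],
      snv = snvs$snv[keep], chr = snvs$chr[keep], pos = snvs$pos[keep],
      ea = snvs$ea[keep], nea = snvs$nea[keep],
      eaf = f[keep],
      beta = rnorm(sum(keep), b_true[k] * causal[keep], se),
      se = se,
      n_case = studies$n_case[k], n_control = studies$n_control[k],
      info = runif(sum(keep), 0.85, 1)
    )
  })
  if (n_dropped > 0) mx_log("excluded %d monomorphic study-SNV records", n_dropped)

  structure(list(
    summaries = summaries,
    studies = studies,
    truth = list(axes = x, b_true = b_true, b0 = config$b0,
                 causal = setNames(causal, snvs$snv),
                 axis_effects = config$axis_effects,
                 bmi_effects = config$bmi_effects)
  ), class = "mx_study_set")
}

#' @export
print.mx_study_set <- function(x, ...) {
  cat("<mx_study_set>", nrow(x$studies), "studies,",
      length(unique(x$summaries$snv)), "SNVs\n")
  invisible(x)
}
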