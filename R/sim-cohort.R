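#' Simulate an individual-level testing cohort
#'
#' Draws genotype dosages `Binomial(2, f)` at each score SNV from the
#' ancestry group's panel frequencies, computes the cluster-specific
#' polygenic scores implied by `ps_model`, and generates a binary outcome
#' from a logistic model whose linear predictor loads configurable log-ORs
#' on the standardized cluster scores plus age and sex, and a quantitative
#' age of disease onset from a linear model on the same terms. True effects
#' are recorded for recovery testing.
#'
#' @param config An [sim_config()] object (seed source).
#' @param ps_model Tibble with columns snv, risk_allele, cluster, weight
#'   (log-OR per risk-allele dosage).
#' @param panels Output of [simulate_haplotype_panels()].
#' @param ancestry Ancestry group whose panel frequencies drive dosages.
#' @param n_individuals Cohort size.
#' @param outcome_effects Named numeric: log-OR per SD of each cluster's
#'   standardized score on the binary outcome (names are cluster ids;
#'   clusters absent from `ps_model` are an error).
#' @param intercept Logistic intercept (baseline log-odds of the outcome).
#' @param onset_effects Named numeric: years per SD of each cluster score on
#'   age of onset.
#' @param seed_tag Character tag mixed into the derived seed so several
#'   cohorts can be drawn from one config.
#' @return An `mx_cohort`: list with `dosages` (individual x SNV matrix),
#'   `samples` (tibble: sample_id, age, sex, t2d, outcome, age_onset),
#'   `ancestry`, and `truth`.
#' @export
simulate_cohort <- function(config, ps_model, panels,
                            ancestry = names(panels)[1],
                            n_individuals = 5000L,
                            outcome_effects = c(),
                            intercept = -2,
                            onset_effects = c(),
                            seed_tag = "cohort") {
  stopifnot(inherits(config, "mx_sim_config"))
  panel <- panels[[ancestry]]
  if (is.null(panel)) abort(sprintf("no panel for ancestry '%s'", ancestry))
  missing_cl <- setdiff(c(names(outcome_effects), names(onset_effects)),
                        as.character(unique(ps_model$cluster)))
  if (length(missing_cl)) {
    abort(sprintf("cluster(s) %s absent from ps_model",
                  paste(missing_cl, collapse = ", ")))
  }
  idx <- match(ps_model$snv, panel$snvs$snv)
  if (anyNA(idx)) abort("ps_model contains SNVs absent from the panel")
  set.seed(derive_seed(config$seed, seed_tag))

  f <- panel$freqs[idx]
  n <- n_individuals
  dos <- matrix(rbinom(n * length(f), 2L, rep(f, each = n)), n, length(f))
  colnames(dos) <- ps_model$snv

  # align dosage to risk allele: panel dosage counts the effect allele
  flip <- ps_model$risk_allele != panel$snvs$ea[idx]
  dos_aligned <- dos
  dos_aligned[, flip] <- 2 - dos[, flip]

  clusters <- sort(unique(as.character(ps_model$cluster)))
  raw <- sapply(clusters, function(cl) {
    j <- which(as.character(ps_model$cluster) == cl)
    drop(dos_aligned[, j, drop = FALSE] %*% ps_model$weight[j])
  })
  std <- scale(raw)

  age <- rnorm(n, 55, 10)
  sex <- rbinom(n, 1, 0.5)
  lp <- intercept + 0.01 * (age - 55) + 0.1 * sex
  for (cl in names(outcome_effects)) lp <- lp + outcome_effects[[cl]] * std[, cl]
  outcome <- rbinom(n, 1, stats::plogis(lp))

  onset <- rnorm(n, 50, 8) + 0.1 * (age - 55)
  for (cl in names(onset_effects)) onset <- onset + onset_effects[[cl]] * std[, cl]
  t2d <- rbinom(n, 1, 0.3)

  structure(list(
    dosages = dos,
    samples = tibble::tibble(
      sample_id = sprintf("ind_%06d", seq_len(n)),
      age = age, sex = sex, t2d = t2d,
      outcome = outcome, age_onset = onset
    ),
    ancestry = ancestry,
    snvs = panel$snvs[idx, ],
    truth = list(outcome_effects = outcome_effects,
                 onset_effects = onset_effects,
                 intercept = intercept)
  ), class = "mx_cohort")
}

#' @export
print.mx_cohort <- function(x, ...) {
  cat("<mx_cohort>", nrow(x$dosages), "individuals x", ncol(x$dosages),
      "SNVs, ancestry", x$ancestry, "\n")
  invisible(x)
}
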