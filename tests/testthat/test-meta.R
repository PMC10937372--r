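test_that("betas exactly linear in axes give zero residual heterogeneity", {
  set.seed(21)
  K <- 12
  ax <- cbind(axis1 = rnorm(K), axis2 = rnorm(K))
  betas <- 0.1 + 0.3 * ax[, 1] - 0.2 * ax[, 2]
  ses <- runif(K, 0.02, 0.1)
  r <- meta_regress_snv(betas, ses, ax)
  expect_lt(r$chisq_res_het, 1e-10)
  expect_equal(r$p_res_het, 1)
})

test_that("equal betas give zero ancestry-correlated heterogeneity", {
  set.seed(22)
  K <- 10
  ax <- matrix(rnorm(K * 3), K, 3)
  r <- meta_regress_snv(rep(0.2, K), runif(K, 0.02, 0.1), ax)
  expect_lt(r$chisq_anc_het, 1e-10)
})

test_that("meta-regression matches the weighted-normal-equations oracle and the Q decomposition", {
  set.seed(23)
  for (rep in 1:5) {
    K <- 10
    ax <- matrix(rnorm(K * 2), K, 2,
                 dimnames = list(NULL, c("axis1", "axis2")))
    betas <- rnorm(K, 0.1, 0.2)
    ses <- runif(K, 0.02, 0.1)
    r <- meta_regress_snv(betas, ses, ax)

    X <- cbind(1, ax)
    o <- wls_oracle(betas, ses, X)
    expect_equal(unname(r$coef[[1]]), unname(o$coef), tolerance = 1e-8)
    expect_equal(unname(r$coef_se[[1]]), unname(o$se), tolerance = 1e-8)
    o0 <- wls_oracle(betas, ses, matrix(1, K, 1))
    w <- 1 / ses^2
    expect_equal(r$chisq_assoc, sum(w * betas^2) - o$rss, tolerance = 1e-8)
    expect_equal(r$chisq_anc_het, o0$rss - o$rss, tolerance = 1e-8)
    expect_equal(r$chisq_res_het, o$rss, tolerance = 1e-8)
    # decomposition: het + residual = Cochran's Q of the intercept-only fit
    q <- fixed_effects_meta(betas, ses)$q
    expect_equal(r$chisq_anc_het + r$chisq_res_het, q,
                 tolerance = 1e-8 * max(1, q))
  }
})

test_that("singular designs are rejected", {
  K <- 10
  ax <- cbind(axis1 = 1:K, axis2 = 2 * (1:K))
  expect_error(meta_regress_snv(rnorm(K), rep(0.1, K), ax), "singular")
  expect_error(meta_regress_snv(rnorm(3), rep(0.1, 3),
                                matrix(rnorm(3), 3, 1)), "studies")
  expect_error(meta_regress_snv(rnorm(10), c(rep(0.1, 9), 0)), "positive")
})

test_that("BMI adjustment removes planted BMI confounding but not orthogonal signals", {
  set.seed(24)
  K <- 14
  bmi_cases <- rnorm(K, 31, 2)
  bmi_controls <- rnorm(K, 27, 2)
  # axes orthogonal to BMI by construction (residualized)
  ax_raw <- matrix(rnorm(K * 2), K, 2)
  ax <- apply(ax_raw, 2, function(a) {
    stats::residuals(stats::lm(a ~ bmi_cases + bmi_controls))
  })
  colnames(ax) <- c("axis1", "axis2")
  ses <- runif(K, 0.02, 0.05)

  # effects purely from case BMI: unadjusted het large, adjusted ~ 0
  betas <- 0.05 * bmi_cases
  unadj <- meta_regress_snv(betas, ses, ax)
  adj <- bmi_adjusted_meta(betas, ses, ax, bmi_controls, bmi_cases)
  expect_gt(unadj$chisq_anc_het, adj$chisq_anc_het)
  expect_lt(adj$chisq_anc_het, 1e-8)
  # oracle for the adjusted fit
  o_base <- wls_oracle(betas, ses, cbind(1, bmi_controls, bmi_cases))
  o_full <- wls_oracle(betas, ses, cbind(1, bmi_controls, bmi_cases, ax))
  expect_equal(adj$chisq_anc_het, o_base$rss - o_full$rss,
               tolerance = 1e-6)

  # effects on axes orthogonal to BMI: adjusted and unadjusted agree
  betas2 <- 0.3 * ax[, 1] + rnorm(K, 0, 0.001)
  unadj2 <- meta_regress_snv(betas2, ses, ax)
  adj2 <- bmi_adjusted_meta(betas2, ses, ax, bmi_controls, bmi_cases)
  expect_equal(adj2$p_anc_het, unadj2$p_anc_het, tolerance = 1e-3)

  expect_error(bmi_adjusted_meta(betas, ses, ax, rep(27, K), rep(31, K)),
               "singular")
})

test_that("fixed-effects meta-analysis has its closed forms and invariances", {
  one <- fixed_effects_meta(0.3, 0.1)
  expect_equal(one$beta, 0.3)
  expect_equal(one$se, 0.1)

  two <- fixed_effects_meta(c(0, 0.2), c(0.1, 0.1))
  expect_equal(two$beta, 0.1)
  expect_equal(two$se, 0.1 / sqrt(2))
  expect_equal(two$q, 2.0)

  set.seed(25)
  betas <- rnorm(5); ses <- runif(5, 0.05, 0.2)
  r <- fixed_effects_meta(betas, ses)
  w <- 1 / ses^2
  expect_equal(r$beta, sum(w * betas) / sum(w), tolerance = 1e-12)
  perm <- sample(5)
  expect_equal(fixed_effects_meta(betas[perm], ses[perm])$q, r$q,
               tolerance = 1e-12)
})

test_that("with zero axes the meta-regression reduces to fixed effects", {
  set.seed(26)
  betas <- rnorm(8, 0.1, 0.1); ses <- runif(8, 0.03, 0.1)
  mr <- meta_regress_snv(betas, ses, axes = NULL)
  fe <- fixed_effects_meta(betas, ses)
  expect_equal(unname(mr$coef[[1]][1]), fe$beta, tolerance = 1e-12)
  expect_equal(unname(mr$coef_se[[1]][1]), fe$se, tolerance = 1e-12)
  expect_equal(mr$chisq_res_het, fe$q, tolerance = 1e-10)
})

test_that("statistics are invariant to allele flips in a subset of studies", {
  w <- small_world()
  ss <- w$studies
  flip_studies <- unique(ss$summaries$study)[c(2, 5)]
  flipped <- ss$summaries %>%
    dplyr::mutate(
      do_flip = .data$study %in% flip_studies,
      ea2 = ifelse(.data$do_flip, .data$nea, .data$ea),
      nea = ifelse(.data$do_flip, .data$ea, .data$nea),
      ea = .data$ea2,
      eaf = ifelse(.data$do_flip, 1 - .data$eaf, .data$eaf),
      beta = ifelse(.data$do_flip, -.data$beta, .data$beta)
    ) %>%
    dplyr::select(-"do_flip", -"ea2")
  ss2 <- structure(list(summaries = flipped, studies = ss$studies),
                   class = "mx_study_set")
  ax1 <- compute_axes(ss, n_axes = 2)
  ax2 <- compute_axes(ss2, n_axes = 2)
  m1 <- quiet(run_meta_regression(ss, ax1, min_studies = 5))
  m2 <- quiet(run_meta_regression(ss2, ax2, min_studies = 5))
  expect_equal(m1$chisq_assoc, m2$chisq_assoc, tolerance = 1e-8)
  expect_equal(m1$chisq_anc_het, m2$chisq_anc_het, tolerance = 1e-8)
  expect_equal(m1$chisq_res_het, m2$chisq_res_het, tolerance = 1e-8)
})

test_that("planted axis slopes are recovered across simulated SNVs", {
  w <- small_world()
  m <- quiet(run_meta_regression(w$studies, w$axes, min_studies = 5))
  # truth: slope 0.6 on latent axis 1; estimated axes reproduce the latent
  # MDS construction so the slope is directly comparable
  est <- m$b_axis1
  mc_se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.6), 2 * mc_se + 0.02)
})
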