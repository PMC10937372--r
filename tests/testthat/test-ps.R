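test_that("variant QC applies the MAF, imputation and HWE rules with inclusive boundaries", {
  vs <- tibble::tibble(
    snv = paste0("s", 1:6),
    maf = c(0.005, 0.01, 0.3, 0.3, 0.3, 0.3),
    info_r2 = c(0.9, 0.9, 0.69, 0.70, 0.9, 0.9),
    hwe_p = c(0.5, 0.5, 0.5, 0.5, 1e-7, 1e-6)
  )
  qc <- quiet(qc_filter_snvs(vs))
  expect_setequal(qc$retained$snv, c("s2", "s4", "s6"))
  expect_equal(qc$excluded$reason[qc$excluded$snv == "s1"], "MAF < 1%")
  expect_equal(qc$excluded$reason[qc$excluded$snv == "s3"],
               "imputation r2 < 0.7")
  expect_equal(qc$excluded$reason[qc$excluded$snv == "s5"], "HWE P < 1e-6")
  # idempotent
  qc2 <- quiet(qc_filter_snvs(qc$retained))
  expect_identical(qc2$retained$snv, qc$retained$snv)
})

test_that("HWE exact test matches full enumeration and handles degenerate input", {
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)
  expect_equal(hwe_exact_test(10, 0, 0), 1)

  # full-enumeration oracle via multinomial probabilities conditioned on
  # the allele count
  hwe_oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    na <- 2 * naa + nAa
    hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
    pr <- vapply(hets, function(h) {
      haa <- (na - h) / 2
      hAA <- n - h - haa
      exp(lfactorial(n) - lfactorial(hAA) - lfactorial(h) - lfactorial(haa) +
            h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
            lfactorial(2 * n))
    }, numeric(1))
    # pr is the exact conditional pmf (sums to 1)
    expect_equal(sum(pr), 1, tolerance = 1e-10)
    sum(pr[pr <= pr[hets == nAa] + 1e-12])
  }
  for (cnt in list(c(50, 0, 50), c(20, 40, 10), c(3, 7, 1), c(0, 2, 98))) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_error(hwe_exact_test(-1, 0, 5), "non-negative")
})

mk_cohort <- function(dosages, ea = NULL) {
  n <- nrow(dosages)
  if (is.null(ea)) ea <- rep("A", ncol(dosages))
  list(dosages = dosages,
       snvs = tibble::tibble(snv = colnames(dosages), ea = ea,
                             nea = "G"),
       samples = tibble::tibble(sample_id = sprintf("i%04d", seq_len(n)),
                                age = rnorm(n, 55, 10),
                                sex = rbinom(n, 1, 0.5)))
}

test_that("partitioned scores standardize exactly and sum to the overall score", {
  # single SNV, w = ln 2, dosages 0/1/2 equally frequent
  d <- matrix(rep(c(0, 1, 2), each = 100), ncol = 1,
              dimnames = list(NULL, "s1"))
  ch <- mk_cohort(d)
  pm <- tibble::tibble(snv = "s1", risk_allele = "A", cluster = 1,
                       weight = log(2))
  sc <- compute_partitioned_ps(ch, pm)
  # 3-point standardization: values {-sqrt(3/2), 0, +sqrt(3/2)} (sample SD)
  sdc <- sqrt(300 / 299)  # sample-variance correction
  expect_equal(sort(unique(round(sc$cluster_1, 10))),
               round(c(-1, 0, 1) * sqrt(3 / 2) / sdc, 10))

  set.seed(111)
  d2 <- matrix(rbinom(500 * 6, 2, 0.4), 500, 6,
               dimnames = list(NULL, paste0("s", 1:6)))
  ch2 <- mk_cohort(d2, ea = c("A", "A", "G", "A", "G", "A"))
  pm2 <- tibble::tibble(snv = paste0("s", 1:6),
                        risk_allele = c("A", "G", "G", "A", "A", "A"),
                        cluster = rep(1:2, 3),
                        weight = runif(6, 0.01, 0.1))
  sc2 <- compute_partitioned_ps(ch2, pm2)
  raw <- attr(sc2, "raw")
  expect_equal(raw[, "overall"],
               raw[, "cluster_1"] + raw[, "cluster_2"], tolerance = 1e-12)
  for (cl in c("overall", "cluster_1", "cluster_2")) {
    expect_lt(abs(mean(sc2[[cl]])), 1e-10)
    expect_lt(abs(stats::var(sc2[[cl]]) - 1), 1e-10)
  }
  # all-zero weights -> zero-variance error
  expect_error(compute_partitioned_ps(
    ch2, dplyr::mutate(pm2, weight = 0)), "zero-variance")
})

test_that("outcome association recovers a planted cluster effect and flags rank deficiency", {
  set.seed(112)
  n <- 20000
  d <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
              dimnames = list(NULL, paste0("s", 1:20)))
  ch <- mk_cohort(d)
  pm <- tibble::tibble(snv = paste0("s", 1:20), risk_allele = "A",
                       cluster = rep(1:2, each = 10),
                       weight = runif(20, 0.02, 0.08))
  sc <- compute_partitioned_ps(ch, pm)
  lp <- -1.5 + 0.2 * sc$cluster_1
  ch$samples$outcome <- rbinom(n, 1, stats::plogis(lp))
  res <- associate_outcome(sc, ch, "outcome", family = "binomial")
  r1 <- res[res$score == "cluster_1", ]
  expect_lt(abs(r1$estimate - 0.2), 2 * r1$se)
  expect_true("overall" %in% res$score)

  # duplicated score as covariate: rank deficient
  ch$samples$dup <- sc$cluster_1
  expect_error(associate_outcome(sc, ch, "outcome", family = "binomial",
                                 covariates = c("age", "sex", "dup")),
               "rank")
  ch$samples$const <- 1
  expect_error(associate_outcome(sc, ch, "const", family = "gaussian"),
               "constant")
})

test_that("score-outcome P values are calibrated when the outcome is independent", {
  set.seed(113)
  n <- 400
  d <- matrix(rbinom(n * 10, 2, 0.4), n, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  pm <- tibble::tibble(snv = paste0("s", 1:10), risk_allele = "A",
                       cluster = rep(1:2, each = 5),
                       weight = runif(10, 0.02, 0.08))
  p <- vapply(1:300, function(i) {
    ch <- mk_cohort(d)
    sc <- compute_partitioned_ps(ch, pm)
    ch$samples$outcome <- rbinom(n, 1, 0.3)
    res <- associate_outcome(sc, ch, "outcome", family = "binomial")
    res$p[res$score == "cluster_1"]
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("DerSimonian-Laird pooling matches the closed formulas and metafor", {
  # identical estimates: tau2 = 0, pooled = fixed effects
  r0 <- random_effects_meta(c(0.2, 0.2, 0.2), c(0.05, 0.05, 0.05))
  expect_equal(r0$tau2, 0)
  expect_equal(r0$estimate, 0.2)

  r1 <- random_effects_meta(0.3, 0.1)
  expect_equal(r1$estimate, 0.3)
  expect_equal(r1$se, 0.1)

  est <- c(0.10, 0.20, 0.30); ses <- c(0.05, 0.05, 0.05)
  r <- random_effects_meta(est, ses)
  w <- 1 / 0.05^2
  q <- w * sum((est - 0.2)^2)
  expect_equal(r$q, 8.0, tolerance = 1e-10)
  cc <- 3 * w - (3 * w^2) / (3 * w)
  tau2 <- (q - 2) / cc
  expect_equal(r$tau2, tau2, tolerance = 1e-10)
  wst <- rep(1 / (0.05^2 + tau2), 3)
  expect_equal(r$estimate, sum(wst * est) / sum(wst), tolerance = 1e-10)
  expect_equal(r$se, 1 / sqrt(sum(wst)), tolerance = 1e-10)

  # independent cross-check against metafor's DL implementation
  mf <- metafor::rma(yi = est, sei = ses, method = "DL")
  expect_equal(r$estimate, as.numeric(mf$beta), tolerance = 1e-10)
  expect_equal(r$se, mf$se, tolerance = 1e-10)
  expect_equal(r$tau2, mf$tau2, tolerance = 1e-10)
})
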