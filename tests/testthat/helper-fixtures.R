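# shared small fixtures, built once per test run

quiet <- function(expr) suppressMessages(expr)

# a small two-group world with planted axis-1 effect, reused across files
fix_env <- new.env()

small_world <- function() {
  if (!is.null(fix_env$world)) return(fix_env$world)
  cfg <- sim_config(
    n_snvs = 120, block_size = 6,
    n_studies_per_group = c(EUR = 4L, EAS = 4L, AFA = 4L),
    group_fst = c(EUR = 0.02, EAS = 0.12, AFA = 0.15),
    n_axes_true = 2, axis_effects = c(0.6, 0), b0 = 0.05,
    n_haplotypes = 300, seed = 42
  )
  panels <- simulate_haplotype_panels(cfg)
  studies <- quiet(simulate_study_summaries(cfg, panels))
  axes <- compute_axes(studies, n_axes = 2)
  fix_env$world <- list(cfg = cfg, panels = panels, studies = studies,
                        axes = axes)
  fix_env$world
}

# brute-force WLS oracle via explicit normal equations (independent of the
# package's lm.wfit route)
wls_oracle <- function(betas, ses, X) {
  W <- diag(1 / ses^2)
  xtwx <- t(X) %*% W %*% X
  coef <- solve(xtwx, t(X) %*% W %*% betas)
  resid <- betas - X %*% coef
  list(coef = drop(coef),
       se = sqrt(diag(solve(xtwx))),
       rss = drop(t(resid) %*% W %*% resid))
}

# adjusted Rand index between two hard partitions
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
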