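#' Pipeline configuration
#'
#' Bundles the simulation block, analysis thresholds, stage toggles and
#' seeds for a seeded end-to-end run. Seeds are mandatory for every
#' stochastic stage and come from the simulation config's seed.
#'
#' @param sim An [sim_config()] object (the simulation block).
#' @param n_axes Axes of genetic variation for the meta-regression.
#' @param min_studies Minimum contributing studies per SNV.
#' @param p_threshold Genome-wide significance threshold for clumping.
#' @param r2_threshold,clump_window,merge_distance,flank Clumping/locus
#'   parameters (bp; see [greedy_clump()] and [merge_loci()]).
#' @param null_window,null_r2_max Null-SNV selection parameters.
#' @param k Cluster count; `NULL` selects by [select_k()] over `k_range`.
#' @param k_range Candidate cluster counts when `k` is `NULL`.
#' @param bmi Also fit the BMI-adjusted meta-regression.
#' @param min_cluster_size Minimum cluster size for the enrichment scan.
#' @param ps_ancestries Ancestry groups in which testing cohorts are
#'   simulated and scored.
#' @param ps_n Individuals per simulated testing cohort.
#' @param ps_outcome_effects Named numeric: planted log-OR per SD of each
#'   cluster score on the simulated outcome (names `"1"`, `"2"`, ...).
#' @param known_variants Tibble (chr, pos) of previously reported variant
#'   positions used for novelty flagging (default empty: all loci novel).
#' @param stages Character vector of stages to run, in dependency order
#'   among `"meta"`, `"clump"`, `"cluster"`, `"enrich"`, `"ps"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            n_axes = 3,
                            min_studies = 5,
                            p_threshold = 5e-8,
                            r2_threshold = 0.05,
                            clump_window = 5e6,
                            merge_distance = 1e6,
                            flank = 5e5,
                            null_window = 5e4,
                            null_r2_max = 0.05,
                            k = NULL,
                            k_range = 2:6,
                            bmi = FALSE,
                            min_cluster_size = 5,
                            ps_ancestries = names(sim$n_studies_per_group)[1:2],
                            ps_n = 4000L,
                            ps_outcome_effects = c(`1` = 0.2),
                            known_variants = NULL,
                            stages = c("meta", "clump", "cluster",
                                       "enrich", "ps")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> axes -> meta-regression (optionally BMI-adjusted)
#' -> fixed-effects -> clumping/loci -> z-scores -> clustering -> profiles
#' -> enrichment -> partitioned scores -> outcome association -> report, in
#' dependency order, skipping disabled stages. Stages whose dependencies
#' are disabled refuse to run with an informative error. When `outdir` is
#' given, every intermediate table is written there and a run manifest
#' (config hash, per-file checksums, wall-clock per stage) is recorded.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory for intermediate tables and the
#'   manifest.
#' @return An `mx_pipeline_run`: named list of stage outputs plus
#'   `manifest` and `report`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  need <- function(stage, dep) {
    if (!(dep %in% stages)) {
      abort(sprintf("stage '%s' requires stage '%s', which is disabled",
                    stage, dep))
    }
  }
  if ("clump" %in% stages) need("clump", "meta")
  if ("cluster" %in% stages) need("cluster", "clump")
  if ("enrich" %in% stages) need("enrich", "cluster")
  if ("ps" %in% stages) need("ps", "cluster")

  out <- list()
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    val <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    val
  }

  out$panels <- tick("simulate_panels", simulate_haplotype_panels(config$sim))
  out$studies <- tick("simulate_studies",
                      simulate_study_summaries(config$sim, out$panels))

  if ("meta" %in% stages) {
    out$axes <- tick("axes", compute_axes(out$studies, n_axes = config$n_axes))
    out$meta <- tick("meta", run_meta_regression(out$studies, out$axes,
                                                 min_studies = config$min_studies))
    if (config$bmi) {
      out$meta_bmi <- tick("meta_bmi",
                           run_meta_regression(out$studies, out$axes,
                                               min_studies = config$min_studies,
                                               bmi = TRUE))
    }
    out$fe <- tick("fe_meta", run_fixed_effects(out$studies))
    out$lambda_gc <- genomic_control_lambda(out$meta$p_assoc)
  }

  if ("clump" %in% stages) {
    out$signals <- tick("clump", greedy_clump(
      out$meta, out$panels, p_threshold = config$p_threshold,
      r2_threshold = config$r2_threshold, window = config$clump_window))
    loci <- merge_loci(out$signals, config$merge_distance, config$flank)
    known <- config$known_variants %||% tibble::tibble(chr = character(),
                                                       pos = numeric())
    out$loci <- flag_novelty(loci, known)
  }

  if ("cluster" %in% stages) {
    if (nrow(out$signals) < max(config$k_range %||% 2, config$k %||% 2) + 1) {
      abort("too few signals for clustering; increase planted effects or SNV count")
    }
    index_tbl <- out$meta %>%
      dplyr::filter(.data$snv %in% out$signals$index_snv) %>%
      dplyr::select("snv", "chr", "pos", "ea", "nea")
    zs <- tick("simulate_zscores",
               simulate_phenotype_zscores(config$sim, index_snvs = index_tbl))
    # risk allele: the allele with positive pooled log-OR
    fe_idx <- out$fe[match(index_tbl$snv, out$fe$snv), ]
    risk <- tibble::tibble(
      snv = fe_idx$snv,
      risk_allele = ifelse(fe_idx$beta >= 0, fe_idx$ea, fe_idx$nea)
    )
    out$zmatrix <- tick("zscores", compute_zscores(
      zs$trait_stats, risk, attr(zs$zmatrix, "n_phen")))
    out$z_truth <- zs$truth
    if (is.null(config$k)) {
      sel <- tick("select_k", select_k(out$zmatrix, config$k_range,
                                       seed = config$sim$seed))
      out$k_selection <- sel[c("k", "votes")]
      out$cluster_model <- sel$models[[as.character(sel$k)]]
    } else {
      out$cluster_model <- tick("cluster", impute_kmeans(
        out$zmatrix, config$k, seed = config$sim$seed))
    }
    out$profiles <- tick("profiles",
                         cluster_phenotype_association(out$cluster_model))
    out$pca <- disparity_pca(out$cluster_model)

    # cluster-level disease effects and axis-heterogeneity contrasts
    idx_meta <- out$meta[match(names(out$cluster_model$assignment), out$meta$snv), ]
    fe_m <- out$fe[match(idx_meta$snv, out$fe$snv), ]
    out$axis_z <- axis_association_zscores(idx_meta, fe_m)
    out$cluster_t2d <- cluster_t2d_effects(abs(fe_m$beta), fe_m$se^2,
                                           out$cluster_model)
    if (out$cluster_model$k >= 2) {
      out$axis_anova <- cluster_axis_anova(out$axis_z, out$cluster_model)
    }
  }

  if ("enrich" %in% stages) {
    model <- out$cluster_model
    index_tbl <- out$meta %>%
      dplyr::filter(.data$snv %in% names(model$assignment)) %>%
      dplyr::select("snv", "chr", "pos")
    nonsig <- out$meta %>%
      dplyr::filter(.data$p_assoc >= config$p_threshold) %>%
      dplyr::select("snv", "chr", "pos")
    cluster_sets <- lapply(seq_len(model$k), function(cl) {
      idx <- index_tbl[model$assignment[index_tbl$snv] == cl, ]
      nulls <- purrr::map_dfr(seq_len(nrow(idx)), function(i) {
        select_null_snvs(idx[i, ], nonsig, out$panels,
                         window = config$null_window,
                         r2_max = config$null_r2_max)
      }) %>% dplyr::distinct()
      list(index = idx, null = nulls)
    })
    names(cluster_sets) <- seq_len(model$k)
    all_nulls <- dplyr::distinct(dplyr::bind_rows(
      lapply(cluster_sets, `[[`, "null")))
    out$annotations <- tick("simulate_annotations", simulate_annotations(
      config$sim, index_tbl, all_nulls))
    out$enrichment <- tick("enrich", enrichment_scan(
      cluster_sets, out$annotations, out$annotations$cell_types,
      min_cluster_size = config$min_cluster_size))
  }

  if ("ps" %in% stages) {
    model <- out$cluster_model
    idx_snvs <- names(model$assignment)
    ps_rows <- purrr::map_dfr(config$ps_ancestries, function(anc) {
      fe_g <- run_fixed_effects(out$studies, group = anc) %>%
        dplyr::filter(.data$snv %in% idx_snvs)
      tibble::tibble(
        snv = fe_g$snv, ancestry = anc,
        risk_allele = ifelse(fe_g$beta >= 0, fe_g$ea, fe_g$nea),
        weight = abs(fe_g$beta),
        cluster = unname(model$assignment[fe_g$snv])
      )
    })
    out$ps_model <- ps_rows
    results <- purrr::map(config$ps_ancestries, function(anc) {
      pm <- dplyr::filter(ps_rows, .data$ancestry == anc)
      cohort <- simulate_cohort(config$sim, pm, out$panels, ancestry = anc,
                                n_individuals = config$ps_n,
                                outcome_effects = config$ps_outcome_effects,
                                seed_tag = paste0("cohort_", anc))
      maf <- pmin(colMeans(cohort$dosages) / 2,
                  1 - colMeans(cohort$dosages) / 2)
      hwe <- vapply(seq_len(ncol(cohort$dosages)), function(j) {
        d <- cohort$dosages[, j]
        hwe_exact_test(sum(d == 2), sum(d == 1), sum(d == 0))
      }, numeric(1))
      qc <- qc_filter_snvs(tibble::tibble(
        snv = colnames(cohort$dosages), maf = maf,
        info_r2 = NA_real_, hwe_p = hwe))
      pm_qc <- dplyr::filter(pm, .data$snv %in% qc$retained$snv)
      scores <- compute_partitioned_ps(cohort, pm_qc)
      assoc <- associate_outcome(scores, cohort, "outcome",
                                 family = "binomial")
      dplyr::mutate(assoc, ancestry = anc)
    })
    out$ps_results <- dplyr::bind_rows(results)
    out$ps_pooled <- out$ps_results %>%
      dplyr::group_by(.data$outcome, .data$score) %>%
      dplyr::group_modify(~ random_effects_meta(.x$estimate, .x$se)) %>%
      dplyr::ungroup()
  }

  out$report <- generate_report(out, config)
  out$manifest <- build_manifest(config, out, timings, outdir)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  structure(out, class = "mx_pipeline_run")
}

#' Assemble the run report
#'
#' Tabulates signal/locus/novelty counts with percentages, heterogeneity
#' counts at the Bonferroni threshold with the one-sided binomial
#' enrichment P, cluster sizes and temperature tables, enrichment hits,
#' and pooled PS associations. Every number is recomputed from the stage
#' outputs (no report-only arithmetic).
#'
#' @param outputs Stage outputs from [run_pipeline()].
#' @param config The run's [pipeline_config()].
#' @return A named list of report tibbles.
#' @export
generate_report <- function(outputs, config) {
  rep <- list()
  if (!is.null(outputs$signals)) {
    n_sig <- nrow(outputs$signals)
    n_loci <- nrow(outputs$loci)
    rep$discovery <- tibble::tibble(
      n_signals = n_sig, n_loci = n_loci,
      n_novel = sum(!outputs$loci$reported),
      pct_novel = if (n_loci > 0) {
        summarize_discovery(sum(!outputs$loci$reported), n_loci)$percent
      } else NA_real_
    )
    if (n_sig > 0 && !is.null(outputs$meta)) {
      thr <- bonferroni_threshold(0.05, n_sig, digits = NULL)
      idx <- outputs$meta[match(outputs$signals$index_snv, outputs$meta$snv), ]
      n_het <- sum(idx$p_anc_het < thr, na.rm = TRUE)
      n_res <- sum(idx$p_res_het < thr, na.rm = TRUE)
      rep$heterogeneity <- tibble::tibble(
        threshold = signif2(thr),
        n_anc_het = n_het,
        pct_anc_het = summarize_discovery(n_het, n_sig)$percent,
        p_anc_binom = binomial_enrichment_test(n_het, n_sig, thr)$p,
        n_res_het = n_res,
        pct_res_het = summarize_discovery(n_res, n_sig)$percent,
        p_res_binom = binomial_enrichment_test(n_res, n_sig, thr)$p
      )
    }
  }
  if (!is.null(outputs$cluster_model)) {
    rep$cluster_sizes <- tibble::tibble(
      cluster = seq_len(outputs$cluster_model$k),
      n_snvs = tabulate(outputs$cluster_model$assignment,
                        outputs$cluster_model$k)
    )
    rep$temperatures <- outputs$profiles
  }
  if (!is.null(outputs$enrichment) && nrow(outputs$enrichment) > 0) {
    rep$enrichment_hits <- dplyr::filter(outputs$enrichment, .data$significant)
  }
  if (!is.null(outputs$ps_pooled)) rep$ps_pooled <- outputs$ps_pooled
  if (!is.null(outputs$lambda_gc)) rep$lambda_gc <- outputs$lambda_gc
  rep
}

build_manifest <- function(config, out, timings, outdir) {
  list(
    config_hash = digest::digest(config),
    package_version = as.character(utils::packageVersion("metaxes")),
    seed = config$sim$seed,
    stage_seconds = timings,
    outdir = outdir
  )
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && is.data.frame(df)) {
      df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
      readr::write_tsv(df, file.path(outdir, paste0(name, ".tsv")))
    }
  }
  wr(out$axes, "axes")
  wr(out$meta, "meta_regression")
  wr(out$fe, "fixed_effects")
  wr(out$signals, "signals")
  wr(out$loci, "loci")
  if (!is.null(out$zmatrix)) write_zmatrix(out$zmatrix, file.path(outdir, "zscores.tsv"))
  if (!is.null(out$cluster_model)) wr(tidy(out$cluster_model), "clusters")
  wr(out$profiles, "cluster_profiles")
  wr(out$enrichment, "enrichment")
  wr(out$ps_results, "ps_results")
  wr(out$ps_pooled, "ps_pooled")
  if (!is.null(out$annotations)) write_bed(out$annotations, file.path(outdir, "annotations.bed"))
  manifest <- out$manifest
  files <- list.files(outdir, full.names = TRUE)
  manifest$checksums <- setNames(
    vapply(files, digest::digest, character(1), file = TRUE),
    basename(files))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' @export
print.mx_pipeline_run <- function(x, ...) {
  cat("<mx_pipeline_run>\n")
  if (!is.null(x$report$discovery)) {
    cat("  signals:", x$report$discovery$n_signals,
        " loci:", x$report$discovery$n_loci, "\n")
  }
  if (!is.null(x$cluster_model)) cat("  clusters: k =", x$cluster_model$k, "\n")
  if (!is.null(x$ps_pooled)) cat("  PS associations:", nrow(x$ps_pooled), "pooled rows\n")
  invisible(x)
}
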