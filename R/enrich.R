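#' Select LD-independent null SNVs near an index SNV
#'
#' Null SNVs are candidates within `window` bp of the index (inclusive) and
#' not in LD with it — r-squared at most `r2_max` in *every* continental
#' group (a single group above the threshold excludes the candidate).
#' Groups where r-squared is undefined (monomorphic) cannot show LD and do
#' not exclude.
#'
#' @param index_snv One-row tibble (snv, chr, pos).
#' @param candidates Tibble of candidate SNVs (snv, chr, pos).
#' @param panels Named list of haplotype panels.
#' @param window Distance window in bp, inclusive (default 5e4).
#' @param r2_max LD exclusion threshold (default 0.05).
#' @return Tibble of selected null SNVs (possibly empty, logged).
#' @export
select_null_snvs <- function(index_snv, candidates, panels,
                             window = 5e4, r2_max = 0.05) {
  near <- candidates %>%
    dplyr::filter(.data$chr == index_snv$chr,
                  abs(.data$pos - index_snv$pos) <= window,
                  .data$snv != index_snv$snv)
  if (nrow(near) == 0) {
    mx_log("no null SNV candidates near %s", index_snv$snv)
    return(near)
  }
  keep <- vapply(near$snv, function(s) {
    r2 <- ld_r2(index_snv$snv, s, panels)$r2
    all(r2[!is.na(r2)] <= r2_max)
  }, logical(1))
  out <- near[keep, , drop = FALSE]
  if (nrow(out) == 0) mx_log("no null SNVs retained for %s", index_snv$snv)
  out
}

#' Annotate SNVs against genic and cell-type intervals
#'
#' Binary indicator per SNV and annotation class. Intervals are BED
#' convention (0-based, half-open); SNV positions are 1-based, so a SNV at
#' 1-based position `p` overlaps an interval `[start, end)` iff
#' `start < p <= end`. Overlap is computed with GenomicRanges. SNVs on
#' chromosomes absent from the annotation get indicator 0, with one logged
#' warning per chromosome.
#'
#' @param snvs Tibble (snv, chr, pos), positions 1-based.
#' @param annotations An `mx_annotation_set` or a tibble (chr, start, end,
#'   class) in BED convention.
#' @return Tibble: snv plus one 0/1 column per annotation class.
#' @export
annotate_snvs <- function(snvs, annotations) {
  iv <- if (inherits(annotations, "mx_annotation_set")) annotations$intervals else annotations
  classes <- unique(iv$class)
  missing_chr <- setdiff(unique(snvs$chr), unique(iv$chr))
  for (mc in missing_chr) {
    mx_log("chromosome %s has no annotation intervals; indicators set to 0", mc)
  }
  snv_gr <- GenomicRanges::GRanges(
    snvs$chr, IRanges::IRanges(start = snvs$pos, width = 1)
  )
  out <- tibble::tibble(snv = snvs$snv)
  for (cls in classes) {
    sub <- iv[iv$class == cls, , drop = FALSE]
    # BED [start, end) 0-based -> 1-based closed [start + 1, end]
    ann_gr <- GenomicRanges::GRanges(
      sub$chr, IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    )
    # disjoint seqlevels are expected when a chromosome has no intervals;
    # we log that case ourselves above
    hits <- suppressWarnings(GenomicRanges::findOverlaps(snv_gr, ann_gr))
    ind <- integer(nrow(snvs))
    ind[unique(S4Vectors::queryHits(hits))] <- 1L
    out[[cls]] <- ind
  }
  out
}

#' Firth-penalized enrichment test for one cell type
#'
#' Codes index SNVs 1 and null SNVs 0, fits the Firth logistic model
#' `logit P(index) = a0 + a_exon G_exon + a_utr3 G_utr3 + a_utr5 G_utr5 +
#' theta X_celltype`, and tests `theta = 0` by the penalized
#' likelihood-ratio statistic (twice the difference of penalized
#' log-likelihoods between the full model and the model omitting the
#' cell-type indicator), chi-square on 1 df.
#'
#' @param index_snvs,null_snvs Tibbles (snv, chr, pos).
#' @param annotations Annotation set or interval tibble (see
#'   [annotate_snvs()]).
#' @param cell_type Name of the cell-type annotation class to test.
#' @param genic_classes Genic annotation classes to adjust for; classes
#'   constant across the SNVs are dropped from the design.
#' @return One-row tibble: cell_type, theta, se, chisq, p, n_index, n_null,
#'   plus list-column `genic_coef`.
#' @export
enrichment_test <- function(index_snvs, null_snvs, annotations, cell_type,
                            genic_classes = c("exon", "utr3", "utr5")) {
  if (nrow(index_snvs) == 0 || nrow(null_snvs) == 0) {
    abort("need at least one index and one null SNV")
  }
  all_snvs <- dplyr::bind_rows(
    dplyr::mutate(index_snvs[, c("snv", "chr", "pos")], y = 1L),
    dplyr::mutate(null_snvs[, c("snv", "chr", "pos")], y = 0L)
  )
  ann <- annotate_snvs(all_snvs, annotations)
  if (!cell_type %in% names(ann)) ann[[cell_type]] <- 0L
  x_ct <- ann[[cell_type]]
  if (length(unique(x_ct)) < 2) {
    abort(sprintf("cell-type indicator for %s is constant: test undefined", cell_type))
  }
  genic <- intersect(genic_classes, names(ann))
  G <- as.matrix(ann[, genic, drop = FALSE])
  if (ncol(G) > 0) G <- G[, apply(G, 2, function(v) length(unique(v)) > 1), drop = FALSE]

  X_full <- cbind(`(Intercept)` = 1, G, celltype = x_ct)
  fit_full <- firth_logistic(all_snvs$y, X_full)
  # constrained fit: theta = 0 under the full design's Jeffreys penalty
  fit_red <- firth_logistic(all_snvs$y, X_full, fixed = "celltype")
  chisq <- max(0, 2 * (fit_full$loglik_penalized - fit_red$loglik_penalized))
  tibble::tibble(
    cell_type = cell_type,
    theta = unname(fit_full$coef["celltype"]),
    se = unname(fit_full$se["celltype"]),
    chisq = chisq,
    p = pchisq(chisq, 1, lower.tail = FALSE),
    n_index = nrow(index_snvs),
    n_null = nrow(null_snvs),
    genic_coef = list(fit_full$coef[setdiff(names(fit_full$coef),
                                            c("(Intercept)", "celltype"))])
  )
}

#' Scan cell-type enrichment across clusters
#'
#' Runs [enrichment_test()] for every (cluster, cell type) pair, applying
#' the Bonferroni threshold for the cell-type set size. Clusters with fewer
#' index SNVs than `min_cluster_size` are skipped with a logged reason
#' (small clusters give unstable parameter estimates).
#'
#' @param cluster_sets Named list: per cluster, a list with `index`
#'   (tibble of the cluster's index SNVs) and `null` (tibble of its
#'   deduplicated null pool).
#' @param annotations Annotation set or interval tibble.
#' @param cell_types Character vector: the cell-type set to scan (its
#'   length sets the Bonferroni family).
#' @param alpha Family-wise error rate (default 0.05).
#' @param min_cluster_size Minimum index SNVs per cluster (default 5).
#' @return Tibble of [enrichment_test()] rows with `cluster`,
#'   `threshold`, and `significant` columns.
#' @export
enrichment_scan <- function(cluster_sets, annotations, cell_types,
                            alpha = 0.05, min_cluster_size = 5) {
  thr <- bonferroni_threshold(alpha, length(cell_types), digits = NULL)
  purrr::map_dfr(names(cluster_sets), function(cl) {
    cs <- cluster_sets[[cl]]
    if (nrow(cs$index) < min_cluster_size) {
      mx_log("cluster %s skipped: %d index SNVs < minimum %d (unstable estimates)",
             cl, nrow(cs$index), min_cluster_size)
      return(tibble::tibble())
    }
    purrr::map_dfr(cell_types, function(ct) {
      row <- tryCatch(enrichment_test(cs$index, cs$null, annotations, ct),
                      error = function(e) {
                        mx_log("cluster %s, cell type %s: %s", cl, ct,
                               conditionMessage(e))
                        tibble::tibble()
                      })
      if (nrow(row) == 0) return(row)
      dplyr::mutate(row, cluster = cl, threshold = thr,
                    significant = .data$p < thr, .before = 1)
    })
  })
}
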