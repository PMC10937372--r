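#' Simulate genic and cell-type open-chromatin annotations
#'
#' Plants a log fold enrichment of the designated cell type at index SNVs:
#' index SNVs overlap that cell type's peaks with probability `p_index` and
#' null SNVs with `p_null`, so the planted log odds ratio is
#' `theta = log[p_index (1 - p_null) / (p_null (1 - p_index))]`.
#' Non-enriched cell types use `p_null` for index and null SNVs alike.
#' Genic annotations (exon, 3'UTR, 5'UTR) are placed independently of
#' index/null status at configurable rates. All annotations are emitted as
#' genomic intervals in BED convention (0-based, half-open): a SNV at
#' 1-based position `p` that overlaps a feature receives an interval
#' containing `p - 1` in 0-based space.
#'
#' @param config An [sim_config()] object (uses `peak_overlap_probs`).
#' @param index_snvs,null_snvs Tibbles with columns snv, chr, pos (1-based);
#'   must be disjoint in `snv`.
#' @param cell_types Character vector of cell-type names; the first is the
#'   enriched one.
#' @param genic_rates Named numeric: overlap probability for each genic class.
#' @param peak_halfwidth Half-width (bp) of each emitted peak interval.
#' @return An `mx_annotation_set`: list with `intervals` (tibble chr, start,
#'   end, class — BED 0-based half-open), `cell_types`, `theta_true`.
#' @export
simulate_annotations <- function(config, index_snvs, null_snvs,
                                 cell_types = c("enriched_celltype",
                                                "other_celltype_1",
                                                "other_celltype_2"),
                                 genic_rates = c(exon = 0.05, utr3 = 0.03,
                                                 utr5 = 0.02),
                                 peak_halfwidth = 200L) {
  stopifnot(inherits(config, "mx_sim_config"))
  p_index <- config$peak_overlap_probs[1]
  p_null <- config$peak_overlap_probs[2]
  if (any(c(p_index, p_null) %in% c(0, 1))) {
    abort("peak overlap probabilities of 0 or 1 give a degenerate logit")
  }
  if (length(intersect(index_snvs$snv, null_snvs$snv)) > 0) {
    abort("index and null SNV sets must be disjoint")
  }
  set.seed(derive_seed(config$seed, "annotations"))

  all_snvs <- dplyr::bind_rows(
    dplyr::mutate(index_snvs[, c("snv", "chr", "pos")], is_index = TRUE),
    dplyr::mutate(null_snvs[, c("snv", "chr", "pos")], is_index = FALSE)
  )
  n <- nrow(all_snvs)

  interval_for <- function(rows) {
    tibble::tibble(
      chr = all_snvs$chr[rows],
      start = pmax(all_snvs$pos[rows] - 1L - peak_halfwidth, 0L),
      end = all_snvs$pos[rows] + peak_halfwidth
    )
  }

  intervals <- list()
  for (ct in cell_types) {
    p <- if (ct == cell_types[1]) {
      ifelse(all_snvs$is_index, p_index, p_null)
    } else {
      rep(p_null, n)
    }
    hit <- which(runif(n) < p)
    if (length(hit)) {
      intervals[[ct]] <- dplyr::mutate(interval_for(hit), class = ct)
    }
  }
  for (gc in names(genic_rates)) {
    hit <- which(runif(n) < genic_rates[[gc]])
    if (length(hit)) {
      intervals[[gc]] <- dplyr::mutate(interval_for(hit), class = gc)
    }
  }
  theta <- log(p_index * (1 - p_null) / (p_null * (1 - p_index)))
  empty <- tibble::tibble(chr = character(), start = integer(),
                          end = integer(), class = character())
  structure(list(
    intervals = dplyr::bind_rows(c(list(empty), intervals)),
    cell_types = cell_types,
    genic_classes = names(genic_rates),
    theta_true = theta
  ), class = "mx_annotation_set")
}

#' @export
print.mx_annotation_set <- function(x, ...) {
  cat("<mx_annotation_set>", nrow(x$intervals), "intervals;",
      length(x$cell_types), "cell types; planted theta =",
      round(x$theta_true, 3), "\n")
  invisible(x)
}
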