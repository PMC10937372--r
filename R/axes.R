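#' Axes of genetic variation from allele-frequency distances
#'
#' Builds the study-level covariates of the meta-regression: a pairwise
#' distance matrix of mean absolute effect-allele-frequency differences over
#' SNVs reported in every study (alleles aligned to a common reference
#' first), decomposed by classical multidimensional scaling (double-centred
#' squared distances, eigendecomposition). The top `n_axes` principal
#' coordinates — eigenvectors scaled by the square root of their
#' eigenvalues, ordered by decreasing eigenvalue — are returned; the
#' downstream regression statistics are invariant to affine rescaling of
#' these covariates.
#'
#' @param studies An `mx_study_set` or a long summary tibble with columns
#'   study, snv, ea, nea, eaf.
#' @param n_axes Number of axes to retain (default 3).
#' @param metric Distance between studies: mean `"absolute"` (default) or
#'   mean `"squared"` EAF difference over shared SNVs.
#' @param drop_ambiguous Exclude strand-ambiguous (A/T, C/G) SNVs before
#'   alignment (default `TRUE`, logged).
#' @return An `mx_axes` tibble (study, axis1..axisK) with attribute
#'   `eigenvalues`; coordinates are column-centred.
#' @export
compute_axes <- function(studies, n_axes = 3,
                         metric = c("absolute", "squared"),
                         drop_ambiguous = TRUE) {
  metric <- match.arg(metric)
  summ <- if (inherits(studies, "mx_study_set")) studies$summaries else studies
  study_ids <- unique(summ$study)
  n_study <- length(study_ids)
  if (n_study < n_axes + 2) {
    abort(sprintf("need at least n_axes + 2 = %d studies, got %d",
                  n_axes + 2, n_study))
  }
  aligned <- align_to_reference(summ, drop_ambiguous = drop_ambiguous)

  wide <- aligned %>%
    dplyr::select("study", "snv", "eaf") %>%
    tidyr::pivot_wider(names_from = "study", values_from = "eaf") %>%
    tidyr::drop_na()
  if (nrow(wide) == 0) abort("no SNV is reported in all studies")
  eafm <- as.matrix(wide[, study_ids])

  d <- matrix(0, n_study, n_study, dimnames = list(study_ids, study_ids))
  for (i in seq_len(n_study - 1)) {
    for (j in (i + 1):n_study) {
      diffs <- eafm[, i] - eafm[, j]
      d[i, j] <- d[j, i] <- if (metric == "absolute") mean(abs(diffs)) else mean(diffs^2)
    }
  }
  if (all(d == 0)) abort("all pairwise study distances are zero: axes are degenerate")

  mds <- stats::cmdscale(d, k = n_axes, eig = TRUE)
  if (ncol(mds$points) < n_axes) {
    abort("distance matrix supports fewer positive-eigenvalue axes than requested")
  }
  coords <- mds$points
  colnames(coords) <- paste0("axis", seq_len(n_axes))
  out <- tibble::tibble(study = study_ids) %>%
    dplyr::bind_cols(tibble::as_tibble(coords))
  attr(out, "eigenvalues") <- mds$eig[seq_len(n_axes)]
  attr(out, "n_shared_snvs") <- nrow(wide)
  class(out) <- c("mx_axes", class(out))
  out
}

# Align per-study records to one reference effect allele per SNV (the first
# study's orientation); swapped records get eaf -> 1 - eaf and beta -> -beta.
# Records whose allele pair matches neither orientation are dropped with a log.
align_to_reference <- function(summ, drop_ambiguous = TRUE) {
  if (drop_ambiguous) {
    amb <- (summ$ea == "A" & summ$nea == "T") | (summ$ea == "T" & summ$nea == "A") |
      (summ$ea == "C" & summ$nea == "G") | (summ$ea == "G" & summ$nea == "C")
    if (any(amb)) {
      mx_log("excluded %d strand-ambiguous study-SNV records",
             sum(amb))
      summ <- summ[!amb, , drop = FALSE]
    }
  }
  ref <- summ %>%
    dplyr::distinct(.data$snv, .keep_all = TRUE) %>%
    dplyr::select("snv", ref_ea = "ea", ref_nea = "nea")
  out <- summ %>%
    dplyr::left_join(ref, by = "snv") %>%
    dplyr::mutate(
      orient = dplyr::case_when(
        .data$ea == .data$ref_ea & .data$nea == .data$ref_nea ~ 1,
        .data$ea == .data$ref_nea & .data$nea == .data$ref_ea ~ -1,
        TRUE ~ NA_real_
      )
    )
  n_bad <- sum(is.na(out$orient))
  if (n_bad > 0) mx_log("excluded %d records with inconsistent alleles", n_bad)
  out <- dplyr::filter(out, !is.na(.data$orient))
  out$eaf <- ifelse(out$orient == 1, out$eaf, 1 - out$eaf)
  if ("beta" %in% names(out)) out$beta <- out$orient * out$beta
  out$ea <- out$ref_ea
  out$nea <- out$ref_nea
  dplyr::select(out, -"ref_ea", -"ref_nea", -"orient")
}
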