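#' Greedy clumping of significant SNVs into independent signals
#'
#' Iterates SNVs with `p < p_threshold` in ascending P (ties broken by
#' chromosome, position, then alleles, for platform-independent
#' determinism). Each still-unassigned SNV becomes an index; unassigned
#' significant SNVs on the same chromosome, strictly less than `window` bp
#' from the index, and with max-over-groups r-squared above `r2_threshold`,
#' join its clump. Membership distance is measured from the index only. The
#' resulting index SNVs are pairwise independent at the r-squared threshold.
#'
#' @param meta_results Tibble with columns snv, chr, pos, and a P-value
#'   column (`p_col`).
#' @param panels Named list of haplotype panels (the LD reference).
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param r2_threshold LD threshold for clump membership (default 0.05).
#' @param window Maximum index-to-member distance in bp, strict (default
#'   5e6).
#' @param p_col Name of the P-value column (default `"p_assoc"`).
#' @return Tibble of signals: signal_id, index_snv, chr, pos, p, n_members,
#'   members (list-column of member SNV ids, index included).
#' @export
greedy_clump <- function(meta_results, panels, p_threshold = 5e-8,
                         r2_threshold = 0.05, window = 5e6,
                         p_col = "p_assoc") {
  df <- meta_results
  df$p <- df[[p_col]]
  sig <- df %>%
    dplyr::filter(.data$p < p_threshold) %>%
    dplyr::arrange(.data$p, .data$chr, .data$pos, .data$snv)
  if (nrow(sig) == 0) {
    return(tibble::tibble(signal_id = integer(), index_snv = character(),
                          chr = character(), pos = integer(), p = numeric(),
                          n_members = integer(), members = list()))
  }
  assigned <- rep(FALSE, nrow(sig))
  signals <- list()
  for (i in seq_len(nrow(sig))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    cand <- which(!assigned &
                    sig$chr == sig$chr[i] &
                    abs(sig$pos - sig$pos[i]) < window)
    members <- sig$snv[i]
    if (length(cand) > 0) {
      r2 <- ld_r2_max_many(sig$snv[i], sig$snv[cand], panels)
      join <- cand[!is.na(r2) & r2 > r2_threshold]
      assigned[join] <- TRUE
      members <- c(members, sig$snv[join])
    }
    signals[[length(signals) + 1L]] <- tibble::tibble(
      index_snv = sig$snv[i], chr = sig$chr[i], pos = sig$pos[i],
      p = sig$p[i], n_members = length(members), members = list(members)
    )
  }
  dplyr::bind_rows(signals) %>%
    dplyr::mutate(signal_id = dplyr::row_number(), .before = 1)
}

#' Merge index SNVs into loci
#'
#' Single-linkage chaining: index SNVs on the same chromosome separated by
#' strictly less than `merge_distance` belong to the same locus (merging is
#' transitive). Locus bounds extend `flank` bp beyond the extreme member
#' index positions, floored at 1.
#'
#' @param signals Signal tibble from [greedy_clump()].
#' @param merge_distance Maximum index separation, strict (default 1e6 bp).
#' @param flank Flank added on each side (default 5e5 bp).
#' @return Tibble of loci: locus_id, chr, start, end, n_signals, signal_ids
#'   (list-column).
#' @export
merge_loci <- function(signals, merge_distance = 1e6, flank = 5e5) {
  if (nrow(signals) == 0) {
    return(tibble::tibble(locus_id = integer(), chr = character(),
                          start = numeric(), end = numeric(),
                          n_signals = integer(), signal_ids = list()))
  }
  signals %>%
    dplyr::arrange(.data$chr, .data$pos) %>%
    dplyr::group_by(.data$chr) %>%
    dplyr::mutate(
      gap = .data$pos - dplyr::lag(as.numeric(.data$pos), default = -Inf),
      chain = cumsum(.data$gap >= merge_distance)
    ) %>%
    dplyr::group_by(.data$chr, .data$chain) %>%
    dplyr::summarise(
      start = max(1, min(.data$pos) - flank),
      end = max(.data$pos) + flank,
      n_signals = dplyr::n(),
      signal_ids = list(.data$signal_id),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$chr, .data$start) %>%
    dplyr::mutate(locus_id = dplyr::row_number(), .before = 1) %>%
    dplyr::select(-"chain")
}

#' Flag previously reported versus novel loci
#'
#' A locus counts as previously reported iff any known variant position
#' falls within its closed interval `[start, end]` on the same chromosome.
#'
#' @param loci Locus tibble from [merge_loci()].
#' @param known_variants Tibble with columns chr, pos (may be empty).
#' @return `loci` with a logical `reported` column (`FALSE` = novel).
#' @export
flag_novelty <- function(loci, known_variants) {
  loci$reported <- vapply(seq_len(nrow(loci)), function(i) {
    any(known_variants$chr == loci$chr[i] &
          known_variants$pos >= loci$start[i] &
          known_variants$pos <= loci$end[i])
  }, logical(1))
  loci
}

#' Discovery count summaries
#'
#' Percentage reporting for discovery counts: `100 * numerator /
#' denominator`, rounded to one decimal place.
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @return One-row tibble: numerator, denominator, percent.
#' @export
summarize_discovery <- function(numerator, denominator) {
  if (denominator <= 0) abort("denominator must be positive")
  tibble::tibble(
    numerator = numerator, denominator = denominator,
    percent = round(100 * numerator / denominator, 1)
  )
}
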