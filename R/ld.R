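#' Linkage disequilibrium r-squared between two SNVs
#'
#' Squared Pearson correlation between the 0/1 haplotype allele vectors of
#' the two SNVs, per continental-group panel, plus the maximum over groups.
#' A group in which either SNV is monomorphic has undefined r-squared and
#' is excluded from the maximum; if every group is undefined an error is
#' raised.
#'
#' @param snv_a,snv_b SNV ids present in every panel.
#' @param panels Named list of `mx_haplotype_panel` objects.
#' @return Tibble: group, r2, plus attribute `max_r2`; also accessible as
#'   `ld_r2_max()`.
#' @export
ld_r2 <- function(snv_a, snv_b, panels) {
  r2 <- vapply(panels, function(p) {
    a <- p$haplotypes[, snv_a]
    b <- p$haplotypes[, snv_b]
    if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
    stats::cor(a, b)^2
  }, numeric(1))
  if (all(is.na(r2))) {
    abort(sprintf("r2 undefined in every group for %s vs %s", snv_a, snv_b))
  }
  out <- tibble::tibble(group = names(panels), r2 = unname(r2))
  attr(out, "max_r2") <- max(r2, na.rm = TRUE)
  out
}

#' @rdname ld_r2
#' @export
ld_r2_max <- function(snv_a, snv_b, panels) {
  attr(ld_r2(snv_a, snv_b, panels), "max_r2")
}

# vectorized: max-over-groups r2 between one index SNV and many candidates
ld_r2_max_many <- function(index_snv, snvs, panels) {
  if (length(snvs) == 0) return(numeric(0))
  r2 <- sapply(panels, function(p) {
    a <- p$haplotypes[, index_snv]
    B <- p$haplotypes[, snvs, drop = FALSE]
    va <- stats::var(a)
    vb <- apply(B, 2, stats::var)
    r <- suppressWarnings(as.vector(stats::cor(a, B)))
    r2 <- r^2
    r2[va == 0 | vb == 0] <- NA_real_
    r2
  })
  r2 <- matrix(r2, nrow = length(snvs))
  out <- apply(r2, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  setNames(out, snvs)
}
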