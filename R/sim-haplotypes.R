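#' Simulate per-ancestry haplotype reference panels
#'
#' Draws a haplotype panel per ancestry group with block-wise LD and
#' Balding-Nichols allele-frequency divergence. Ancestral allele frequencies
#' are shared across groups; each group's frequency for a SNV is drawn
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`, with
#' `F` the group's divergence parameter (`F = 0` returns `p` exactly).
#' Within an LD block, each haplotype carries one latent uniform; a SNV
#' allele copies the block's latent uniform (thresholded at the group
#' frequency) with probability `ld_within`, and is an independent Bernoulli
#' draw otherwise. Marginal allele frequencies are therefore exact
#' Balding-Nichols draws, while SNVs in a block are correlated and SNVs in
#' different blocks are independent.
#'
#' @param config An [sim_config()] object.
#' @param ancestral_freqs Optional numeric vector of ancestral allele
#'   frequencies (length `n_snvs`); by default drawn uniform on
#'   `[0.05, 0.95]`.
#' @return A named list (one element per ancestry group) of
#'   `mx_haplotype_panel` objects: list with `group`, `haplotypes`
#'   (haplotype x SNV 0/1 matrix), `snvs` (tibble: snv, chr, pos, ea, nea,
#'   block), and `freqs` (the Balding-Nichols group frequencies).
#' @export
simulate_haplotype_panels <- function(config, ancestral_freqs = NULL) {
  stopifnot(inherits(config, "mx_sim_config"))
  if (config$block_size < 1L) abort("block size must be positive")
  set.seed(derive_seed(config$seed, "haplotypes"))
  m <- config$n_snvs
  groups <- names(config$n_studies_per_group)

  if (is.null(ancestral_freqs)) {
    ancestral_freqs <- runif(m, 0.05, 0.95)
  }
  if (length(ancestral_freqs) != m) abort("`ancestral_freqs` must have length n_snvs")

  # one shared coordinate space: positions strictly increasing, 1-based
  pos <- cumsum(sample(2000:20000, m, replace = TRUE))
  block <- (seq_len(m) - 1L) %/% config$block_size + 1L
  # strand-unambiguous allele pairs only (purine/pyrimidine mixes)
  pairs <- matrix(c("A", "G", "A", "C", "T", "C", "T", "G"), ncol = 2, byrow = TRUE)
  pick <- sample(nrow(pairs), m, replace = TRUE)
  snvs <- tibble::tibble(
    snv = sprintf("snv_%05d", seq_len(m)),
    chr = "chr1", pos = pos,
    ea = pairs[pick, 1], nea = pairs[pick, 2],
    block = block
  )

  panels <- lapply(groups, function(g) {
    fst <- config$group_fst[[g]]
    f <- if (fst == 0) {
      ancestral_freqs
    } else {
      shape1 <- ancestral_freqs * (1 - fst) / fst
      shape2 <- (1 - ancestral_freqs) * (1 - fst) / fst
      stats::rbeta(m, shape1, shape2)
    }
    nh <- config$n_haplotypes
    # latent block uniforms per haplotype: comonotone copula within block
    u_block <- matrix(runif(nh * max(block)), nh, max(block))
    copy <- matrix(runif(nh * m) < config$ld_within, nh, m)
    fresh <- matrix(runif(nh * m), nh, m)
    q <- ifelse(copy, u_block[, block, drop = FALSE], fresh)
    H <- 1L * (q < matrix(f, nh, m, byrow = TRUE))
    colnames(H) <- snvs$snv
    structure(list(group = g, haplotypes = H, snvs = snvs, freqs = f),
              class = "mx_haplotype_panel")
  })
  names(panels) <- groups
  panels
}

#' @export
print.mx_haplotype_panel <- function(x, ...) {
  cat("<mx_haplotype_panel> group", x$group, ":",
      nrow(x$haplotypes), "haplotypes x", ncol(x$haplotypes), "SNVs\n")
  invisible(x)
}
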