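mk_panel <- function(H, group = "G1", pos = NULL) {
  m <- ncol(H)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  snvs <- tibble::tibble(snv = colnames(H), chr = "chr1", pos = pos,
                         ea = "A", nea = "G", block = 1L)
  structure(list(group = group, haplotypes = H, snvs = snvs,
                 freqs = colMeans(H)), class = "mx_haplotype_panel")
}

test_that("r2 is 1 for identical columns, ~0 for independent ones, and exact on 2x2 counts", {
  set.seed(51)
  a <- rbinom(10000, 1, 0.4)
  b <- rbinom(10000, 1, 0.4)
  H <- cbind(s1 = a, s2 = a, s3 = b)
  panels <- list(G1 = mk_panel(H))
  expect_equal(ld_r2_max("s1", "s2", panels), 1)
  expect_lt(ld_r2_max("s1", "s3", panels), 0.01)

  # haplotype table (AB, Ab, aB, ab) = (40, 10, 10, 40) over 100
  x <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  y <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  H2 <- cbind(s1 = x, s2 = y)
  expect_equal(ld_r2_max("s1", "s2", list(G1 = mk_panel(H2))),
               (0.4 * 0.4 - 0.1 * 0.1)^2 / (0.25 * 0.25),
               tolerance = 1e-12)

  # monomorphic in one group: excluded from the max; all groups -> error
  Hm <- cbind(s1 = rep(1, 100), s2 = rbinom(100, 1, 0.5))
  panels2 <- list(G1 = mk_panel(H2), G2 = mk_panel(Hm))
  r <- ld_r2("s1", "s2", panels2)
  expect_true(is.na(r$r2[r$group == "G2"]))
  expect_equal(attr(r, "max_r2"), 0.36, tolerance = 1e-12)
  expect_error(ld_r2("s1", "s2", list(G2 = mk_panel(Hm))), "undefined")
})

# deterministic 6-SNV toy: r2 blocks {1,3} and {2,4,5}; SNV 6 independent
toy_clump_world <- function() {
  set.seed(52)
  n <- 2000
  u1 <- rbinom(n, 1, 0.5)
  u2 <- rbinom(n, 1, 0.5)
  u3 <- rbinom(n, 1, 0.5)
  H <- cbind(s1 = u1, s2 = u2, s3 = u1, s4 = u2, s5 = u2, s6 = u3)
  panels <- list(G1 = mk_panel(H, pos = c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5)))
  meta <- tibble::tibble(
    snv = paste0("s", 1:6), chr = "chr1",
    pos = c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5),
    p_assoc = c(1e-20, 1e-18, 1e-16, 1e-14, 1e-12, 1e-3)
  )
  list(panels = panels, meta = meta)
}

test_that("greedy clumping reproduces the hand-enumerated toy and the partition property", {
  w <- toy_clump_world()
  sig <- greedy_clump(w$meta, w$panels, p_threshold = 5e-8)
  expect_equal(nrow(sig), 2)
  expect_equal(sig$index_snv, c("s1", "s2"))
  expect_setequal(sig$members[[1]], c("s1", "s3"))
  expect_setequal(sig$members[[2]], c("s2", "s4", "s5"))
  # s6 is above the threshold: excluded entirely
  expect_false("s6" %in% unlist(sig$members))
  # partition property: each significant SNV in exactly one signal
  all_members <- unlist(sig$members)
  expect_equal(sort(all_members), sort(unique(all_members)))
  # index SNVs pairwise independent (brute force)
  expect_lte(ld_r2_max("s1", "s2", w$panels), 0.05)

  # single significant SNV and empty input
  one <- greedy_clump(w$meta[1, ], w$panels)
  expect_equal(one$members[[1]], "s1")
  expect_equal(nrow(greedy_clump(w$meta[6, , drop = FALSE], w$panels)), 0)
})

test_that("clump output is invariant to input row order", {
  w <- toy_clump_world()
  s1 <- greedy_clump(w$meta, w$panels)
  s2 <- greedy_clump(w$meta[sample(6), ], w$panels)
  expect_equal(s1$index_snv, s2$index_snv)
  expect_equal(lapply(s1$members, sort), lapply(s2$members, sort))
})

test_that("the clump window is strict and measured from the index", {
  set.seed(53)
  n <- 1000
  u <- rbinom(n, 1, 0.5)
  v <- ifelse(rbinom(n, 1, 0.9) == 1, u, rbinom(n, 1, 0.5))
  H <- cbind(a = u, b = v)
  # b is 5 Mb away exactly: strict window excludes it
  panels <- list(G1 = mk_panel(H, pos = c(1L, 5000001L)))
  meta <- tibble::tibble(snv = c("a", "b"), chr = "chr1",
                         pos = c(1, 5000001), p_assoc = c(1e-20, 1e-15))
  sig <- greedy_clump(meta, panels)
  expect_equal(nrow(sig), 2)
  # just inside the window it joins
  panels2 <- list(G1 = mk_panel(H, pos = c(1L, 4999999L)))
  meta2 <- dplyr::mutate(meta, pos = c(1, 4999999))
  expect_equal(nrow(greedy_clump(meta2, panels2)), 1)
})

test_that("locus merging is single-linkage with exact flanks and strict distance", {
  sig <- function(pos) tibble::tibble(signal_id = seq_along(pos),
                                      index_snv = paste0("s", seq_along(pos)),
                                      chr = "chr1", pos = pos,
                                      p = 1e-10, n_members = 1,
                                      members = as.list(paste0("s", seq_along(pos))))
  l1 <- merge_loci(sig(c(1e6, 1.9e6)))
  expect_equal(nrow(l1), 1)
  expect_equal(c(l1$start, l1$end), c(5e5, 2.4e6))

  l2 <- merge_loci(sig(c(1e6, 2.1e6)))
  expect_equal(nrow(l2), 2)

  # transitive chaining: adjacent gaps 0.9 Mb, ends 1.8 Mb apart
  l3 <- merge_loci(sig(c(1e6, 1.9e6, 2.8e6)))
  expect_equal(nrow(l3), 1)
  expect_equal(c(l3$start, l3$end), c(5e5, 3.3e6))

  # exactly 1 Mb apart is two loci (strict); floor at 1
  expect_equal(nrow(merge_loci(sig(c(1e6, 2e6)))), 2)
  expect_equal(merge_loci(sig(2e5))$start, 1)
})

test_that("novelty uses closed locus bounds", {
  loci <- tibble::tibble(locus_id = 1:2, chr = "chr1",
                         start = c(1e6, 5e6), end = c(2e6, 6e6))
  known <- tibble::tibble(chr = "chr1", pos = 1e6)  # exactly at start
  fl <- flag_novelty(loci, known)
  expect_true(fl$reported[1])
  expect_false(fl$reported[2])
  fl2 <- flag_novelty(loci, tibble::tibble(chr = character(), pos = numeric()))
  expect_false(any(fl2$reported))
  # midpoint and end+1
  expect_true(flag_novelty(loci, tibble::tibble(chr = "chr1", pos = 1.5e6))$reported[1])
  expect_false(flag_novelty(loci, tibble::tibble(chr = "chr1", pos = 2e6 + 1))$reported[1])
})

test_that("discovery percentages reproduce the printed ratios", {
  expect_equal(summarize_discovery(145, 611)$percent, 23.7)
  expect_equal(summarize_discovery(36, 39)$percent, 92.3)
  expect_equal(summarize_discovery(127, 1289)$percent, 9.9)
  expect_equal(summarize_discovery(118, 127)$percent, 92.9)
  expect_equal(summarize_discovery(4, 1289)$percent, 0.3)
  expect_equal(summarize_discovery(0, 10)$percent, 0)
  expect_error(summarize_discovery(1, 0), "positive")
})
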