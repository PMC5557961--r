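test_that("composite profiles average bins and collapse degenerate bands", {
  tr <- vec_track(rep(2, 5000), rep(0, 5000))
  anchors <- tibble::tibble(chrom = "chrT", pos = c(1500, 2500, 3500),
                            strand = "+")
  cp <- composite_profile(tr, anchors, bin_size = 20, flank = 200,
                          n_boot = 50, seed = 1)
  expect_equal(cp$profile$mean, rep(40, 20))
  expect_equal(cp$profile$lo, cp$profile$mean)   # identical anchors: no spread
  expect_equal(cp$profile$hi, cp$profile$mean)

  single <- composite_profile(tr, anchors[1, ], bin_size = 20, flank = 100,
                              n_boot = 20, seed = 1)
  expect_equal(single$profile$lo, single$profile$mean)
  expect_equal(single$profile$hi, single$profile$mean)
  expect_error(composite_profile(tr, anchors[0, ]), "empty")

  # deterministic given seed; tidy() exposes the tibble
  cp2 <- composite_profile(tr, anchors, bin_size = 20, flank = 200,
                           n_boot = 50, seed = 1)
  expect_identical(tidy(cp), tidy(cp2))
})

test_that("bootstrap band narrows with anchor count and covers a known mean", {
  mk_cp <- function(n_anchors, seed) {
    withr::with_seed(seed, {
      len <- 400 * (n_anchors + 2)
      tr <- vec_track(rpois(len, 0.5), numeric(len))
      anchors <- tibble::tibble(chrom = "chrT",
                                pos = 400 * seq_len(n_anchors) + 100,
                                strand = "+")
    })
    composite_profile(tr, anchors, bin_size = 20, flank = 100,
                      n_boot = 300, seed = seed)
  }
  widths <- vapply(c(10, 100, 400), function(n) {
    cp <- mk_cp(n, seed = 5)
    median(cp$profile$hi - cp$profile$lo)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # with many anchors the band hugs the true mean 0.5 * 20 = 10
  cp <- mk_cp(400, seed = 6)
  expect_true(all(cp$profile$lo <= 10.8 & cp$profile$hi >= 9.2))
})

test_that("group scaling uses one shared constant and is idempotent", {
  tr_a <- vec_track(rep(4, 3000), numeric(3000))
  tr_b <- vec_track(rep(2, 3000), numeric(3000))
  anchors <- tibble::tibble(chrom = "chrT", pos = 1500, strand = "+")
  pa <- composite_profile(tr_a, anchors, 20, 100, n_boot = 10, seed = 1)
  pb <- composite_profile(tr_b, anchors, 20, 100, n_boot = 10, seed = 1)
  sc <- scaled_profiles(list(A = pa, B = pb))
  expect_equal(max(sc$A$profile$mean), 1)
  expect_equal(unique(sc$B$profile$mean), 0.5)
  expect_equal(attr(sc, "scale_max"), 80)
  # within-group ratios preserved exactly
  expect_equal(sc$A$profile$mean / sc$B$profile$mean,
               pa$profile$mean / pb$profile$mean)
  sc2 <- scaled_profiles(sc)
  expect_equal(sc2$A$profile$mean, sc$A$profile$mean)
})

test_that("heatmaps sort rows by the declared key with deterministic ties", {
  tr <- toy_track(20000, seed = 2, lambda = 0.3)
  el <- tibble::tibble(id = c("e1", "e2", "e3"), chrom = "chrT",
                       pos = c(5000, 9000, 13000), strand = "+",
                       intersummit_distance = c(30, 120, 80))
  hm <- heatmap_matrix(tr, el, bin_size = 10, flank = 500,
                       sort_key = "intersummit_distance")
  expect_equal(rownames(hm$matrix), c("e1", "e3", "e2"))
  # values equal query_bins row-wise
  expect_equal(unname(hm$matrix["e2", ]),
               query_bins(tr, "chrT", 9000, "+", 10, 50, "sense"))

  el$intersummit_distance <- c(7, 7, 7)
  hm2 <- heatmap_matrix(tr, el, 10, 500, sort_key = "intersummit_distance")
  expect_equal(rownames(hm2$matrix), c("e1", "e2", "e3"))  # ties by id

  hp <- heatmap_matrix(tr, el, bin_size = 4, flank = 200,
                       paired_strands = TRUE)
  expect_equal(dim(hp$matrix_sense), c(3, 100))
  expect_equal(unname(hp$matrix_antisense["e1", ]),
               query_bins(tr, "chrT", 5000, "+", 4, 50, "antisense"))
})

test_that("factor sites are categorized with 1-bp overlap and precedence", {
  prom <- tibble::tibble(chrom = "c", start = 1000L, end = 1500L)
  dtre <- tibble::tibble(chrom = "c", start = c(1400L, 3000L),
                         end = c(1900L, 3400L))
  peaks <- tibble::tibble(
    chrom = "c",
    start = c(1450L, 2999L, 5000L, 2600L),
    end = c(1460L, 3000L, 5100L, 3001L))
  out <- categorize_factor_sites(peaks, prom, dtre)
  # peak 1 overlaps both -> promoter precedence; peak 2 ends at 3000 (half-open:
  # no overlap); peak 4 reaches 1 bp into the dTRE
  expect_equal(out$sites$category,
               c("promoter", "untranscribed", "untranscribed", "dTRE"))
  expect_equal(sum(out$counts$n), nrow(peaks))
  expect_equal(sum(out$counts$percent), 100)
  out2 <- categorize_factor_sites(peaks, prom, dtre, precedence = "dtre")
  expect_equal(out2$sites$category[1], "dTRE")
})

test_that("gene binding windows and summit-to-pause distances are exact", {
  genes <- filter_genes(tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chrT",
    start = c(10000L, 40000L), end = c(20000L, 50000L),
    strand = c("+", "-")))
  quants <- tibble::tibble(
    gene_id = c("gp", "gm"),
    pause_start = c(10020, 49910), pause_end = c(10070, 49960))
  # summit exactly at the plus-gene pause midpoint
  pk1 <- tibble::tibble(chrom = "chrT", start = 10000L, end = 10100L,
                        summit = 10045L)
  out1 <- gene_binding(pk1, genes, quants)
  expect_true(out1$bound[1])
  expect_equal(out1$summit_to_pause[1], 0)
  expect_false(out1$bound[2])

  # peak just inside the -2500 upstream edge of the minus-strand gene
  pk2 <- tibble::tibble(chrom = "chrT", start = 52498L, end = 52600L,
                        summit = 52510L)
  out2 <- gene_binding(pk2, genes, quants)
  expect_true(out2$bound[2])
  expect_lt(out2$summit_to_pause[2], 0)  # upstream of the pause
  # one bp further and the window no longer overlaps
  pk3 <- tibble::tibble(chrom = "chrT", start = 52500L, end = 52600L,
                        summit = 52550L)
  expect_false(gene_binding(pk3, genes, quants)$bound[2])
})

test_that("binding-score conversion maps the intensity range onto [107, 1000]", {
  raw <- c(5, 1, 3)
  sc <- convert_binding_score(raw)
  expect_equal(sc[2], 107)
  expect_equal(sc[1], 1000)
  expect_equal(sc[3], (107 + 1000) / 2)  # midpoint raw -> 553.5
  expect_warning(constant <- convert_binding_score(c(2, 2)), "constant")
  expect_equal(constant, c(553.5, 553.5))
})

test_that("group statistics match hand-computed rank formulas", {
  x <- c(3, 1, 4, 1.5, 5)
  y <- 2 * x + 1
  gs <- group_stats(x, y = y)
  expect_equal(gs$spearman$rho, 1)

  # hand-computed Spearman on a fixed permutation (no ties)
  x2 <- c(1, 2, 3, 4, 5)
  y2 <- c(2, 1, 4, 3, 5)
  d2 <- rank(x2) - rank(y2)
  rho_hand <- 1 - 6 * sum(d2^2) / (5 * 24)
  expect_equal(group_stats(x2, y = y2)$spearman$rho, rho_hand)

  # Mann-Whitney U equals the count of dominating pairs
  a <- c(1, 2, 3); b <- c(4, 5, 6, 7)
  gs2 <- group_stats(c(a, b), groups = rep(c("lo", "hi"), c(3, 4)))
  u <- gs2$mann_whitney$u
  expect_equal(u, sum(outer(a, b, ">")))  # 0
  # identical groups: no evidence of a shift
  gs3 <- group_stats(rep(c(1, 2, 3), 2), groups = rep(c("g1", "g2"), each = 3))
  expect_gte(gs3$mann_whitney$p_value, 0.99)
})
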