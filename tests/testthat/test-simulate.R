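tiny_params <- function(seed = 5, ...) {
  sim_params(n_genes = 6, n_dtres = 4, n_untranscribed_sites = 3,
             n_long_genes = 1, chrom_length = 6e5, seed = seed, ...)
}

test_that("generate_genome satisfies its structural invariants", {
  p <- small_params()
  tr <- generate_genome(p)
  g <- tr$genes
  expect_true(all(g$length >= 500))
  expect_gte(sum(g$length > 150000), 3)
  expect_true(all(g$class %in% c("Up", "Down", "UnCh", "UnExp")))
  # same-strand genes never overlap
  for (s in c("+", "-")) {
    gs <- g[g$strand == s, ]
    gs <- gs[order(gs$start), ]
    if (nrow(gs) > 1) expect_true(all(gs$start[-1] >= gs$end[-nrow(gs)]))
  }
  # dTREs keep clear of annotated TSSs
  d <- tr$dtres
  for (i in seq_len(nrow(d))) {
    expect_false(any(g$tss >= d$start[i] & g$tss < d$end[i]))
  }
  expect_true(all(d$summit_minus >= d$start & d$summit_plus < d$end))
})

test_that("the synthetic genome is deterministic and class draws are seeded", {
  p <- small_params(seed = 23)
  expect_identical(generate_genome(p), generate_genome(p))
  t1 <- simulate_tracks(generate_genome(p), p, "HS", 2)
  t2 <- simulate_tracks(generate_genome(p), p, "HS", 2)
  expect_identical(t1$plus, t2$plus)
  expect_identical(t1$minus, t2$minus)
  # different seeds move the layout
  expect_false(identical(generate_genome(small_params(seed = 24))$genes$start,
                         generate_genome(p)$genes$start))
  # expected class proportions (binomial bound, 4 sigma)
  p2 <- sim_params(n_genes = 50, frac_up = 0.2, frac_down = 0.4, seed = 7,
                   chrom_length = 3e6)
  cls <- table(factor(generate_genome(p2)$genes$class,
                      levels = c("Up", "Down", "UnCh", "UnExp")))
  expect_lt(abs(cls[["Up"]] - 10), 4 * sqrt(50 * 0.2 * 0.8) + 1)
  expect_lt(abs(cls[["Down"]] - 20), 4 * sqrt(50 * 0.4 * 0.6) + 1)
})

test_that("infeasible element packing is an explicit error", {
  expect_error(generate_genome(sim_params(n_genes = 80, chrom_length = 3e5,
                                          hs_duration = 10,
                                          elongation_rate = 2000)),
               "infeasible packing")
})

test_that("HS expectation rewires only up to the elongation wave front", {
  p <- tiny_params()
  tr <- generate_genome(p)
  # force the long gene Down with consistent derived fields
  li <- which.max(tr$genes$length)
  expect_gt(tr$genes$length[li], 150000)
  tr$genes$class[li] <- "Down"
  tr$genes$body_rpk_hs[li] <- tr$genes$body_rpk_nhs[li] * p$fc_down
  tr$genes$pause_rpk_hs[li] <- tr$genes$pause_rpk_nhs[li] * p$hs_pause_gain
  tr$genes$pause_offset_hs[li] <- tr$genes$pause_offset_nhs[li] - p$hs_pause_shift

  nhs <- prowire:::expected_signal(tr, p, "NHS")
  hs <- prowire:::expected_signal(tr, p, "HS")
  g <- tr$genes[li, ]
  sense <- if (g$strand == "+") hs$plus else hs$minus
  sense_n <- if (g$strand == "+") nhs$plus else nhs$minus
  rel_idx <- function(a, b) {
    gg <- prowire:::rel_to_genomic(g$tss, g$strand, a, b)
    (gg[1] + 1):gg[2]
  }
  front <- p$elongation_rate * p$hs_duration
  # beyond +100 kb (wave front is 60 kb): identical expectation
  expect_equal(sense[rel_idx(100000, g$length - 500)],
               sense_n[rel_idx(100000, g$length - 500)])
  # inside the receding-wave zone: reduced by fc_down
  expect_equal(sense[rel_idx(1000, front)],
               sense_n[rel_idx(1000, front)] * p$fc_down)
  # UnCh genes: identical everywhere
  ui <- which(tr$genes$class == "UnCh")[1]
  if (!is.na(ui)) {
    gu <- tr$genes[ui, ]
    idx <- (gu$start + 1):gu$end
    expect_equal(hs$plus[idx], nhs$plus[idx])
    expect_equal(hs$minus[idx], nhs$minus[idx])
  }
})

test_that("realized counts match NB expectation (conservation within 4 SE)", {
  p <- tiny_params(seed = 9)
  tr <- generate_genome(p)
  lam <- prowire:::expected_signal(tr, p, "NHS")
  total_exp <- sum(lam$plus) + sum(lam$minus)
  total_var <- sum(lam$plus + p$nb_dispersion * lam$plus^2) +
    sum(lam$minus + p$nb_dispersion * lam$minus^2)
  totals <- vapply(1:20, function(r) {
    t1 <- simulate_tracks(tr, p, "NHS", r)
    sum(t1$plus$chrS) + sum(t1$minus$chrS)
  }, numeric(1))
  se <- sqrt(total_var / 20)
  expect_lt(abs(mean(totals) - total_exp), 4 * se)
})

test_that("zero dispersion gives Poisson-like counts", {
  p <- tiny_params(seed = 2, nb_dispersion = 0)
  tr <- generate_genome(p)
  g <- tr$genes[tr$genes$class != "UnExp", ][1, ]
  idx <- prowire:::rel_to_genomic(g$tss, g$strand, 600, 1100)
  counts <- vapply(1:80, function(r) {
    t1 <- simulate_tracks(tr, p, "NHS", r)
    v <- if (g$strand == "+") t1$plus$chrS else t1$minus$chrS
    sum(v[(idx[1] + 1):idx[2]])
  }, numeric(1))
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.5)
})

test_that("DNaseI track peaks between divergent summits with controllable noise", {
  p0 <- tiny_params(seed = 4, dnase_noise_sd = 0)
  tr <- generate_genome(p0)
  # make the first dTRE strand-symmetric
  tr$dtres$rpk_minus_nhs[1] <- tr$dtres$rpk_plus_nhs[1]
  pro <- simulate_tracks(tr, p0, "NHS", 1)
  dn <- simulate_dnase(tr, p0, pro)
  expect_identical(dn$track$plus$chrS, dn$expectation)  # sd = 0: no noise

  d <- tr$dtres[1, ]
  win <- (d$start - 200 + 1):(d$end + 200)
  apex <- win[which.max(dn$expectation[win])] - 1
  midpoint <- (d$summit_plus + d$summit_minus) / 2
  expect_lt(abs(apex - midpoint), 25 + p0$pause_width / 2)

  # untranscribed sites carry zero expectation
  u <- tr$untranscribed[1, ]
  expect_equal(sum(dn$expectation[(u$start + 1):u$end]), 0)

  # with noise, output differs from expectation but stays non-negative
  p1 <- tiny_params(seed = 4, dnase_noise_sd = 0.05)
  dn1 <- simulate_dnase(tr, p1, pro)
  expect_false(identical(dn1$track$plus$chrS, dn1$expectation))
  expect_true(all(dn1$track$plus$chrS >= 0))
})

test_that("simulated sequences carry class-dependent composition", {
  sim <- get_small_sim()
  p <- sim$params
  seqs <- sim$sequences
  gc_window <- function(center) {
    sub <- Biostrings::subseq(seqs[[1]], max(1, center - 499), center + 500)
    sum(Biostrings::letterFrequency(sub, c("G", "C"))) / 1000
  }
  cpg_window <- function(center) {
    sub <- Biostrings::subseq(seqs[[1]], max(1, center - 499), center + 500)
    Biostrings::countPattern("CG", sub) / 999
  }
  gc_prom <- vapply(sim$truth$genes$tss, gc_window, numeric(1))
  expect_gte(mean(gc_prom >= 0.55 & gc_prom <= 0.65), 0.95)
  cpg_prom <- vapply(sim$truth$genes$tss, cpg_window, numeric(1))
  cpg_dtre <- vapply(sim$truth$dtres$mid, cpg_window, numeric(1))
  expect_gt(mean(cpg_prom), mean(cpg_dtre))  # ordering follows parameters

  # degenerate GC = 1 gives an all-G/C element
  p1 <- tiny_params(seed = 8, gc_promoter = 1)
  tr1 <- generate_genome(p1)
  s1 <- simulate_sequences(tr1, p1)
  tss <- tr1$genes$tss[1]
  sub <- Biostrings::subseq(s1[[1]], tss - 400, tss + 400)
  expect_equal(sum(Biostrings::letterFrequency(sub, c("G", "C"))), 801)
})

test_that("factor peaks follow the category mix and jitter rules", {
  p <- tiny_params(seed = 6)
  tr <- generate_genome(p)
  # all-promoter mix: summits within -300..+50 of a TSS in the gene frame
  fp <- simulate_factor_peaks(tr, p, n = 30, mix = c(1, 0, 0))
  expect_true(all(fp$category == "promoter"))
  rel <- vapply(seq_len(nrow(fp)), function(i) {
    g <- tr$genes[tr$genes$gene_id == fp$element_id[i], ]
    if (g$strand == "+") fp$summit[i] - g$tss else g$tss - fp$summit[i]
  }, numeric(1))
  expect_true(all(rel >= -300 & rel <= 50))

  # jitter = 0 pins dTRE summits to the element midpoint
  fp2 <- simulate_factor_peaks(tr, p, n = 20, mix = c(0, 1, 0), jitter = 0)
  mids <- tr$dtres$mid[match(fp2$element_id, tr$dtres$dtre_id)]
  expect_equal(fp2$summit, mids)

  # seeded draw is reproducible
  fp3 <- simulate_factor_peaks(tr, p, n = 25, mix = c(0.31, 0.29, 0.40))
  fp4 <- simulate_factor_peaks(tr, p, n = 25, mix = c(0.31, 0.29, 0.40))
  expect_identical(fp3, fp4)
})

test_that("written simulations are byte-identical across runs", {
  p <- tiny_params(seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_experiment(p, n_reps = 1, dnase = FALSE,
                                       sequences = FALSE), d1)
  write_simulation(simulate_experiment(p, n_reps = 1, dnase = FALSE,
                                       sequences = FALSE), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})
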