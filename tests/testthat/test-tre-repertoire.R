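# dedicated classifier fixture: balanced promoters / dTREs
get_classifier_sim <- function() {
  if (is.null(.fixtures$clf_sim)) {
    p <- sim_params(n_genes = 60, n_dtres = 60, n_untranscribed_sites = 10,
                    chrom_length = 3e6, seed = 19)
    .fixtures$clf_sim <- simulate_experiment(p, n_reps = 1, dnase = FALSE,
                                             factor_peaks = FALSE)
  }
  .fixtures$clf_sim
}

classifier_sites <- function(sim) {
  g <- sim$truth$genes[sim$truth$genes$class != "UnExp", ]
  tibble::tibble(
    chrom = "chrS",
    center = c(g$tss, sim$truth$dtres$mid),
    label = c(rep("promoter", nrow(g)), rep("dTRE", nrow(sim$truth$dtres))))
}

test_that("sequence composition features count GC and CpG exactly", {
  seqs <- Biostrings::DNAStringSet(c(chrQ = "AAAAAAAAAA"))
  expect_equal(cpg_gc_features(seqs, "chrQ", 5, 10), c(gc = 0, cpg = 0))
  seqs2 <- Biostrings::DNAStringSet(c(chrQ = "CGCGCG"))
  expect_equal(cpg_gc_features(seqs2, "chrQ", 3, 6), c(gc = 1, cpg = 3 / 5))
  # brute-force oracle on a random sequence
  withr::with_seed(9, {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  })
  seqs3 <- Biostrings::DNAStringSet(setNames(s, "chrQ"))
  got <- cpg_gc_features(seqs3, "chrQ", 200, 100)
  chars <- strsplit(substr(s, 151, 250), "")[[1]]
  expect_equal(got[["gc"]], mean(chars %in% c("G", "C")))
  expect_equal(got[["cpg"]],
               sum(chars[-100] == "C" & chars[-1] == "G") / 99)
})

test_that("the classifier separates synthetic promoters from dTREs", {
  sim <- get_classifier_sim()
  sites <- classifier_sites(sim)
  model <- train_tre_classifier(sites, sim$tracks$NHS[[1]], sim$sequences,
                                seed = 7)
  expect_gte(model$auc_combined, 0.9)
  expect_gte(model$auc_combined,
             max(model$auc_proseq, model$auc_cpg_gc) - 0.02)
  g <- glance(model)
  expect_true(all(c("auc_combined", "window_size") %in% names(g)))
  .fixtures$clf_model <- model

  expect_error(train_tre_classifier(sites[sites$label == "dTRE", ],
                                    sim$tracks$NHS[[1]], sim$sequences),
               "both classes")
})

test_that("permuted labels give chance-level AUC", {
  sim <- get_classifier_sim()
  sites <- classifier_sites(sim)
  withr::with_seed(3, sites$label <- sample(sites$label))
  null_model <- train_tre_classifier(sites, sim$tracks$NHS[[1]],
                                     sim$sequences,
                                     n_windows_grid = 10,
                                     window_size_grid = 50,
                                     seq_window_grid = 500,
                                     gamma_mult = 1, cost_grid = 1, seed = 7)
  expect_lt(abs(null_model$auc_combined - 0.5), 0.1)
})

test_that("classification thresholds at margin zero and excludes TSS overlaps", {
  sim <- get_classifier_sim()
  sites <- classifier_sites(sim)
  model <- .fixtures$clf_model
  if (is.null(model)) {
    model <- train_tre_classifier(sites, sim$tracks$NHS[[1]], sim$sequences,
                                  seed = 7)
  }
  d <- sim$truth$dtres[1:10, ]
  tres <- tibble::tibble(chrom = "chrS", start = d$start, end = d$end,
                         center = d$mid)
  out <- classify_tres(model, tres, sim$tracks$NHS[[1]], sim$sequences,
                       filter_genes(sim$truth$genes))
  expect_true(all(out$class[out$score > 0] == "promoter"))
  expect_true(all(out$class[out$score <= 0] %in% c("dTRE", "excluded_tss")))

  # drop a fake annotated TSS inside a dTRE-classified element
  dcls <- which(out$class == "dTRE")[1]
  skip_if(is.na(dcls), "no dTRE-classified element in fixture")
  fake <- filter_genes(sim$truth$genes)
  fake$tss[1] <- out$start[dcls] + 5
  fake$chrom[1] <- "chrS"
  out2 <- classify_tres(model, tres, sim$tracks$NHS[[1]], sim$sequences, fake)
  expect_equal(out2$class[dcls], "excluded_tss")
  # promoter-classified elements are never relabeled
  expect_equal(out2$class[out2$score > 0], out$class[out$score > 0])

  # deterministic given the model
  out3 <- classify_tres(model, tres, sim$tracks$NHS[[1]], sim$sequences,
                        filter_genes(sim$truth$genes))
  expect_identical(out3$score, out$score)
})

test_that("dTRE quantification scores strands independently with 5' tie-breaks", {
  n <- 3000
  plus <- numeric(n); minus <- numeric(n)
  plus[1400 + 1] <- 1   # single plus-strand count
  minus[1200 + 1] <- 1  # single minus-strand count
  tr <- vec_track(plus, minus)
  d <- tibble::tibble(dtre_id = "d1", chrom = "chrT", start = 1000L, end = 1600L)
  q <- quantify_dtres(tr, d)
  expect_equal(q$rpk_plus, 1000 / 600)
  expect_equal(q$rpk_minus, 1000 / 600)
  # plus strand: most-upstream covering window starts at 1351 -> summit 1376
  expect_equal(q$summit_plus, 1376)
  # minus strand: 5' = rightmost; covering window [1200,1250) -> summit 1225
  expect_equal(q$summit_minus, 1225)
  expect_equal(q$intersummit_dist, 151)

  # zero minus strand: tie-break takes the most 5' minus window (3' edge)
  tr0 <- vec_track(plus, numeric(n))
  q0 <- quantify_dtres(tr0, d)
  expect_equal(q0$rpk_minus, 0)
  expect_equal(q0$summit_minus, 1600 - 50 + 25)

  # strand mirror symmetry: flipping the track and element swaps the strands
  trm <- vec_track(rev(minus), rev(plus))
  dm <- tibble::tibble(dtre_id = "d1", chrom = "chrT",
                       start = n - 1600L, end = n - 1000L)
  qm <- quantify_dtres(trm, dm)
  expect_equal(qm$rpk_plus, q$rpk_minus)
  expect_equal(qm$rpk_minus, q$rpk_plus)
  expect_equal(qm$intersummit_dist, q$intersummit_dist)
})

test_that("dTRE quantification equals brute force on simulated elements", {
  sim <- get_small_sim()
  tr <- sim$tracks$NHS[[1]]
  d <- sim$truth$dtres[1:6, ]
  q <- quantify_dtres(tr, dplyr::rename(d, dtre_id = dtre_id))
  for (i in seq_len(nrow(d))) {
    len <- d$end[i] - d$start[i]
    pv <- tr$plus$chrS[(d$start[i] + 1):d$end[i]]
    mv <- tr$minus$chrS[(d$start[i] + 1):d$end[i]]
    expect_equal(q$rpk_plus[i], 1000 * sum(pv) / len)
    expect_equal(q$rpk_minus[i], 1000 * sum(mv) / len)
    bf <- bf_max_window(tr, "chrS", d$start[i], "+", 0, len, 50, "sense")
    expect_equal(q$summit_plus[i], d$start[i] + bf$offset + 25)
  }
})

test_that("repertoire comparison honors the 50% boundary and partitions", {
  a <- tibble::tibble(id = "a1", chrom = "c", start = 100L, end = 300L)
  b1 <- tibble::tibble(id = "b1", chrom = "c", start = 200L, end = 400L)
  b2 <- tibble::tibble(id = "b2", chrom = "c", start = 201L, end = 400L)
  expect_equal(nrow(compare_repertoires(a, b1)$shared), 1)  # 100 = 0.5 x 200
  expect_equal(nrow(compare_repertoires(a, b2)$shared), 0)  # 99 < 100

  # reciprocal flag also requires the fraction of b
  a2 <- tibble::tibble(id = "a2", chrom = "c", start = 100L, end = 200L)
  b3 <- tibble::tibble(id = "b3", chrom = "c", start = 100L, end = 500L)
  expect_equal(nrow(compare_repertoires(a2, b3)$shared), 1)
  expect_equal(nrow(compare_repertoires(a2, b3, reciprocal = TRUE)$shared), 0)

  dis_a <- tibble::tibble(id = c("x", "y"), chrom = "c",
                          start = c(0L, 1000L), end = c(100L, 1100L))
  dis_b <- tibble::tibble(id = "z", chrom = "c", start = 5000L, end = 5100L)
  cmp <- compare_repertoires(dis_a, dis_b)
  expect_equal(tidy(cmp)$n, c(0, 2, 1))

  # partition + greedy maximality on random interval sets
  withr::with_seed(14, {
    mk <- function(n, pre) {
      s <- sort(sample(0:20000, n))
      tibble::tibble(id = paste0(pre, seq_len(n)), chrom = "c",
                     start = s, end = s + sample(100:400, n, replace = TRUE))
    }
    A <- mk(40, "a"); B <- mk(40, "b")
  })
  cmp2 <- compare_repertoires(A, B)
  expect_equal(nrow(cmp2$shared) + nrow(cmp2$a_only), nrow(A))
  expect_equal(nrow(cmp2$shared) + nrow(cmp2$b_only), nrow(B))
  # no unmatched qualifying pair remains (greedy maximality)
  for (i in seq_len(nrow(cmp2$a_only))) {
    ai <- cmp2$a_only[i, ]
    for (j in seq_len(nrow(cmp2$b_only))) {
      bj <- cmp2$b_only[j, ]
      ov <- max(0, min(ai$end, bj$end) - max(ai$start, bj$start))
      expect_lt(ov, 0.5 * (ai$end - ai$start))
    }
  }
})
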