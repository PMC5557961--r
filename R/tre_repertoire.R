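#' Sequence composition features for TRE classification
#'
#' GC fraction and CpG dinucleotide rate of a single window centered on a
#' site: `GC = (G+C)/length`, `CpG rate = #CG dinucleotides / (length - 1)`.
#'
#' @param seqs A [Biostrings::DNAStringSet] keyed by chromosome.
#' @param chrom,center Site (0-based base).
#' @param window Window width, bp.
#' @return Named numeric vector `c(gc, cpg)`.
#' @export
cpg_gc_features <- function(seqs, chrom, center, window = 500) {
  s <- seqs[[chrom]]
  a <- max(1, center - window %/% 2 + 1)
  b <- min(length(s), a + window - 1)
  sub <- Biostrings::subseq(s, a, b)
  len <- b - a + 1
  gc <- sum(Biostrings::letterFrequency(sub, c("G", "C"))) / len
  cpg <- Biostrings::countPattern("CG", sub) / (len - 1)
  c(gc = unname(gc), cpg = unname(cpg))
}

cpg_gc_matrix <- function(seqs, chrom, centers, window) {
  t(vapply(centers, function(p) cpg_gc_features(seqs, chrom, p, window),
           numeric(2)))
}

cv_auc <- function(features, labels, folds = 5, gamma = NULL, cost = 1,
                   seed = 1L, return_scores = FALSE) {
  # labels: factor with levels c("dTRE", "promoter"); score > 0 => promoter
  withr::with_seed(seed, {
    n <- length(labels)
    fold <- sample(rep_len(seq_len(folds), n))
    scores <- numeric(n)
    for (k in seq_len(folds)) {
      tr <- fold != k
      if (length(unique(labels[tr])) < 2) next
      fit <- e1071::svm(features[tr, , drop = FALSE], labels[tr],
                        type = "C-classification", kernel = "radial",
                        gamma = gamma %||% (1 / ncol(features)), cost = cost,
                        scale = FALSE)
      dv <- attr(predict(fit, features[!tr, , drop = FALSE],
                         decision.values = TRUE), "decision.values")
      sign_flip <- if (grepl("^promoter", colnames(dv)[1])) 1 else -1
      scores[!tr] <- sign_flip * dv[, 1]
    }
    auc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          levels = c("dTRE", "promoter"),
                                          direction = "<")))
    if (return_scores) list(auc = auc, scores = scores) else auc
  })
}

#' Train the promoter vs dTRE SVM classifier
#'
#' Two independent component classifiers are tuned first: (1) the PRO-seq
#' shape classifier — per-strand log1p counts in non-overlapping windows
#' centered on the site; with the window size fixed at 50 bp the number of
#' windows is chosen by 5-fold CV AUC, then the window size is re-tuned at
#' the chosen genomic span; (2) the CpG/GC classifier — GC fraction and CpG
#' rate in a single window whose width is tuned the same way. The final
#' model concatenates both feature sets and selects the Gaussian-kernel
#' gamma and cost C by internal 10-fold cross-validated AUC. Held-out AUCs
#' (cross-validated) are reported for each component and the combination.
#'
#' @param sites Tibble `chrom, center, label` with `label` in
#'   `{"promoter", "dTRE"}`.
#' @param track Stranded PRO-seq [signal_track()].
#' @param seqs [Biostrings::DNAStringSet] genome.
#' @param n_windows_grid,window_size_grid,seq_window_grid Tuning grids.
#' @param gamma_mult,cost_grid Final SVM grids (`gamma = gamma_mult / d`).
#' @param seed Seed controlling all CV splits.
#' @return A `tre_classifier`; see [tidy.tre_classifier()].
#' @export
train_tre_classifier <- function(sites, track, seqs,
                                 n_windows_grid = c(5, 10, 15),
                                 window_size_grid = c(20, 50, 100),
                                 seq_window_grid = c(200, 500, 1000),
                                 gamma_mult = c(0.25, 1, 4),
                                 cost_grid = c(0.3, 1, 10),
                                 seed = 1L) {
  labels <- factor(sites$label, levels = c("dTRE", "promoter"))
  if (nlevels(droplevels(labels)) < 2) abort("both classes required for training")
  chrom <- sites$chrom[1]

  # stage 1: number of 50-bp windows
  aucs1 <- map_dbl(n_windows_grid, function(nw) {
    f <- feature_matrix(track, chrom, sites$center, 50, nw)
    cv_auc(f, labels, folds = 5, seed = seed)
  })
  nw50 <- n_windows_grid[which.max(aucs1)]
  span <- 50 * (2 * nw50 + 1)
  # stage 2: window size at fixed span
  aucs2 <- map_dbl(window_size_grid, function(ws) {
    nw <- max(1, round((span / ws - 1) / 2))
    f <- feature_matrix(track, chrom, sites$center, ws, nw)
    cv_auc(f, labels, folds = 5, seed = seed)
  })
  ws <- window_size_grid[which.max(aucs2)]
  nw <- max(1, round((span / ws - 1) / 2))
  proseq_feat <- feature_matrix(track, chrom, sites$center, ws, nw)
  proseq_auc <- max(aucs2)

  # CpG/GC window
  aucs3 <- map_dbl(seq_window_grid, function(w) {
    f <- cpg_gc_matrix(seqs, chrom, sites$center, w)
    cv_auc(f, labels, folds = 5, seed = seed)
  })
  seq_w <- seq_window_grid[which.max(aucs3)]
  seq_feat <- cpg_gc_matrix(seqs, chrom, sites$center, seq_w)
  seq_auc <- max(aucs3)

  # combined model: 10-fold CV over (gamma, C)
  comb <- cbind(proseq_feat, seq_feat)
  grid <- tidyr::expand_grid(gamma = gamma_mult / ncol(comb), cost = cost_grid)
  cvres <- map(seq_len(nrow(grid)), function(i)
    cv_auc(comb, labels, folds = 10, gamma = grid$gamma[i],
           cost = grid$cost[i], seed = seed, return_scores = TRUE))
  grid$auc <- map_dbl(cvres, "auc")
  best_i <- which.max(grid$auc)
  fit <- e1071::svm(comb, labels, type = "C-classification", kernel = "radial",
                    gamma = grid$gamma[best_i], cost = grid$cost[best_i],
                    scale = FALSE)
  structure(list(
    fit = fit, window_size = ws, n_windows = nw, seq_window = seq_w,
    gamma = grid$gamma[best_i], cost = grid$cost[best_i],
    auc_proseq = proseq_auc, auc_cpg_gc = seq_auc,
    auc_combined = grid$auc[best_i],
    cv_scores = tibble(label = labels, score = cvres[[best_i]]$scores),
    tuning = list(n_windows = tibble(n_windows = n_windows_grid, auc = aucs1),
                  window_size = tibble(window_size = window_size_grid, auc = aucs2),
                  seq_window = tibble(seq_window = seq_window_grid, auc = aucs3),
                  svm = grid)
  ), class = "tre_classifier")
}

#' @export
print.tre_classifier <- function(x, ...) {
  cat(sprintf(paste0("<tre_classifier> %d bp x %d windows + CpG/GC %d bp; ",
                     "AUC combined %.3f (PRO-seq %.3f, CpG/GC %.3f)\n"),
              x$window_size, x$n_windows, x$seq_window,
              x$auc_combined, x$auc_proseq, x$auc_cpg_gc))
  invisible(x)
}

#' @rdname train_tre_classifier
#' @param x A `tre_classifier`.
#' @param ... Unused.
#' @export
glance.tre_classifier <- function(x, ...) {
  tibble(window_size = x$window_size, n_windows = x$n_windows,
         seq_window = x$seq_window, gamma = x$gamma, cost = x$cost,
         auc_proseq = x$auc_proseq, auc_cpg_gc = x$auc_cpg_gc,
         auc_combined = x$auc_combined)
}

#' @rdname train_tre_classifier
#' @export
tidy.tre_classifier <- function(x, ...) x$cv_scores

tre_score <- function(model, track, seqs, chrom, centers) {
  f <- cbind(
    feature_matrix(track, chrom, centers, model$window_size, model$n_windows),
    cpg_gc_matrix(seqs, chrom, centers, model$seq_window))
  dv <- attr(predict(model$fit, f, decision.values = TRUE), "decision.values")
  sign_flip <- if (grepl("^promoter", colnames(dv)[1])) 1 else -1
  as.numeric(sign_flip * dv[, 1])
}

#' Classify refined TREs into promoters and dTREs
#'
#' Scores each element with the trained SVM (positive margin = promoter; the
#' decision threshold sits at the margin 0) and then relabels any
#' dTRE-classified element that overlaps an annotated TSS (within 1 bp) as
#' `excluded_tss`: such regions are not considered distal regulatory
#' elements.
#'
#' @param model A [train_tre_classifier()] model.
#' @param tres Tibble `chrom, start, end, center` of refined elements.
#' @param track,seqs Data matching the training inputs.
#' @param genes Annotation ([filter_genes()]) supplying TSS positions.
#' @return `tres` with `score` and `class` columns
#'   (`promoter` / `dTRE` / `excluded_tss`).
#' @export
classify_tres <- function(model, tres, track, seqs, genes) {
  score <- tre_score(model, track, seqs, tres$chrom[1], tres$center)
  cls <- if_else(score > 0, "promoter", "dTRE")
  tss <- genes$tss[genes$chrom == tres$chrom[1]]
  on_tss <- map_lgl(seq_len(nrow(tres)), function(i)
    any(tss >= tres$start[i] - 1 & tss <= tres$end[i]))
  tres %>% mutate(score = score,
                  class = if_else(cls == "dTRE" & on_tss, "excluded_tss", cls))
}

#' Strand-specific quantification of a dTRE
#'
#' Over the full element length, per strand: the mean density (RPK) and the
#' maximal 50-nt window (1-bp scan; ties resolved toward the 5' end in that
#' strand's own orientation). The summit is the window midpoint; the
#' inter-summit distance separates the plus- and minus-strand summits.
#'
#' @param track Stranded [signal_track()].
#' @param dtres Tibble `dtre_id, chrom, start, end`.
#' @param condition Label stored in the result.
#' @param window Scored window width, bp.
#' @return Tibble with per-strand `rpk`, `summit`, and `intersummit_dist`.
#' @export
quantify_dtres <- function(track, dtres, condition = NA_character_,
                           window = 50) {
  rows <- map(seq_len(nrow(dtres)), function(i) {
    d <- dtres[i, ]
    len <- d$end - d$start
    wp <- max_window(track, d$chrom, d$start, "+", 0, len, window,
                     strand_mode = "sense")
    wm <- max_window(track, d$chrom, d$end - 1, "-", 0, len, window,
                     strand_mode = "sense")
    sp <- wp$start + window / 2
    sm <- wm$start + window / 2
    tibble(dtre_id = d$dtre_id, chrom = d$chrom,
           start = d$start, end = d$end,
           rpk_plus = region_rpk(track, d$chrom, d$start, d$end, "+", "sense"),
           rpk_minus = region_rpk(track, d$chrom, d$start, d$end, "-", "sense"),
           summit_plus = sp, summit_minus = sm,
           intersummit_dist = abs(sp - sm))
  })
  bind_rows(rows) %>% mutate(condition = condition)
}

interval_overlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Compare dTRE repertoires between two conditions
#'
#' Elements from the two sets are "shared" when they overlap by at least
#' `min_frac` of the first element's length (`reciprocal = TRUE` additionally
#' requires the fraction of the second). Matching is greedy on decreasing
#' overlap and one-to-one, so the three output sets partition the union.
#'
#' @param a,b Tibbles `id, chrom, start, end` for the two conditions.
#' @param min_frac Overlap fraction criterion (default 0.5, inclusive).
#' @param reciprocal Require the fraction on both elements.
#' @return A `repertoire_comparison`: `shared` (pairs), `a_only`, `b_only`,
#'   and the criterion record; see [tidy.repertoire_comparison()].
#' @export
compare_repertoires <- function(a, b, min_frac = 0.5, reciprocal = FALSE) {
  pairs <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b))) %>%
    mutate(ov = interval_overlap(a$start[.data$i], a$end[.data$i],
                                 b$start[.data$j], b$end[.data$j]),
           same_chrom = a$chrom[.data$i] == b$chrom[.data$j],
           ok = .data$same_chrom &
             .data$ov >= min_frac * (a$end[.data$i] - a$start[.data$i]) &
             (!reciprocal |
                .data$ov >= min_frac * (b$end[.data$j] - b$start[.data$j]))) %>%
    filter(.data$ok) %>%
    arrange(dplyr::desc(.data$ov), .data$i, .data$j)
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  shared <- pairs[keep, ] %>%
    mutate(a_id = a$id[.data$i], b_id = b$id[.data$j]) %>%
    select("a_id", "b_id", overlap = "ov")
  structure(list(shared = shared,
                 a_only = a[!used_a, ], b_only = b[!used_b, ],
                 criterion = list(min_frac = min_frac, reciprocal = reciprocal)),
            class = "repertoire_comparison")
}

#' @export
print.repertoire_comparison <- function(x, ...) {
  cat(sprintf("<repertoire_comparison> %d shared, %d A-only, %d B-only (>=%.0f%% overlap%s)\n",
              nrow(x$shared), nrow(x$a_only), nrow(x$b_only),
              100 * x$criterion$min_frac,
              if (x$criterion$reciprocal) ", reciprocal" else ""))
  invisible(x)
}

#' @rdname compare_repertoires
#' @param x A `repertoire_comparison`.
#' @param ... Unused.
#' @export
tidy.repertoire_comparison <- function(x, ...) {
  tibble(set = c("shared", "a_only", "b_only"),
         n = c(nrow(x$shared), nrow(x$a_only), nrow(x$b_only)))
}
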