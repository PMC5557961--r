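#' Negative-binomial Wald test on replicate counts
#'
#' Tests each feature for a count change between two conditions under a
#' negative-binomial model. Raw counts are scaled by per-sample size factors
#' (from [fit_scale_factors()]); the per-feature dispersion is estimated by
#' method of moments across replicates and, because a handful of replicates
#' gives a very noisy moment estimate, moderated toward the across-feature
#' common dispersion with `prior_df` pseudo-degrees of freedom
#' (empirical-Bayes style). The Wald statistic compares log mean scaled
#' counts (0.5-count pseudocount) with a delta-method standard error.
#'
#' @param counts_a,counts_b Integer matrices, features x replicates, for the
#'   two conditions (a = reference/NHS, b = HS). Vectors are treated as
#'   single-feature matrices.
#' @param size_factors_a,size_factors_b Multiplicative per-replicate factors
#'   that bring counts onto a common scale (default 1).
#' @param prior_df Weight of the common dispersion in the moderated estimate.
#' @param dispersion_floor Lower bound on the dispersion used in the test.
#' @return Tibble: `feature`, `base_mean`, `log2fc` (b over a), `p_value`,
#'   `dispersion`, `all_zero`.
#' @export
nb_test <- function(counts_a, counts_b,
                    size_factors_a = NULL, size_factors_b = NULL,
                    prior_df = 10, dispersion_floor = 1e-8) {
  counts_a <- rbind(counts_a); counts_b <- rbind(counts_b)
  if (nrow(counts_a) != nrow(counts_b)) abort("feature counts differ between conditions")
  if (ncol(counts_a) < 2 || ncol(counts_b) < 2) {
    abort("nb_test needs at least 2 replicates per condition")
  }
  sfa <- size_factors_a %||% rep(1, ncol(counts_a))
  sfb <- size_factors_b %||% rep(1, ncol(counts_b))
  ya <- sweep(counts_a, 2, sfa, `*`)
  yb <- sweep(counts_b, 2, sfb, `*`)
  na <- ncol(ya); nb <- ncol(yb)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  va <- apply(ya, 1, var); vb <- apply(yb, 1, var)
  # per-condition moment dispersions, pooled by residual df
  alpha_of <- function(v, m) if_else(m > 0, (v - m) / m^2, NA_real_)
  aa <- alpha_of(va, ma); ab <- alpha_of(vb, mb)
  wa <- (na - 1) * as.numeric(!is.na(aa))
  wb <- (nb - 1) * as.numeric(!is.na(ab))
  num <- if_else(is.na(aa), 0, aa) * wa + if_else(is.na(ab), 0, ab) * wb
  a_raw <- num / (wa + wb)
  a_raw[is.nan(a_raw)] <- NA_real_
  # mean, not median: the moment estimator is right-skewed at few replicates
  # and the median would systematically understate the common dispersion
  common <- mean(pmax(a_raw, 0), na.rm = TRUE)
  if (!is.finite(common)) common <- 0
  df <- (na - 1) + (nb - 1)
  a_mod <- (prior_df * common + df * pmax(a_raw, 0)) / (prior_df + df)
  a_mod[is.na(a_mod)] <- common
  alpha <- pmax(a_mod, dispersion_floor)

  mu_a <- ma + 0.5; mu_b <- mb + 0.5
  log2fc <- log2(mu_b / mu_a)
  se2 <- (ma + alpha * ma^2) / na / mu_a^2 + (mb + alpha * mb^2) / nb / mu_b^2
  w <- (log(mu_b) - log(mu_a)) / sqrt(se2)
  p <- 2 * pnorm(-abs(w))
  all_zero <- ma == 0 & mb == 0
  log2fc[all_zero] <- 0
  p[all_zero] <- 1
  feat <- rownames(counts_a) %||% as.character(seq_len(nrow(counts_a)))
  tibble(feature = feat, base_mean = (ma * na + mb * nb) / (na + nb),
         log2fc = as.numeric(log2fc), p_value = as.numeric(p),
         dispersion = as.numeric(alpha), all_zero = all_zero)
}

#' Count reads in gene bodies per replicate
#'
#' Builds the raw-count matrix the differential test consumes: sense-strand
#' counts over each gene's body region (+500 from TSS to −500 from polyA).
#' Genes shorter than 1000 bp get zero-length bodies and zero counts.
#'
#' @param tracks List of raw [signal_track()]s (one per replicate).
#' @param genes Output of [filter_genes()].
#' @return Integer matrix, genes x replicates, rownames = gene ids.
#' @export
gene_body_counts <- function(tracks, genes) {
  m <- vapply(tracks, function(tr) {
    map_dbl(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      if (g$length <= 1000) return(0)
      sum(rel_values(tr, g$chrom, g$tss, g$strand, 500, g$length - 500, "sense"))
    })
  }, numeric(nrow(genes)))
  rownames(m) <- genes$gene_id
  m
}

#' Strand-specific counts over dTRE elements per replicate
#'
#' @param tracks List of raw [signal_track()]s.
#' @param dtres Tibble with `dtre_id, chrom, start, end`.
#' @return List of two matrices (`plus`, `minus`), elements x replicates.
#' @export
dtre_counts <- function(tracks, dtres) {
  one <- function(strand) {
    m <- vapply(tracks, function(tr) {
      map_dbl(seq_len(nrow(dtres)), function(i) {
        d <- dtres[i, ]
        sum(strand_vec(tr, d$chrom, strand)[(d$start + 1):d$end])
      })
    }, numeric(nrow(dtres)))
    rownames(m) <- dtres$dtre_id
    m
  }
  list(plus = one("+"), minus = one("-"))
}

dreg_score_at_tss <- function(genes, candidates, tss_window = 200) {
  map_dbl(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    hit <- candidates$chrom == g$chrom &
      candidates$start < g$tss + tss_window &
      candidates$end > g$tss - tss_window
    if (any(hit)) max(candidates$score[hit]) else NA_real_
  })
}

#' Assign stress-response classes to genes
#'
#' Classes follow fixed raw-p cutoffs: Up requires `p <= p_max`, fold-change
#' magnitude `>= min_fc`, positive log2FC, and a detector-identified TRE with
#' score `>= min_dreg_score` within `tss_window` bp of the TSS; Down is
#' symmetric. Genes flagged UnExp keep that class; genes with no qualifying
#' TRE at the TSS become Filtered (their change cannot be attributed to the
#' gene's own promoter); everything else is UnCh. The classes partition the
#' gene set. A Benjamini-Hochberg column is emitted for reference but plays
#' no role in class assignment.
#'
#' @param diff [nb_test()] result for gene-body counts (`feature` = gene id).
#' @param genes Output of [filter_genes()].
#' @param unexp [flag_unexpressed()] result.
#' @param candidates Tibble of broad TRE calls: `chrom, start, end, score`.
#' @param p_max,min_fc,min_dreg_score,tss_window Thresholds (defaults 0.001,
#'   1.25, 0.7, 200).
#' @return `diff` with `dreg_score_at_tss`, `padj` and `class` columns.
#' @export
classify_genes <- function(diff, genes, unexp, candidates,
                           p_max = 0.001, min_fc = 1.25,
                           min_dreg_score = 0.7, tss_window = 200) {
  miss <- setdiff(diff$feature, genes$gene_id)
  if (length(miss)) abort(paste0("tested gene(s) missing from annotation: ", miss[1]))
  genes <- genes[match(diff$feature, genes$gene_id), ]
  miss_q <- setdiff(diff$feature, unexp$gene_id)
  if (length(miss_q)) abort(paste0("no quantification for tested gene: ", miss_q[1]))
  ds <- dreg_score_at_tss(genes, candidates, tss_window)
  lfc_min <- log2(min_fc)
  diff %>%
    mutate(
      dreg_score_at_tss = ds,
      padj = stats::p.adjust(.data$p_value, "BH"),
      unexp = unexp$unexp[match(.data$feature, unexp$gene_id)],
      has_tre = !is.na(ds) & ds >= min_dreg_score,
      class = case_when(
        unexp ~ "UnExp",
        !has_tre ~ "Filtered",
        .data$p_value <= p_max & .data$log2fc >= lfc_min ~ "Up",
        .data$p_value <= p_max & .data$log2fc <= -lfc_min ~ "Down",
        TRUE ~ "UnCh")) %>%
    select(-"unexp", -"has_tre")
}

#' Classify dTREs from strand-specific tests
#'
#' A dTRE is up- or downregulated when either strand changes significantly
#' (`p <= p_max`, fold-change magnitude `>= min_fc`) in that direction; when
#' the two strands change significantly in opposite directions the element is
#' reported as `discordant` and excluded from the up/down sets; otherwise it
#' is `unchanged`.
#'
#' @param diff_plus,diff_minus [nb_test()] results for the two strands
#'   (same feature order).
#' @param p_max,min_fc Thresholds (defaults 0.05, 1.25).
#' @return Tibble: `feature`, per-strand `log2fc`/`p`, `class`.
#' @export
classify_dtres <- function(diff_plus, diff_minus, p_max = 0.05, min_fc = 1.25) {
  stopifnot(identical(diff_plus$feature, diff_minus$feature))
  lfc <- log2(min_fc)
  sig_up <- function(d) d$p_value <= p_max & d$log2fc >= lfc
  sig_dn <- function(d) d$p_value <= p_max & d$log2fc <= -lfc
  up <- sig_up(diff_plus) | sig_up(diff_minus)
  dn <- sig_dn(diff_plus) | sig_dn(diff_minus)
  tibble(feature = diff_plus$feature,
         log2fc_plus = diff_plus$log2fc, p_plus = diff_plus$p_value,
         log2fc_minus = diff_minus$log2fc, p_minus = diff_minus$p_value,
         class = case_when(up & dn ~ "discordant", up ~ "up", dn ~ "down",
                           TRUE ~ "unchanged"))
}

#' Assign descriptive gene groups
#'
#' Overlapping groups used for profile analyses: `highly_up` (Up, log2FC > 2
#' and RPK gain > 200), `moderately_up` (Up but not highly up),
#' `highly_transcribed` (baseline body RPK > 500) and `all_transcribed`
#' (anything not UnExp).
#'
#' @param calls [classify_genes()] result.
#' @param quants Row-bound [quantify_genes()] across the two conditions, with
#'   a `condition` column matching `nhs`/`hs`.
#' @param nhs,hs Condition labels in `quants`.
#' @return Tibble of logical group columns keyed by `gene_id`.
#' @export
assign_gene_groups <- function(calls, quants, nhs = "NHS", hs = "HS") {
  wide <- quants %>%
    filter(.data$condition %in% c(nhs, hs)) %>%
    select("gene_id", "condition", "body_rpk") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "body_rpk")
  x <- calls %>%
    left_join(wide, by = c(feature = "gene_id")) %>%
    mutate(delta_rpk = .data[[hs]] - .data[[nhs]])
  tibble(gene_id = x$feature,
         highly_up = x$class == "Up" & x$log2fc > 2 &
           !is.na(x$delta_rpk) & x$delta_rpk > 200,
         moderately_up = x$class == "Up" & !(x$class == "Up" & x$log2fc > 2 &
           !is.na(x$delta_rpk) & x$delta_rpk > 200),
         highly_transcribed = !is.na(x[[nhs]]) & x[[nhs]] > 500,
         all_transcribed = x$class != "UnExp")
}
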