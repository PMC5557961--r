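#' Composite (meta) profile with bootstrap interval
#'
#' Averages binned signal over a set of anchors in their 5'→3' frames and
#' attaches a per-bin bootstrap band: anchors are resampled with replacement
#' `n_boot` times and the 12.5th-87.5th percentiles of the resampled means
#' form a nominal 75% interval for each bin.
#'
#' @param track A [signal_track()].
#' @param anchors Tibble `chrom, pos, strand` (strand may be `"."`).
#' @param bin_size Bin width, bp (default 20).
#' @param flank Profile half-width, bp (multiple of `bin_size`).
#' @param strand_mode `"sense"`, `"antisense"`, `"both"`, `"unstranded"`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Percentile band (default `c(12.5, 87.5)`).
#' @param seed Seed for the bootstrap.
#' @return A `composite_profile`: tibble of `bin_start` (relative bp),
#'   `mean`, `lo`, `hi`, plus metadata; see [autoplot.composite_profile()].
#' @export
composite_profile <- function(track, anchors, bin_size = 20, flank = 1000,
                              strand_mode = "sense", n_boot = 1000,
                              conf = c(12.5, 87.5), seed = 1L) {
  if (nrow(anchors) == 0) abort("empty anchor set")
  if (flank %% bin_size != 0) abort("flank must be a multiple of bin_size")
  nb <- flank %/% bin_size
  m <- t(vapply(seq_len(nrow(anchors)), function(i)
    query_bins(track, anchors$chrom[i], anchors$pos[i],
               anchors$strand[i] %||% "+", bin_size, nb, strand_mode),
    numeric(2 * nb)))
  mu <- colMeans(m)
  n <- nrow(m)
  withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    W <- matrix(0, n_boot, n)
    for (r in seq_len(n_boot)) {
      tab <- tabulate(idx[r, ], nbins = n)
      W[r, ] <- tab
    }
    boot_means <- (W %*% m) / n
    qs <- apply(boot_means, 2, quantile, probs = conf / 100, names = FALSE)
  })
  structure(list(
    profile = tibble(bin_start = seq(-flank, flank - bin_size, by = bin_size),
                     mean = mu, lo = qs[1, ], hi = qs[2, ]),
    bin_size = bin_size, n_anchors = n, strand_mode = strand_mode,
    conf = conf, n_boot = n_boot
  ), class = "composite_profile")
}

#' @export
print.composite_profile <- function(x, ...) {
  cat(sprintf("<composite_profile> %d anchors, %d-bp bins, %s strand, %g-%g%% band\n",
              x$n_anchors, x$bin_size, x$strand_mode, x$conf[1], x$conf[2]))
  print(x$profile, n = 5)
  invisible(x)
}

#' @rdname composite_profile
#' @param x A `composite_profile`.
#' @param ... Unused.
#' @export
tidy.composite_profile <- function(x, ...) x$profile

#' Scale a set of composite profiles to a shared maximum
#'
#' For one factor across several element groups, the highest mean bin value
#' in any group becomes 1 and every bin in every group is divided by that
#' single constant, preserving all within- and between-group ratios.
#' Applying the scaling twice changes nothing.
#'
#' @param profiles Named list of [composite_profile()] objects.
#' @return The list, scaled, with the constant in `attr(, "scale_max")`.
#' @export
scaled_profiles <- function(profiles) {
  stopifnot(length(profiles) > 0)
  mx <- max(map_dbl(profiles, ~ max(.x$profile$mean)))
  if (mx <= 0) return(profiles)
  out <- map(profiles, function(p) {
    p$profile <- p$profile %>%
      mutate(across(c("mean", "lo", "hi"), ~ .x / mx))
    p
  })
  attr(out, "scale_max") <- mx
  out
}

#' Binned signal heatmap matrix over elements
#'
#' One row per element, binned signal across a fixed window around each
#' element's anchor (mirrored for minus-strand anchors). Rows are sorted by
#' `sort_key` ascending, ties broken by element id, and the order is
#' recorded. With `paired_strands = TRUE` both strands are queried
#' separately (the 4-bp strand-paired mode used for nucleotide-resolution
#' factor footprints) and two matrices are returned.
#'
#' @param track A [signal_track()].
#' @param elements Tibble `id, chrom, pos, strand` plus the sort-key column.
#' @param bin_size Bin width, bp (default 10; 4 for strand-paired mode).
#' @param flank Half-width, bp.
#' @param strand_mode Passed to [query_bins()] (ignored when paired).
#' @param sort_key Column of `elements` to sort rows by (NULL keeps order).
#' @param paired_strands Query sense and antisense separately.
#' @return A `heatmap_matrix`: `matrix` (or `matrix_sense`/`matrix_antisense`),
#'   `elements` (in row order), `bin_size`.
#' @export
heatmap_matrix <- function(track, elements, bin_size = 10, flank = 1000,
                           strand_mode = "sense", sort_key = NULL,
                           paired_strands = FALSE) {
  if (flank %% bin_size != 0) abort("flank must be a multiple of bin_size")
  if (!is.null(sort_key)) {
    elements <- elements[order(elements[[sort_key]], elements$id), ]
  }
  nb <- flank %/% bin_size
  q <- function(mode) {
    m <- t(vapply(seq_len(nrow(elements)), function(i)
      query_bins(track, elements$chrom[i], elements$pos[i],
                 elements$strand[i] %||% "+", bin_size, nb, mode),
      numeric(2 * nb)))
    rownames(m) <- elements$id
    colnames(m) <- seq(-flank, flank - bin_size, by = bin_size)
    m
  }
  out <- if (paired_strands) {
    list(matrix_sense = q("sense"), matrix_antisense = q("antisense"))
  } else {
    list(matrix = q(strand_mode))
  }
  structure(c(out, list(elements = elements, bin_size = bin_size,
                        sort_key = sort_key)),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  m <- x$matrix %||% x$matrix_sense
  cat(sprintf("<heatmap_matrix> %d elements x %d bins (%d bp)%s, sorted by %s\n",
              nrow(m), ncol(m), x$bin_size,
              if (is.null(x$matrix)) ", strand-paired" else "",
              x$sort_key %||% "input order"))
  invisible(x)
}

#' Categorize factor-binding sites by overlap with TREs
#'
#' A peak overlapping a promoter TRE by at least one nucleotide is a
#' promoter site; otherwise a peak overlapping a dTRE by at least one
#' nucleotide is a dTRE site; everything else is untranscribed. The
#' promoter-first precedence for dual-overlap peaks can be inverted.
#'
#' @param peaks Tibble `chrom, start, end` (+ any other columns, kept).
#' @param promoters,dtres Tibbles `chrom, start, end`.
#' @param precedence `"promoter"` (default) or `"dtre"` first.
#' @return List: `sites` (peaks + `category`), `counts`
#'   (category, n, percent).
#' @export
categorize_factor_sites <- function(peaks, promoters, dtres,
                                    precedence = c("promoter", "dtre")) {
  precedence <- match.arg(precedence)
  hits <- function(set) {
    map_lgl(seq_len(nrow(peaks)), function(i)
      any(set$chrom == peaks$chrom[i] &
            set$start < peaks$end[i] & peaks$start[i] < set$end))
  }
  in_prom <- hits(promoters); in_dtre <- hits(dtres)
  cat3 <- if (precedence == "promoter") {
    case_when(in_prom ~ "promoter", in_dtre ~ "dTRE", TRUE ~ "untranscribed")
  } else {
    case_when(in_dtre ~ "dTRE", in_prom ~ "promoter", TRUE ~ "untranscribed")
  }
  sites <- peaks %>% mutate(category = !!cat3)
  counts <- sites %>%
    dplyr::count(.data$category, name = "n") %>%
    mutate(percent = 100 * .data$n / sum(.data$n))
  list(sites = sites, counts = counts)
}

#' Factor binding on genes and summit-to-pause distances
#'
#' A gene is bound when any peak overlaps the window from `upstream` bp
#' before the TSS to the polyA site (in the gene's frame). For bound genes
#' the signed distance from the nearest peak summit to the sense
#' pause-window midpoint is reported in gene-frame bp (negative = upstream
#' of the pause).
#'
#' @param peaks Tibble `chrom, start, end, summit`.
#' @param genes Output of [filter_genes()].
#' @param quants [quantify_genes()] result supplying the pause windows.
#' @param upstream Window extension upstream of the TSS, bp (default 2500).
#' @return Tibble `gene_id, bound, summit_to_pause`.
#' @export
gene_binding <- function(peaks, genes, quants, upstream = 2500) {
  q <- quants[match(genes$gene_id, quants$gene_id), ]
  rows <- map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gg <- rel_to_genomic(g$tss, g$strand, -upstream, g$length)
    ov <- peaks$chrom == g$chrom & peaks$start < gg[2] & gg[1] < peaks$end
    if (!any(ov)) {
      return(tibble(gene_id = g$gene_id, bound = FALSE,
                    summit_to_pause = NA_real_))
    }
    pause_mid <- (q$pause_start[i] + q$pause_end[i]) / 2
    rel <- function(x) if (g$strand == "+") x - g$tss else g$tss - x
    d <- rel(peaks$summit[ov]) - rel(pause_mid)
    tibble(gene_id = g$gene_id, bound = TRUE,
           summit_to_pause = d[which.min(abs(d))])
  })
  bind_rows(rows)
}

#' Convert raw binding intensities to browser-style scores
#'
#' Affine min-max map of the raw intensities over a peak set onto
#' `[lo, hi]` (defaults 107-1000): the strongest peak maps to `hi`, the
#' weakest to `lo`.
#'
#' @param raw Raw intensities (e.g. fold enrichment over input).
#' @param lo,hi Target score endpoints.
#' @return Numeric scores in `[lo, hi]`.
#' @export
convert_binding_score <- function(raw, lo = 107, hi = 1000) {
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warn("constant intensities; returning midpoint score")
    return(rep((lo + hi) / 2, length(raw)))
  }
  lo + (raw - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Rank-based group statistics
#'
#' Spearman's rank correlation between `x` and `y` (exact p-value for
#' n <= 20 without ties, normal approximation otherwise), and/or a two-sided
#' Mann-Whitney U test between every pair of groups.
#'
#' @param x Numeric values.
#' @param y Optional paired values (Spearman).
#' @param groups Optional group labels for `x` (Mann-Whitney).
#' @return List with tibbles `spearman` and/or `mann_whitney`.
#' @export
group_stats <- function(x, y = NULL, groups = NULL) {
  out <- list()
  if (!is.null(y)) {
    n <- length(x)
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = n <= 20))
    out$spearman <- tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                           n = n)
  }
  if (!is.null(groups)) {
    lev <- unique(as.character(groups))
    cmp <- utils::combn(lev, 2, simplify = FALSE)
    out$mann_whitney <- bind_rows(map(cmp, function(pr) {
      wt <- suppressWarnings(
        wilcox.test(x[groups == pr[1]], x[groups == pr[2]],
                    alternative = "two.sided"))
      tibble(group1 = pr[1], group2 = pr[2],
             u = unname(wt$statistic), p_value = wt$p.value)
    }))
  }
  out
}
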