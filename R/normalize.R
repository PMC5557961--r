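#' Reference regions for cross-condition normalization
#'
#' The 3' ends of long genes move too slowly to change within a 30-minute
#' stress: an advancing or receding Pol II wave travelling at ~2 kb/min covers
#' at most ~60 kb, so for genes longer than 150 kb the region from +100 kb
#' after the TSS to −0.5 kb before the polyA site is transcriptionally
#' invariant and anchors the scale factors.
#'
#' @param genes Output of [filter_genes()].
#' @param min_length Minimum gene length, bp (strict `>`).
#' @param from_tss,before_polya Region bounds within the gene frame, bp.
#' @return Tibble `gene_id, chrom, start, end, strand` (genomic, half-open).
#' @export
reference_regions <- function(genes, min_length = 150000,
                              from_tss = 100000, before_polya = 500) {
  long <- genes %>% filter(.data$length > min_length)
  if (nrow(long) == 0) {
    abort(paste0("no genes longer than ", min_length, " bp; normalization impossible"))
  }
  g <- purrr::pmap(
    list(long$tss, long$strand, long$length),
    function(tss, strand, length)
      rel_to_genomic(tss, strand, from_tss, length - before_polya))
  tibble(gene_id = long$gene_id, chrom = long$chrom,
         start = map_dbl(g, 1), end = map_dbl(g, 2), strand = long$strand)
}

region_sums <- function(track, regions) {
  map_dbl(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    sum(rel_values(track, r$chrom, r$start, "+", 0, r$end - r$start, "both"))
  })
}

#' Fit per-sample scale factors from reference regions
#'
#' The default estimator is the ratio of total reference-region counts
#' (both strands summed): `factor_s = sum(baseline) / sum(sample_s)`.
#' Applying `factor_s` to sample `s` equalizes the reference sums exactly.
#' A median-of-per-region-ratios estimator is available behind
#' `method = "median_ratio"`.
#'
#' @param tracks Named list of [signal_track()] objects.
#' @param regions Output of [reference_regions()].
#' @param baseline Name of the baseline sample (factor fixed to 1).
#' @param method `"ratio"` (default) or `"median_ratio"`.
#' @return A `normalization_fit` object; see [tidy.normalization_fit()].
#' @export
fit_scale_factors <- function(tracks, regions, baseline = names(tracks)[1],
                              method = c("ratio", "median_ratio")) {
  method <- match.arg(method)
  if (nrow(regions) == 0) abort("no reference regions")
  if (!baseline %in% names(tracks)) abort("baseline sample not in tracks")
  sums <- map(tracks, region_sums, regions = regions)
  totals <- map_dbl(sums, sum)
  if (any(totals == 0)) {
    abort(paste0("zero reference counts in sample(s): ",
                 paste(names(totals)[totals == 0], collapse = ", ")))
  }
  factors <- switch(method,
    ratio = totals[[baseline]] / totals,
    median_ratio = map_dbl(sums, function(s) {
      ok <- s > 0 & sums[[baseline]] > 0
      if (!any(ok)) abort("no usable reference region ratios")
      median(sums[[baseline]][ok] / s[ok])
    })
  )
  structure(list(
    factors = tibble(sample = names(tracks), factor = unname(factors),
                     reference_sum = unname(totals)),
    regions = regions, baseline = baseline, method = method
  ), class = "normalization_fit")
}

#' @export
print.normalization_fit <- function(x, ...) {
  cat(sprintf("<normalization_fit> %d reference regions, baseline %s, method %s\n",
              nrow(x$regions), x$baseline, x$method))
  print(x$factors)
  invisible(x)
}

#' @rdname fit_scale_factors
#' @param x A `normalization_fit`.
#' @param ... Unused.
#' @export
tidy.normalization_fit <- function(x, ...) x$factors

#' Apply a scale factor to a track
#'
#' Multiplies every value by `factor` and records it in the track metadata.
#' A second application is refused: normalization is not idempotent and
#' double-scaling is almost always a pipeline bug.
#'
#' @param track A raw [signal_track()].
#' @param factor Positive scale factor.
#' @return The normalized [signal_track()].
#' @export
apply_scale <- function(track, factor) {
  stopifnot(factor > 0)
  if (!is.null(track$norm_factor)) {
    abort(paste0("track already normalized (factor ", track$norm_factor,
                 "); refusing to scale twice"))
  }
  track$plus <- lapply(track$plus, `*`, factor)
  if (is_stranded(track)) track$minus <- lapply(track$minus, `*`, factor)
  track$norm_factor <- factor
  track
}
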