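#' @title Relative-frame coordinate arithmetic
#' @description
#' Every quantification in the package works in an element's own frame:
#' relative position 0 is the TSS (or anchor) base and positions increase
#' 5'→3' of the element. For a minus-strand anchor the genomic coordinates are
#' mirrored, so a half-open relative window `[a, b)` maps to the genomic
#' interval `[tss - b + 1, tss - a + 1)`; for a plus-strand anchor it maps to
#' `[tss + a, tss + b)`. Mirroring also swaps which physical strand is "sense".
#' @name relative-frame
NULL

rel_to_genomic <- function(anchor, strand, rel_start, rel_end) {
  if (strand == "-") c(anchor - rel_end + 1, anchor - rel_start + 1)
  else c(anchor + rel_start, anchor + rel_end)
}

physical_strand <- function(anchor_strand, strand_mode) {
  switch(strand_mode,
    sense = anchor_strand,
    antisense = if (anchor_strand == "-") "+" else "-",
    unstranded = ".",
    both = "both",
    abort(paste0("unknown strand_mode: ", strand_mode))
  )
}

# Per-base values over a relative half-open window, oriented 5'->3' of the
# anchor. Errors (never truncates) if the window leaves the chromosome.
rel_values <- function(track, chrom, anchor, anchor_strand,
                       rel_start, rel_end, strand_mode = "sense") {
  g <- rel_to_genomic(anchor, anchor_strand, rel_start, rel_end)
  if (!chrom %in% names(track$chrom_sizes)) {
    abort(paste0("chromosome not in track: ", chrom))
  }
  n <- track$chrom_sizes[[chrom]]
  if (g[1] < 0 || g[2] > n) {
    abort(sprintf("window [%d,%d) off chromosome %s (length %d)", g[1], g[2], chrom, n))
  }
  ps <- physical_strand(anchor_strand, strand_mode)
  idx <- (g[1] + 1):g[2]
  v <- if (identical(ps, "both")) {
    strand_vec(track, chrom, "+")[idx] +
      (if (is_stranded(track)) strand_vec(track, chrom, "-")[idx] else 0)
  } else {
    strand_vec(track, chrom, ps)[idx]
  }
  if (anchor_strand == "-") rev(v) else v
}

#' Query signal in fixed bins around an anchor
#'
#' Sums per-base signal in `2 * n_bins_flank` half-open bins of `bin_size` bp
#' covering relative positions `[-n_bins_flank * bin_size,
#' +n_bins_flank * bin_size)` around an anchor base, in the anchor's 5'→3'
#' frame. Minus-strand anchors are mirrored (bin order runs 5'→3' of the
#' element; sense and antisense physical strands are swapped).
#'
#' @param track A [signal_track()].
#' @param chrom,anchor,anchor_strand Anchor base (0-based) and its strand.
#' @param bin_size Bin width in bp.
#' @param n_bins_flank Number of bins on each side of the anchor.
#' @param strand_mode `"sense"`, `"antisense"`, `"both"` or `"unstranded"`.
#' @return Numeric vector of bin sums, 5'→3'.
#' @export
query_bins <- function(track, chrom, anchor, anchor_strand = "+",
                       bin_size = 20, n_bins_flank = 10,
                       strand_mode = "sense") {
  span <- bin_size * n_bins_flank
  v <- rel_values(track, chrom, anchor, anchor_strand, -span, span, strand_mode)
  as.numeric(colSums(matrix(v, nrow = bin_size)))
}

#' Signal density in reads per kilobase (RPK)
#'
#' `RPK = 1000 * sum(counts in interval on the selected strand) / length`.
#'
#' @inheritParams query_bins
#' @param start,end Genomic interval, 0-based half-open.
#' @return RPK (double).
#' @export
region_rpk <- function(track, chrom, start, end, anchor_strand = "+",
                       strand_mode = "sense") {
  if (end <= start) abort("zero-length interval in region_rpk")
  v <- rel_values(track, chrom, if (anchor_strand == "-") end - 1 else start,
                  anchor_strand, 0, end - start, strand_mode)
  1000 * sum(v) / (end - start)
}

#' Maximal fixed-width window within a search region
#'
#' Scans all placements of a `window`-bp window fully inside the relative
#' search region `[rel_start, rel_end)` (default step 1 bp) and returns the
#' placement with the highest count. Ties are broken by the most upstream
#' window in the element's 5'→3' frame, so the call is deterministic.
#'
#' @inheritParams query_bins
#' @param rel_start,rel_end Half-open search region in relative coordinates.
#' @param window Window width, bp.
#' @param step Scan step, bp (default 1).
#' @return A one-row tibble: `offset` (window start relative to the anchor),
#'   `count`, `rpk`, and the genomic `start`/`end` of the window.
#' @export
max_window <- function(track, chrom, anchor, anchor_strand = "+",
                       rel_start = -100, rel_end = 400, window = 50,
                       strand_mode = "sense", step = 1) {
  if (window > rel_end - rel_start) abort("window larger than search region")
  v <- rel_values(track, chrom, anchor, anchor_strand, rel_start, rel_end, strand_mode)
  cs <- c(0, cumsum(v))
  starts <- seq(1, length(v) - window + 1, by = step)
  sums <- cs[starts + window] - cs[starts]
  i <- which.max(sums)  # first max = most upstream in 5'->3' frame
  offset <- rel_start + starts[i] - 1
  g <- rel_to_genomic(anchor, anchor_strand, offset, offset + window)
  tibble(offset = offset, count = sums[i], rpk = 1000 * sums[i] / window,
         start = g[1], end = g[2])
}
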