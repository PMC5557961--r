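#' Filter an annotation to eligible genes
#'
#' Keeps RNA/protein-coding genes of at least 500 bp and collapses redundancy:
#' among genes sharing an identical TSS (same chromosome, strand and
#' position), only the longest survives.
#'
#' @param annotation Tibble with columns `gene_id, chrom, start, end, strand`
#'   (0-based half-open, strand `+`/`-`).
#' @param min_length Minimum gene length, bp (inclusive).
#' @return The filtered annotation with `tss`, `polya` and `length` columns
#'   added.
#' @export
filter_genes <- function(annotation, min_length = 500) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(annotation))
  if (length(miss)) abort(paste0("annotation lacks columns: ", paste(miss, collapse = ", ")))
  bad <- which(!(annotation$strand %in% c("+", "-")) |
                 annotation$start < 0 | annotation$end <= annotation$start)
  if (length(bad)) {
    abort(paste0("malformed annotation record(s) at row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  annotation %>%
    mutate(length = .data$end - .data$start,
           tss = if_else(.data$strand == "+", .data$start, .data$end - 1L),
           polya = if_else(.data$strand == "+", .data$end - 1L, .data$start)) %>%
    filter(.data$length >= min_length) %>%
    group_by(.data$chrom, .data$strand, .data$tss) %>%
    arrange(dplyr::desc(.data$length), .data$gene_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start)
}

#' Quantify pausing, divergent initiation and gene-body transcription
#'
#' For each gene, in its own 5'→3' frame: the promoter-proximal pause is the
#' maximal 50-nt window on the coding strand within −100..+400 nt of the TSS;
#' divergent initiation is the maximal 50-nt window on the antisense strand
#' within −800..+100 nt; gene-body density is the RPK from +500 nt after the
#' TSS to −500 nt before the polyA site. The pausing index is pause-window
#' RPK divided by body RPK (both length-normalized densities) and is left
#' `NA` when the body is empty or undefined (genes shorter than 1000 bp).
#'
#' @param track A [signal_track()].
#' @param genes Output of [filter_genes()].
#' @param condition Label stored in the result.
#' @param pause_region,divergent_region Half-open relative search regions.
#' @param window Scored window width, bp.
#' @param pause_scan_step Step of the window scan, bp.
#' @return Tibble, one row per gene: pause and divergent window calls
#'   (`*_offset`, `*_rpk`, genomic `*_start`/`*_end`), `body_rpk`,
#'   `pausing_index`, `condition`.
#' @export
quantify_genes <- function(track, genes, condition = NA_character_,
                           pause_region = c(-100, 400),
                           divergent_region = c(-800, 100),
                           window = 50, pause_scan_step = 1) {
  rows <- purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$tss, genes$strand, genes$length),
    function(gene_id, chrom, tss, strand, length) {
      p <- max_window(track, chrom, tss, strand,
                      pause_region[1], pause_region[2], window,
                      strand_mode = "sense", step = pause_scan_step)
      d <- max_window(track, chrom, tss, strand,
                      divergent_region[1], divergent_region[2], window,
                      strand_mode = "antisense", step = pause_scan_step)
      body_len <- length - 1000
      if (body_len > 0) {
        v <- rel_values(track, chrom, tss, strand, 500, length - 500, "sense")
        body_rpk <- 1000 * sum(v) / body_len
      } else {
        body_rpk <- NA_real_
      }
      tibble(gene_id = gene_id,
             pause_offset = p$offset, pause_rpk = p$rpk,
             pause_start = p$start, pause_end = p$end,
             div_offset = d$offset, div_rpk = d$rpk,
             div_start = d$start, div_end = d$end,
             body_rpk = body_rpk,
             pausing_index = if (!is.na(body_rpk) && body_rpk > 0)
               p$rpk / body_rpk else NA_real_)
    })
  bind_rows(rows) %>% mutate(condition = condition)
}

#' Flag genes not transcribed in any condition
#'
#' A gene is UnExp when, in every condition supplied, its body RPK is below
#' `min_body_rpk` and its pause RPK is below `min_pause_rpk` (strict `<`).
#' The thresholds are configuration values, not biological claims.
#'
#' @param quants Row-bound [quantify_genes()] results across conditions.
#' @param min_body_rpk,min_pause_rpk Thresholds (defaults 0.5 and 2).
#' @return Tibble `gene_id`, `unexp`.
#' @export
flag_unexpressed <- function(quants, min_body_rpk = 0.5, min_pause_rpk = 2) {
  quants %>%
    group_by(.data$gene_id) %>%
    summarise(unexp = all(
      (is.na(.data$body_rpk) | .data$body_rpk < min_body_rpk) &
        .data$pause_rpk < min_pause_rpk), .groups = "drop")
}
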