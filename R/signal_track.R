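#' Strand-specific base-resolution signal track
#'
#' A `signal_track` holds per-base, per-strand, non-negative signal (the 3'
#' ends of nascent RNAs for PRO-seq; read density for DNaseI) over one or more
#' chromosomes. All genomic coordinates used by the package are 0-based
#' half-open (BED convention): the value at genomic position `p` on chromosome
#' `chrom` lives at `track$plus[[chrom]][p + 1]`.
#'
#' Raw tracks carry integer counts; normalized tracks carry non-negative reals
#' and record the scale factor that was applied (see [apply_scale()]).
#'
#' @param plus,minus Named lists of non-negative numeric vectors, one per
#'   chromosome. `minus` may be `NULL` for an unstranded track (DNaseI).
#' @param sample,condition,replicate Optional metadata labels.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(plus, minus = NULL,
                         sample = NA_character_, condition = NA_character_,
                         replicate = NA_integer_) {
  stopifnot(is.list(plus), !is.null(names(plus)))
  if (!is.null(minus)) {
    stopifnot(identical(names(plus), names(minus)))
    for (chr in names(plus)) {
      if (length(plus[[chr]]) != length(minus[[chr]])) {
        abort(paste0("plus and minus strand lengths differ on ", chr))
      }
    }
  }
  for (chr in names(plus)) {
    if (any(plus[[chr]] < 0) || (!is.null(minus) && any(minus[[chr]] < 0))) {
      abort("signal_track values must be non-negative")
    }
  }
  structure(
    list(plus = plus, minus = minus,
         chrom_sizes = vapply(plus, length, integer(1)),
         sample = sample, condition = condition, replicate = replicate,
         norm_factor = NULL),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> ", if (is.null(x$minus)) "unstranded" else "stranded",
      if (!is.null(x$norm_factor)) sprintf(", normalized (factor %.4g)", x$norm_factor) else ", raw",
      "\n", sep = "")
  for (chr in names(x$plus)) {
    cat(sprintf("  %s: %s bp, total signal %.4g (+)%s\n", chr,
                format(x$chrom_sizes[[chr]], big.mark = ","),
                sum(x$plus[[chr]]),
                if (is.null(x$minus)) "" else sprintf(" / %.4g (-)", sum(x$minus[[chr]]))))
  }
  invisible(x)
}

is_stranded <- function(track) !is.null(track$minus)

strand_vec <- function(track, chrom, strand) {
  v <- switch(strand,
    "+" = track$plus[[chrom]],
    "-" = {
      if (!is_stranded(track)) abort("track is unstranded; no minus strand")
      track$minus[[chrom]]
    },
    "." = track$plus[[chrom]],
    abort(paste0("unknown strand: ", strand))
  )
  if (is.null(v)) abort(paste0("chromosome not in track: ", chrom))
  v
}

#' Write one strand of a track as bedGraph
#'
#' Runs of equal value are collapsed; zero runs are omitted. Coordinates are
#' 0-based half-open (the bedGraph convention).
#'
#' @param track A [signal_track()].
#' @param path Output file.
#' @param strand `"+"`, `"-"` or `"."` (unstranded).
#' @param negate_minus Write minus-strand values as negative magnitudes, the
#'   dialect used by many PRO-seq browsers. Values are stored internally as
#'   magnitudes either way.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, strand = "+", negate_minus = FALSE) {
  gr_list <- list()
  for (chr in names(track$plus)) {
    v <- strand_vec(track, chr, strand)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    keep <- r$values != 0
    if (!any(keep)) next
    score <- r$values[keep]
    if (strand == "-" && negate_minus) score <- -score
    gr_list[[chr]] <- GenomicRanges::GRanges(
      seqnames = chr,
      ranges = IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
      score = score
    )
  }
  gr <- if (length(gr_list)) do.call(c, unname(gr_list)) else
    GenomicRanges::GRanges(score = numeric(0))
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Read a bedGraph file into per-base vectors
#'
#' @param path bedGraph file.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return Named list of per-base numeric vectors. Negative values (the
#'   minus-strand dialect) are stored as magnitudes.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  gr <- rtracklayer::import.bedGraph(path)
  out <- lapply(chrom_sizes, function(n) numeric(n))
  df <- as.data.frame(gr)
  for (i in seq_len(nrow(df))) {
    chr <- as.character(df$seqnames[i])
    if (!chr %in% names(out)) abort(paste0("bedGraph chromosome not in chrom_sizes: ", chr))
    idx <- df$start[i]:df$end[i]  # GRanges 1-based closed == our vector index
    out[[chr]][idx] <- abs(df$score[i])
  }
  out
}

#' Assemble a stranded track from two bedGraph files
#'
#' @inheritParams read_bedgraph
#' @param plus_path,minus_path Per-strand bedGraph files.
#' @inheritParams signal_track
#' @return A [signal_track()].
#' @export
read_signal_track <- function(plus_path, minus_path, chrom_sizes,
                              sample = NA_character_, condition = NA_character_,
                              replicate = NA_integer_) {
  signal_track(read_bedgraph(plus_path, chrom_sizes),
               read_bedgraph(minus_path, chrom_sizes),
               sample = sample, condition = condition, replicate = replicate)
}

#' Read a BED6-like file of intervals as a tibble
#'
#' Accepts 3 to 6 columns; missing columns are filled with defaults
#' (`name = "."`, `score = 0`, `strand = "."`). narrowPeak files (10 columns,
#' summit offset in column 10) gain `summit` = start + offset.
#'
#' @param path BED/narrowPeak file.
#' @return Tibble with `chrom, start, end, name, score, strand` (+ `summit`).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  nc <- ncol(df)
  out <- tibble(
    chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    name = if (nc >= 4) as.character(df[[4]]) else ".",
    score = if (nc >= 5) as.numeric(df[[5]]) else 0,
    strand = if (nc >= 6) as.character(df[[6]]) else "."
  )
  if (nc >= 10) out$summit <- out$start + as.integer(df[[10]])
  out
}

#' Write intervals as BED6 or narrowPeak
#'
#' @param x Tibble with `chrom, start, end` and optionally `name, score,
#'   strand, summit`.
#' @param path Output file.
#' @param narrowpeak Write 10-column narrowPeak (requires `summit`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, narrowpeak = FALSE) {
  name <- x$name %||% rep(".", nrow(x))
  score <- x$score %||% rep(0, nrow(x))
  strand <- x$strand %||% rep(".", nrow(x))
  df <- data.frame(x$chrom, x$start, x$end, name, score, strand)
  if (narrowpeak) {
    stopifnot(!is.null(x$summit))
    df <- cbind(df, -1, -1, -1, x$summit - x$start)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
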