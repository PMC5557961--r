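#' Simulation parameters for the synthetic genome
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' simulated study: a single chromosome carrying a few hundred genes and
#' dozens of distal transcribed regulatory elements (dTREs), profiled in two
#' conditions (NHS = unstressed, HS = after a 30-minute heat shock) with two
#' replicates each. Genes initiate divergently (stable sense transcript plus
#' an unstable upstream antisense transcript), carry a promoter-proximal
#' pause peak 20-60 bp downstream of the TSS and uniform gene-body signal;
#' heat shock moves Pol II into the pause (pause accumulation) while the body
#' signal of downregulated genes is cleared 5'→3' up to a hard wave front at
#' `elongation_rate * hs_duration` bp, and upregulated genes gain body signal
#' only up to the same advancing front. Counts are negative-binomial via
#' independent per-base Gamma-Poisson draws with one shared dispersion
#' parameter.
#'
#' @param n_genes Number of genes (a few are forced longer than 150 kb so
#'   that the long-gene normalization anchor always exists).
#' @param n_dtres,n_untranscribed_sites Numbers of dTREs and of untranscribed
#'   control sites.
#' @param chrom_length Chromosome length, bp.
#' @param elongation_rate Pol II elongation rate, bp per minute.
#' @param hs_duration Heat-shock duration, minutes.
#' @param pause_position_range Offsets of the pause-peak start from the TSS, bp.
#' @param pause_width Width of the pause peak, bp.
#' @param body_density_range Range of expected gene-body density, reads per kb.
#' @param nb_dispersion Negative-binomial dispersion (Gamma-Poisson mixing
#'   variance); 0 gives Poisson counts.
#' @param frac_up,frac_down,frac_unexp Proportions of genes that are
#'   upregulated, downregulated, or untranscribed.
#' @param fc_up,fc_down Fold changes applied to responsive elements in HS.
#' @param hs_pause_gain Pause-peak fold increase for Down genes in HS
#'   (pause accumulation without release).
#' @param hs_pause_shift How many bp the Down-gene pause summit tightens
#'   toward the TSS upon HS.
#' @param divergent_offset_range Distance of the upstream antisense initiation
#'   site from the sense TSS, bp.
#' @param divergent_rel_intensity Antisense peak density relative to the sense
#'   pause density.
#' @param pause_index_meanlog,pause_index_sdlog Log-normal parameters of the
#'   per-gene pausing index used to scale pause peaks.
#' @param gene_length_meanlog,gene_length_sdlog,gene_length_range Log-normal
#'   parameters and clamp for gene lengths, bp.
#' @param n_long_genes,long_gene_length_range Number and length range of the
#'   forced long (>150 kb) genes.
#' @param dtre_length_range,dtre_intersummit_range,dtre_rpk_range dTRE element
#'   length, distance between the two strand summits, and per-strand peak
#'   density (reads per kb).
#' @param dtre_frac_paused Fraction of dTREs whose HS response is pause
#'   accumulation without a count change (profile change only).
#' @param dnase_bandwidth Gaussian bandwidth of the DNaseI expectation, bp.
#' @param dnase_noise_sd Standard deviation of i.i.d. noise added to the
#'   DNaseI track, signal units.
#' @param gc_promoter,gc_dtre,gc_background Mean GC fraction of promoter
#'   windows, dTRE windows, and the genomic background.
#' @param cpg_promoter,cpg_dtre CpG dinucleotide rates of the two classes.
#' @param seed Integer seed; identical parameters and seed give byte-identical
#'   outputs.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_genes = 300, n_dtres = 80, n_untranscribed_sites = 40,
                       chrom_length = 6e6,
                       elongation_rate = 2000, hs_duration = 30,
                       pause_position_range = c(20, 60), pause_width = 40,
                       body_density_range = c(5, 80),
                       nb_dispersion = 0.05,
                       frac_up = 0.12, frac_down = 0.40, frac_unexp = 0.10,
                       fc_up = 3, fc_down = 0.3,
                       hs_pause_gain = 2, hs_pause_shift = 10,
                       divergent_offset_range = c(110, 250),
                       divergent_rel_intensity = 0.5,
                       pause_index_meanlog = log(8), pause_index_sdlog = 0.5,
                       gene_length_meanlog = log(6000), gene_length_sdlog = 0.8,
                       gene_length_range = c(600, 40000),
                       n_long_genes = 4, long_gene_length_range = c(160e3, 220e3),
                       dtre_length_range = c(300, 900),
                       dtre_intersummit_range = c(60, 200),
                       dtre_rpk_range = c(30, 200),
                       dtre_frac_paused = 0,
                       dnase_bandwidth = 150, dnase_noise_sd = 0.05,
                       gc_promoter = 0.60, gc_dtre = 0.48, gc_background = 0.41,
                       cpg_promoter = 0.10, cpg_dtre = 0.04,
                       seed = 1L) {
  p <- as.list(environment())
  with(p, {
    stopifnot(n_genes > 0, n_dtres > 0, n_untranscribed_sites > 0,
              chrom_length > 0, pause_width > 0, nb_dispersion >= 0,
              frac_up >= 0, frac_down >= 0, frac_unexp >= 0,
              frac_up + frac_down + frac_unexp <= 1,
              dtre_frac_paused >= 0, dtre_frac_paused <= 1,
              fc_up > 0, fc_down > 0, dnase_noise_sd >= 0)
    if (elongation_rate * hs_duration >= chrom_length) {
      abort("elongation_rate * hs_duration must be < chrom_length")
    }
  })
  structure(p, class = "sim_params")
}

# seed stream: decorrelates conditions/replicates while staying reproducible
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in ks) s <- (s * 48271 + as.double(k)) %% 2147483629
  as.integer(s)
}

hs_front <- function(params) params$elongation_rate * params$hs_duration

#' Generate the ground-truth element layout of a synthetic genome
#'
#' Lays out non-overlapping genes (on the same strand), dTREs and
#' untranscribed sites on one chromosome, assigns response classes and
#' expression levels, and emits broad candidate TRE regions with scores
#' (emulating the output of an upstream broad-region TRE detector). All
#' downstream simulators consume this truth object.
#'
#' @param params A [sim_params()] object.
#' @return A `synthetic_truth` list with tibbles `genes`, `dtres`,
#'   `untranscribed`, `candidates`, `truth_peaks`, plus `chrom_sizes`.
#'   Gene coordinates are 0-based half-open; `tss` and `polya` are the
#'   0-based initiation and cleavage bases.
#' @export
generate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(derive_seed(params$seed, 1L), {
    p <- params
    chrom <- "chrS"
    n_short <- p$n_genes - p$n_long_genes
    if (n_short < 0) abort("n_long_genes exceeds n_genes")
    len_short <- round(pmin(pmax(
      stats::rlnorm(n_short, p$gene_length_meanlog, p$gene_length_sdlog),
      p$gene_length_range[1]), p$gene_length_range[2]))
    len_long <- round(runif(p$n_long_genes, p$long_gene_length_range[1],
                            p$long_gene_length_range[2]))
    glen <- c(len_short, len_long)
    is_long_forced <- c(rep(FALSE, n_short), rep(TRUE, p$n_long_genes))

    pr <- c(p$frac_up, p$frac_down, p$frac_unexp)
    cls <- sample(c("Up", "Down", "UnExp", "UnCh"), p$n_genes, replace = TRUE,
                  prob = c(pr, 1 - sum(pr)))
    # long genes anchor normalization: keep them transcribed
    redraw <- is_long_forced & cls == "UnExp"
    if (any(redraw)) {
      pr2 <- c(p$frac_up, p$frac_down, 1 - p$frac_up - p$frac_down - p$frac_unexp)
      cls[redraw] <- sample(c("Up", "Down", "UnCh"), sum(redraw),
                            replace = TRUE, prob = pr2 / sum(pr2))
    }

    dlen <- round(runif(p$n_dtres, p$dtre_length_range[1], p$dtre_length_range[2]))
    ulen <- rep(600L, p$n_untranscribed_sites)

    # pack blocks: each element plus clearance for divergent/upstream signal
    blocks <- tibble(
      kind = c(rep("gene", p$n_genes), rep("dtre", p$n_dtres),
               rep("untx", p$n_untranscribed_sites)),
      idx = c(seq_len(p$n_genes), seq_len(p$n_dtres),
              seq_len(p$n_untranscribed_sites)),
      len = c(glen, dlen, ulen),
      pad = c(rep(1500, p$n_genes), rep(1200, p$n_dtres),
              rep(1200, p$n_untranscribed_sites))
    )
    margin <- 5000
    need <- sum(blocks$len + 2 * blocks$pad)
    avail <- p$chrom_length - 2 * margin
    if (need > avail) {
      abort(sprintf(
        "infeasible packing: elements need %d bp but only %d bp available",
        need, avail))
    }
    ord <- sample(nrow(blocks))
    blocks <- blocks[ord, ]
    slack <- avail - need
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, nrow(blocks) + 1)))
    starts <- margin + cumsum(c(0, blocks$len + 2 * blocks$pad)[seq_len(nrow(blocks))]) +
      cumsum(gaps[seq_len(nrow(blocks))])
    blocks$start <- starts + blocks$pad
    blocks$end <- blocks$start + blocks$len

    gb <- blocks[blocks$kind == "gene", ]
    gb <- gb[order(gb$idx), ]
    strand <- sample(c("+", "-"), p$n_genes, replace = TRUE)
    body <- runif(p$n_genes, p$body_density_range[1], p$body_density_range[2])
    pidx <- stats::rlnorm(p$n_genes, p$pause_index_meanlog, p$pause_index_sdlog)
    poff <- round(runif(p$n_genes, p$pause_position_range[1],
                        p$pause_position_range[2]))
    doff <- round(runif(p$n_genes, p$divergent_offset_range[1],
                        p$divergent_offset_range[2]))
    body[cls == "UnExp"] <- 0
    genes <- tibble(
      gene_id = sprintf("gene%04d", seq_len(p$n_genes)),
      chrom = chrom, start = gb$start, end = gb$end, strand = strand,
      length = gb$len, class = cls,
      tss = if_else(strand == "+", gb$start, gb$end - 1),
      polya = if_else(strand == "+", gb$end - 1, gb$start),
      body_rpk_nhs = body,
      body_rpk_hs = case_when(cls == "Up" ~ body * p$fc_up,
                              cls == "Down" ~ body * p$fc_down,
                              TRUE ~ body),
      pause_index = pidx,
      pause_rpk_nhs = body * pidx,
      pause_rpk_hs = case_when(cls == "Up" ~ body * pidx * p$fc_up,
                               cls == "Down" ~ body * pidx * p$hs_pause_gain,
                               TRUE ~ body * pidx),
      pause_offset_nhs = poff,
      pause_offset_hs = if_else(cls == "Down",
                                pmax(p$pause_position_range[1],
                                     poff - p$hs_pause_shift), poff),
      div_offset = doff
    )

    db <- blocks[blocks$kind == "dtre", ]
    db <- db[order(db$idx), ]
    dcls <- sample(c("up", "down", "unchanged"), p$n_dtres, replace = TRUE,
                   prob = c(p$frac_up, p$frac_down, 1 - p$frac_up - p$frac_down))
    paused_profile <- runif(p$n_dtres) < p$dtre_frac_paused
    isd <- round(runif(p$n_dtres, p$dtre_intersummit_range[1],
                       p$dtre_intersummit_range[2]))
    rpk_plus <- runif(p$n_dtres, p$dtre_rpk_range[1], p$dtre_rpk_range[2])
    rpk_minus <- runif(p$n_dtres, p$dtre_rpk_range[1], p$dtre_rpk_range[2])
    dmid <- floor((db$start + db$end) / 2)
    dfc <- case_when(dcls == "up" ~ p$fc_up, dcls == "down" ~ p$fc_down,
                     TRUE ~ 1)
    dfc[paused_profile] <- 1
    dtres <- tibble(
      dtre_id = sprintf("dtre%04d", seq_len(p$n_dtres)),
      chrom = chrom, start = db$start, end = db$end, class = dcls,
      mid = dmid, intersummit = isd,
      summit_plus = dmid + floor(isd / 2),
      summit_minus = dmid - ceiling(isd / 2),
      rpk_plus_nhs = rpk_plus, rpk_minus_nhs = rpk_minus,
      rpk_plus_hs = rpk_plus * dfc, rpk_minus_hs = rpk_minus * dfc,
      paused_profile = paused_profile
    )

    ub <- blocks[blocks$kind == "untx", ]
    ub <- ub[order(ub$idx), ]
    untx <- tibble(site_id = sprintf("untx%04d", seq_len(p$n_untranscribed_sites)),
                   chrom = chrom, start = ub$start, end = ub$end)

    # broad candidate regions with detector-like scores
    expressed <- genes$class != "UnExp"
    cj <- round(runif(p$n_genes, -80, 80))
    prom_lo <- pmin(genes$tss, genes$tss) - genes$div_offset - 150 + cj
    prom_hi <- genes$tss + 350 + round(runif(p$n_genes, -80, 80))
    prom_cand <- tibble(
      chrom = chrom,
      start = if_else(genes$strand == "+", prom_lo, genes$tss - 350 - round(runif(p$n_genes, -80, 80))),
      end = if_else(genes$strand == "+", prom_hi, genes$tss + genes$div_offset + 150 - cj),
      score = if_else(expressed, runif(p$n_genes, 0.75, 1), runif(p$n_genes, 0.1, 0.6)),
      kind = "promoter", element_id = genes$gene_id
    )
    dt_cand <- tibble(
      chrom = chrom,
      start = dtres$start - round(runif(p$n_dtres, 0, 120)),
      end = dtres$end + round(runif(p$n_dtres, 0, 120)),
      score = runif(p$n_dtres, 0.72, 1),
      kind = "dtre", element_id = dtres$dtre_id
    )
    candidates <- bind_rows(prom_cand, dt_cand)

    # true DNaseI apexes: midpoint between the divergent initiation summits
    pk_prom <- tibble(
      chrom = chrom,
      pos = round((genes$tss +
                     if_else(genes$strand == "+", 1, -1) *
                     round((genes$pause_offset_nhs + p$pause_width / 2 -
                              genes$div_offset - p$pause_width / 2) / 2))),
      element_id = genes$gene_id, kind = "promoter"
    )[expressed, ]
    pk_dtre <- tibble(chrom = chrom, pos = dtres$mid,
                      element_id = dtres$dtre_id, kind = "dtre")
    truth_peaks <- bind_rows(pk_prom, pk_dtre)

    structure(list(genes = genes, dtres = dtres, untranscribed = untx,
                   candidates = candidates, truth_peaks = truth_peaks,
                   chrom_sizes = setNames(as.integer(p$chrom_length), chrom)),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d genes (%s), %d dTREs, %d untranscribed sites on %s (%s bp)\n",
              nrow(x$genes),
              paste(sprintf("%s=%d", names(table(x$genes$class)),
                            as.integer(table(x$genes$class))), collapse = ", "),
              nrow(x$dtres), nrow(x$untranscribed),
              names(x$chrom_sizes)[1], format(x$chrom_sizes[[1]], big.mark = ",")))
  invisible(x)
}

# Flat list of expectation segments (element, strand, genomic half-open
# interval, per-base density) for one condition. The hard wave front for
# responsive genes sits at elongation_rate * hs_duration bp past the TSS.
signal_segments <- function(truth, params, condition = c("NHS", "HS")) {
  condition <- match.arg(condition)
  p <- params
  front <- hs_front(p)
  hs <- condition == "HS"
  segs <- list()
  k <- 0L
  put <- function(elem, strand, g0, g1, dens) {
    if (g1 > g0 && dens > 0) {
      k <<- k + 1L
      segs[[k]] <<- list(elem = elem, strand = strand,
                         start = g0, end = g1, dens = dens)
    }
  }
  for (i in seq_len(nrow(truth$genes))) {
    g <- truth$genes[i, ]
    if (g$class == "UnExp") next
    body <- (if (hs) g$body_rpk_hs else g$body_rpk_nhs) / 1000
    body_nhs <- g$body_rpk_nhs / 1000
    prpk <- (if (hs) g$pause_rpk_hs else g$pause_rpk_nhs) / 1000
    poff <- if (hs) g$pause_offset_hs else g$pause_offset_nhs
    sense <- g$strand
    anti <- if (sense == "+") "-" else "+"
    rel_put <- function(strand, a, b, dens) {
      gg <- rel_to_genomic(g$tss, g$strand, a, b)
      put(g$gene_id, strand, gg[1], gg[2], dens)
    }
    L <- g$length
    if (!hs || g$class == "UnCh") {
      rel_put(sense, 100, L, body)
    } else {
      # responsive gene in HS: the wave has only travelled `front` bp
      wf <- min(front, L)
      rel_put(sense, 100, 500, if (g$class == "Down") body_nhs else body)
      rel_put(sense, 500, wf, body)
      if (wf < L) rel_put(sense, wf, L, body_nhs)  # beyond the front: untouched
    }
    rel_put(sense, poff, poff + p$pause_width, prpk)
    rel_put(anti, -(g$div_offset + p$pause_width), -g$div_offset,
            p$divergent_rel_intensity * prpk)
  }
  for (i in seq_len(nrow(truth$dtres))) {
    d <- truth$dtres[i, ]
    rp <- (if (hs) d$rpk_plus_hs else d$rpk_plus_nhs) / 1000
    rm <- (if (hs) d$rpk_minus_hs else d$rpk_minus_nhs) / 1000
    w <- p$pause_width
    # plus-strand transcript fires rightward from its summit, minus leftward
    put(d$dtre_id, "+", d$summit_plus, d$summit_plus + w, rp)
    put(d$dtre_id, "+", d$summit_plus + w, d$summit_plus + w + 200, 0.15 * rp)
    put(d$dtre_id, "-", d$summit_minus - w + 1, d$summit_minus + 1, rm)
    put(d$dtre_id, "-", d$summit_minus - w + 1 - 200, d$summit_minus - w + 1,
        0.15 * rm)
  }
  bind_rows(lapply(segs, as_tibble))
}

# difference-array accumulation: O(chrom + segments)
segments_to_vector <- function(segs, n, weights = NULL) {
  delta <- numeric(n + 1)
  dens <- segs$dens * (weights %||% 1)
  s0 <- pmax(segs$start, 0); s1 <- pmin(segs$end, n)
  ok <- s1 > s0
  for (i in which(ok)) {
    delta[s0[i] + 1] <- delta[s0[i] + 1] + dens[i]
    delta[s1[i] + 1] <- delta[s1[i] + 1] - dens[i]
  }
  cumsum(delta)[seq_len(n)]
}

# Per-base expected signal for one condition; returns list(plus, minus).
expected_signal <- function(truth, params, condition = c("NHS", "HS")) {
  segs <- signal_segments(truth, params, condition)
  n <- truth$chrom_sizes[[1]]
  list(plus = segments_to_vector(segs[segs$strand == "+", ], n),
       minus = segments_to_vector(segs[segs$strand == "-", ], n))
}

#' Simulate a strand-specific PRO-seq-like track
#'
#' Draws negative-binomial counts around the per-base expectation for one
#' condition and replicate: independent Gamma-Poisson draws per base with a
#' single shared dispersion parameter (`nb_dispersion`), the same
#' mean-variance law the differential model assumes.
#'
#' @param truth A [generate_genome()] result.
#' @param params The same [sim_params()].
#' @param condition `"NHS"` or `"HS"`.
#' @param replicate Replicate index (1-based).
#' @param depth Global scale factor applied to the expectation (sequencing
#'   depth); used to exercise normalization recovery.
#' @return A stranded [signal_track()].
#' @export
simulate_tracks <- function(truth, params, condition = c("NHS", "HS"),
                            replicate = 1L, depth = 1) {
  condition <- match.arg(condition)
  stopifnot(inherits(truth, "synthetic_truth"), depth > 0)
  p <- params
  segs <- signal_segments(truth, p, condition)
  n <- truth$chrom_sizes[[1]]
  cond_i <- if (condition == "NHS") 1L else 2L
  withr::with_seed(derive_seed(p$seed, 2L, cond_i, replicate), {
    disp <- p$nb_dispersion
    # independent per-base Gamma-Poisson draws; the dispersion parameter is
    # shared across all bases of the chromosome
    draw_strand <- function(strand) {
      lam <- segments_to_vector(segs[segs$strand == strand, ], n) * depth
      counts <- numeric(n)
      nz <- which(lam > 0)
      counts[nz] <- if (disp > 0) {
        rnbinom(length(nz), mu = lam[nz], size = 1 / disp)
      } else {
        rpois(length(nz), lam[nz])
      }
      counts
    }
    plus <- draw_strand("+")
    minus <- draw_strand("-")
    signal_track(setNames(list(plus), names(truth$chrom_sizes)),
                 setNames(list(minus), names(truth$chrom_sizes)),
                 sample = paste0(condition, "_rep", replicate),
                 condition = condition, replicate = as.integer(replicate))
  })
}

# unnormalized (max 1): the smoothed track is a Gaussian-weighted sum, so a
# divergent initiation pair of unit mass yields an O(mass) hypersensitivity
# peak rather than a vanishing average
gaussian_kernel <- function(bw) {
  h <- ceiling(3 * bw)
  x <- (-h):h
  exp(-x^2 / (2 * bw^2))
}

#' Simulate a DNaseI hypersensitivity track from PRO-seq signal
#'
#' The DNaseI expectation is a Gaussian-kernel smoothing (default bandwidth
#' 150 bp) of the summed-strand PRO-seq signal restricted to
#' initiation-proximal windows (pause and divergent peaks; gene bodies are
#' masked out), so hypersensitivity peaks between the divergently oriented
#' pause summits. i.i.d. Gaussian noise with `dnase_noise_sd` is added and
#' the track clamped at zero.
#'
#' @inheritParams simulate_tracks
#' @param proseq A stranded [signal_track()] simulated from the same truth.
#' @return List with `track` (unstranded [signal_track()]) and `expectation`
#'   (per-base numeric vector, noise-free).
#' @export
simulate_dnase <- function(truth, params, proseq) {
  p <- params
  chrom <- names(truth$chrom_sizes)[1]
  n <- truth$chrom_sizes[[1]]
  mask <- logical(n)
  mark <- function(g0, g1) {
    g0 <- max(g0, 0); g1 <- min(g1, n)
    if (g1 > g0) mask[(g0 + 1):g1] <<- TRUE
  }
  for (i in seq_len(nrow(truth$genes))) {
    g <- truth$genes[i, ]
    gg <- rel_to_genomic(g$tss, g$strand, -(g$div_offset + p$pause_width + 40),
                         g$pause_offset_nhs + p$pause_width + 40)
    mark(gg[1], gg[2])
  }
  for (i in seq_len(nrow(truth$dtres))) {
    d <- truth$dtres[i, ]
    mark(d$start - 100, d$end + 100)
  }
  raw <- (proseq$plus[[chrom]] + proseq$minus[[chrom]]) * mask
  kern <- gaussian_kernel(p$dnase_bandwidth)
  h <- (length(kern) - 1) / 2
  expectation <- numeric(n)
  # convolve only around masked segments (signal is sparse)
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (j in which(r$values)) {
    a <- max(1, starts[j] - 4 * h); b <- min(n, ends[j] + 4 * h)
    seg <- raw[a:b]
    sm <- stats::convolve(seg, rev(kern), type = "open")
    sm <- sm[(h + 1):(h + length(seg))]
    expectation[a:b] <- pmax(expectation[a:b], sm)
  }
  withr::with_seed(derive_seed(p$seed, 3L), {
    noisy <- if (p$dnase_noise_sd > 0) {
      pmax(expectation + rnorm(n, 0, p$dnase_noise_sd), 0)
    } else expectation
    list(track = signal_track(setNames(list(noisy), chrom), NULL,
                              sample = "DNaseI"),
         expectation = expectation)
  })
}

#' Simulate chromosome sequence with class-dependent composition
#'
#' The background is i.i.d. with GC = `gc_background`; 1-kb windows centered
#' on promoter TSSs and dTRE midpoints are first-order Markov chains whose
#' stationary GC matches the class mean and whose CpG dinucleotide rate
#' matches the class rate.
#'
#' @inheritParams simulate_tracks
#' @param window Width of the element-composition window, bp.
#' @return A [Biostrings::DNAStringSet] with one sequence per chromosome.
#' @export
simulate_sequences <- function(truth, params, window = 1000) {
  p <- params
  chrom <- names(truth$chrom_sizes)[1]
  n <- truth$chrom_sizes[[1]]
  withr::with_seed(derive_seed(p$seed, 4L), {
    base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                                 G = gc / 2, T = (1 - gc) / 2)
    seqv <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = base_probs(p$gc_background))
    markov_seg <- function(len, gc, cpg) {
      pb <- base_probs(gc)
      trans <- rbind(A = pb, C = pb, G = pb, T = pb)
      if (pb[["C"]] > 0) {
        pg_c <- min(0.95, cpg / pb[["C"]])
        rest <- trans["C", c("A", "C", "T")]
        trans["C", c("A", "C", "T")] <-
          if (sum(rest) > 0) rest / sum(rest) * (1 - pg_c) else (1 - pg_c) / 3
        trans["C", "G"] <- pg_c
      }
      bases <- c("A", "C", "G", "T")
      out <- character(len)
      out[1] <- sample(bases, 1, prob = pb)
      u <- runif(len)
      cdf <- t(apply(trans, 1, cumsum))
      for (i in 2:len) {
        out[i] <- bases[findInterval(u[i], cdf[out[i - 1], ]) + 1]
      }
      out
    }
    put <- function(center, gc, cpg) {
      a <- max(1, center - window %/% 2 + 1)
      b <- min(n, a + window - 1)
      seqv[a:b] <<- markov_seg(b - a + 1, gc, cpg)
    }
    for (i in seq_len(nrow(truth$genes))) {
      put(truth$genes$tss[i], p$gc_promoter, p$cpg_promoter)
    }
    for (i in seq_len(nrow(truth$dtres))) {
      put(truth$dtres$mid[i], p$gc_dtre, p$cpg_dtre)
    }
    Biostrings::DNAStringSet(setNames(paste(seqv, collapse = ""), chrom))
  })
}

#' Simulate transcription-factor peak calls over truth elements
#'
#' Places peaks at a configurable mix of promoters (summit uniform in
#' −300..+50 of the TSS), dTREs (summit at the element midpoint plus Gaussian
#' jitter) and untranscribed sites, and records the truth category.
#'
#' @inheritParams simulate_tracks
#' @param n Number of peaks.
#' @param mix Length-3 probabilities for (promoter, dtre, untranscribed).
#' @param jitter SD (bp) of the summit jitter at dTREs.
#' @return Tibble with `chrom, start, end, name, score, strand, summit,
#'   raw_intensity, category, element_id`.
#' @export
simulate_factor_peaks <- function(truth, params, n = 120,
                                  mix = c(0.31, 0.29, 0.40), jitter = 20) {
  stopifnot(length(mix) == 3, all(mix >= 0), sum(mix) > 0)
  p <- params
  chrom <- names(truth$chrom_sizes)[1]
  withr::with_seed(derive_seed(p$seed, 5L), {
    cat3 <- sample(c("promoter", "dtre", "untranscribed"), n, replace = TRUE,
                   prob = mix / sum(mix))
    width <- round(runif(n, 200, 400))
    summit <- integer(n); elem <- character(n)
    for (i in seq_len(n)) {
      if (cat3[i] == "promoter") {
        g <- truth$genes[sample(nrow(truth$genes), 1), ]
        rel <- round(runif(1, -300, 50))
        summit[i] <- g$tss + (if (g$strand == "+") rel else -rel)
        elem[i] <- g$gene_id
      } else if (cat3[i] == "dtre") {
        d <- truth$dtres[sample(nrow(truth$dtres), 1), ]
        summit[i] <- d$mid + (if (jitter > 0) round(rnorm(1, 0, jitter)) else 0L)
        elem[i] <- d$dtre_id
      } else {
        u <- truth$untranscribed[sample(nrow(truth$untranscribed), 1), ]
        summit[i] <- round(runif(1, u$start + 50, u$end - 50))
        elem[i] <- u$site_id
      }
    }
    tibble(
      chrom = chrom,
      start = pmax(0L, as.integer(summit - width %/% 2)),
      end = as.integer(summit + width %/% 2),
      name = sprintf("peak%04d", seq_len(n)),
      score = 0, strand = ".",
      summit = as.integer(summit),
      raw_intensity = stats::rlnorm(n, log(10), 0.8),
      category = cat3, element_id = elem
    )
  })
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper: genome truth, two conditions x `n_reps` replicate
#' PRO-seq tracks, a DNaseI track, sequences and factor peaks.
#'
#' @inheritParams simulate_tracks
#' @param n_reps Replicates per condition.
#' @param hs_depth Global depth factor injected into the HS tracks.
#' @param sequences,factor_peaks,dnase Logical switches to skip the heavier
#'   simulators.
#' @return List with `truth`, `params`, `tracks` (nested by condition then
#'   replicate), and optionally `dnase`, `sequences`, `factor_peaks`.
#' @export
simulate_experiment <- function(params = sim_params(), n_reps = 2,
                                hs_depth = 1, dnase = TRUE, sequences = TRUE,
                                factor_peaks = TRUE) {
  truth <- generate_genome(params)
  tracks <- list(
    NHS = lapply(seq_len(n_reps), function(r)
      simulate_tracks(truth, params, "NHS", r)),
    HS = lapply(seq_len(n_reps), function(r)
      simulate_tracks(truth, params, "HS", r, depth = hs_depth))
  )
  out <- list(truth = truth, params = params, tracks = tracks)
  if (dnase) out$dnase <- simulate_dnase(truth, params, tracks$NHS[[1]])
  if (sequences) out$sequences <- simulate_sequences(truth, params)
  if (factor_peaks) out$factor_peaks <- simulate_factor_peaks(truth, params)
  out
}

#' Write a simulated experiment to plain-text files
#'
#' Emits per-strand bedGraphs for every track, a gene TSV, BED6 for dTREs and
#' untranscribed sites, narrowPeak for factor peaks, FASTA, chrom.sizes, and
#' the truth tables as TSV.
#'
#' @param sim A [simulate_experiment()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  for (cond in names(sim$tracks)) {
    for (r in seq_along(sim$tracks[[cond]])) {
      tr <- sim$tracks[[cond]][[r]]
      write_bedgraph(tr, fp(sprintf("%s_rep%d_plus.bedGraph", cond, r)), "+")
      write_bedgraph(tr, fp(sprintf("%s_rep%d_minus.bedGraph", cond, r)), "-")
    }
  }
  readr::write_tsv(sim$truth$genes, fp("genes.tsv"))
  readr::write_tsv(sim$truth$candidates, fp("candidates.tsv"))
  write_bed(sim$truth$dtres %>%
              mutate(name = .data$dtre_id, score = 0, strand = "."),
            fp("dtres.bed"))
  write_bed(sim$truth$untranscribed %>%
              mutate(name = .data$site_id, score = 0, strand = "."),
            fp("untranscribed.bed"))
  if (!is.null(sim$dnase)) {
    write_bedgraph(sim$dnase$track, fp("dnase.bedGraph"), ".")
  }
  if (!is.null(sim$sequences)) {
    Biostrings::writeXStringSet(sim$sequences, fp("genome.fa"))
  }
  if (!is.null(sim$factor_peaks)) {
    write_bed(sim$factor_peaks, fp("factor_peaks.narrowPeak"), narrowpeak = TRUE)
    readr::write_tsv(sim$factor_peaks, fp("factor_peaks_truth.tsv"))
  }
  writeLines(sprintf("%s\t%d", names(sim$truth$chrom_sizes),
                     sim$truth$chrom_sizes), fp("chrom.sizes"))
  invisible(outdir)
}
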