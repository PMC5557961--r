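# Shared fixtures built in code. The small simulation is computed lazily and
# cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

small_params <- function(seed = 11, ...) {
  sim_params(n_genes = 40, n_dtres = 16, n_untranscribed_sites = 8,
             chrom_length = 2e6, seed = seed, ...)
}

get_small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_experiment(small_params())
  }
  .fixtures$sim
}

# random stranded toy track over one short chromosome
toy_track <- function(len = 5000, seed = 1, lambda = 0.2, chrom = "chrT") {
  withr::with_seed(seed, {
    signal_track(setNames(list(rpois(len, lambda)), chrom),
                 setNames(list(rpois(len, lambda)), chrom))
  })
}

# track with given per-base vectors
vec_track <- function(plus, minus = NULL, chrom = "chrT") {
  signal_track(setNames(list(plus), chrom),
               if (!is.null(minus)) setNames(list(minus), chrom))
}

# brute-force per-base window sum in the relative frame (independent oracle:
# walks bases one by one, no cumsum / vector tricks)
bf_rel_sum <- function(track, chrom, anchor, strand, a, b, strand_mode) {
  phys <- switch(strand_mode,
                 sense = strand,
                 antisense = if (strand == "-") "+" else "-",
                 both = "both", unstranded = ".")
  tot <- 0
  for (r in a:(b - 1)) {
    g <- if (strand == "-") anchor - r else anchor + r
    tot <- tot + if (identical(phys, "both")) {
      track$plus[[chrom]][g + 1] + track$minus[[chrom]][g + 1]
    } else if (phys == "-") {
      track$minus[[chrom]][g + 1]
    } else {
      track$plus[[chrom]][g + 1]
    }
  }
  tot
}

# brute-force max-window scan: enumerate every placement
bf_max_window <- function(track, chrom, anchor, strand, a, b, w, strand_mode) {
  offs <- a:(b - w)
  sums <- vapply(offs, function(o)
    bf_rel_sum(track, chrom, anchor, strand, o, o + w, strand_mode),
    numeric(1))
  i <- which.max(sums)
  list(offset = offs[i], count = sums[i])
}
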