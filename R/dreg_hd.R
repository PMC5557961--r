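#' PRO-seq feature vector around a genomic position
#'
#' log1p-transformed per-strand counts in `2 * n_windows + 1` non-overlapping
#' windows of `window_size` bp tiled 5'→3' around the position (the center
#' window straddles it). Plus-strand windows come first, then minus-strand.
#'
#' @param track A stranded [signal_track()].
#' @param chrom,position Anchor (0-based).
#' @param window_size Window width, bp.
#' @param n_windows Windows on each side of the center window.
#' @param log1p Transform counts with `log1p` (default TRUE).
#' @return Numeric vector of length `2 * (2 * n_windows + 1)`.
#' @export
extract_features <- function(track, chrom, position, window_size = 50,
                             n_windows = 10, log1p = TRUE) {
  half <- window_size %/% 2
  a <- -half - n_windows * window_size
  b <- a + (2 * n_windows + 1) * window_size
  wsum <- function(strand_mode) {
    v <- rel_values(track, chrom, position, "+", a, b, strand_mode)
    as.numeric(colSums(matrix(v, nrow = window_size)))
  }
  f <- c(wsum("sense"), wsum("antisense"))
  if (log1p) log1p(f) else f
}

#' Sample training positions within candidate regions
#'
#' Draws positions uniformly within broad candidate TRE regions extended by
#' `extend` bp on either side, the site pool the imputation model trains on.
#'
#' @param candidates Tibble `chrom, start, end`.
#' @param n Number of positions.
#' @param extend Extension on each side, bp.
#' @param seed Seed for the draw.
#' @return Tibble `chrom, pos`.
#' @export
sample_candidate_positions <- function(candidates, n, extend = 200, seed = 1L) {
  withr::with_seed(seed, {
    lens <- candidates$end - candidates$start + 2 * extend
    i <- sample(nrow(candidates), n, replace = TRUE, prob = lens)
    tibble(chrom = candidates$chrom[i],
           pos = floor(runif(n, candidates$start[i] - extend,
                             candidates$end[i] + extend)))
  })
}

feature_matrix <- function(track, chrom, positions, window_size = 50,
                           n_windows = 10, log1p = TRUE) {
  t(vapply(positions, function(p)
    extract_features(track, chrom, p, window_size, n_windows, log1p),
    numeric(2 * (2 * n_windows + 1))))
}

#' Train an SVR imputing DNaseI hypersensitivity from PRO-seq
#'
#' Epsilon-support-vector regression with a Gaussian kernel, trained on
#' PRO-seq feature vectors at positions sampled within broad candidate TRE
#' regions (extended 200 bp each side) against the DNaseI signal there.
#' The free parameters (kernel gamma, cost C, epsilon) are selected on a
#' small log-spaced grid by Pearson correlation on a holdout split not used
#' in training.
#'
#' @param features Numeric matrix, sites x features ([extract_features()]).
#' @param targets DNaseI values at the same sites.
#' @param holdout_frac Fraction of sites held out for model selection.
#' @param gamma_mult,cost_grid,epsilon_grid Hyperparameter grids; `gamma`
#'   is `gamma_mult / ncol(features)`.
#' @param log1p_targets Train on `log1p(targets)` (default TRUE; predictions
#'   are mapped back).
#' @param seed Seed for the holdout split.
#' @return An `svr_model`; see [glance.svr_model()].
#' @export
train_svr <- function(features, targets, holdout_frac = 0.25,
                      gamma_mult = c(0.25, 1, 4), cost_grid = c(0.3, 1, 10),
                      epsilon_grid = c(0.01, 0.1), log1p_targets = TRUE,
                      seed = 1L) {
  stopifnot(nrow(features) == length(targets))
  if (nrow(features) < 200) abort("train_svr needs at least 200 training sites")
  if (stats::sd(targets) == 0) abort("degenerate targets: zero variance")
  y <- if (log1p_targets) log1p(targets) else targets
  withr::with_seed(seed, {
    n <- nrow(features)
    ho <- sample(n, max(2, round(holdout_frac * n)))
    grid <- tidyr::expand_grid(gamma = gamma_mult / ncol(features),
                               cost = cost_grid, epsilon = epsilon_grid)
    grid$r <- map_dbl(seq_len(nrow(grid)), function(i) {
      fit <- e1071::svm(features[-ho, , drop = FALSE], y[-ho],
                        type = "eps-regression", kernel = "radial",
                        gamma = grid$gamma[i], cost = grid$cost[i],
                        epsilon = grid$epsilon[i], scale = FALSE)
      suppressWarnings(cor(predict(fit, features[ho, , drop = FALSE]), y[ho]))
    })
    grid$r[is.na(grid$r)] <- -Inf
    best <- grid[which.max(grid$r), ]
    fit <- e1071::svm(features[-ho, , drop = FALSE], y[-ho],
                      type = "eps-regression", kernel = "radial",
                      gamma = best$gamma, cost = best$cost,
                      epsilon = best$epsilon, scale = FALSE)
    structure(list(fit = fit, gamma = best$gamma, cost = best$cost,
                   epsilon = best$epsilon, holdout_r = best$r,
                   grid = grid, log1p_targets = log1p_targets),
              class = "svr_model")
  })
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("<svr_model> gamma=%.4g cost=%.4g epsilon=%.4g, holdout r=%.3f\n",
              x$gamma, x$cost, x$epsilon, x$holdout_r))
  invisible(x)
}

#' @rdname train_svr
#' @param x An `svr_model`.
#' @param ... Unused.
#' @export
glance.svr_model <- function(x, ...) {
  tibble(gamma = x$gamma, cost = x$cost, epsilon = x$epsilon,
         holdout_r = x$holdout_r, n_support = nrow(x$fit$SV))
}

predict_svr <- function(model, features) {
  p <- as.numeric(predict(model$fit, features))
  if (model$log1p_targets) expm1(p) else p
}

#' Impute a DNaseI profile across a region
#'
#' Predicts the imputed hypersensitivity every `step` bp across a candidate
#' region extended `extend` bp on each side.
#'
#' @param model An [train_svr()] model.
#' @param track The stranded PRO-seq [signal_track()].
#' @param chrom,start,end Candidate region (0-based half-open).
#' @param step Prediction spacing, bp (default 10).
#' @param extend Extension on each side, bp (default 200).
#' @param window_size,n_windows Feature layout; must match training.
#' @return Tibble `pos`, `value` (an imputed profile).
#' @export
impute_profile <- function(model, track, chrom, start, end, step = 10,
                           extend = 200, window_size = 50, n_windows = 10) {
  pos <- seq(start - extend, end + extend, by = step)
  f <- feature_matrix(track, chrom, pos, window_size, n_windows)
  tibble(pos = pos, value = predict_svr(model, f))
}

#' Call peaks in an imputed profile by spline smoothing
#'
#' Fits a penalized cubic smoothing spline (penalty `lambda`) to the profile,
#' finds strict local maxima of the smoothed curve with height at least
#' `tau`, merges apexes closer than `merge_dist` (keeping the higher), and
#' reports for each peak the maximal run around the apex where the spline
#' stays above `max(tau, apex/2)`.
#'
#' @param profile Tibble `pos`, `value` from [impute_profile()].
#' @param lambda Spline smoothing penalty (on the unit-scaled abscissa).
#' @param tau Intensity threshold for calling a peak.
#' @param merge_dist Minimum apex separation, bp.
#' @return Tibble `start, end, apex, apex_value` (possibly empty).
#' @export
call_peaks <- function(profile, lambda = 1e-5, tau = 0, merge_dist = 150) {
  empty <- tibble(start = numeric(0), end = numeric(0),
                  apex = numeric(0), apex_value = numeric(0))
  if (nrow(profile) < 7) abort("profile too short for peak calling (< 7 points)")
  if (length(unique(profile$value)) == 1) return(empty)
  sp <- smooth.spline(profile$pos, profile$value, lambda = lambda,
                      keep.data = FALSE, cv = NA)
  s <- predict(sp, profile$pos)$y
  n <- length(s)
  is_max <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] > s[3:n], FALSE)
  apex_i <- which(is_max & s >= tau)
  if (!length(apex_i)) return(empty)
  # merge apexes closer than merge_dist, keeping the higher
  ord <- apex_i[order(-s[apex_i])]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(profile$pos[kept] - profile$pos[i]) >= merge_dist)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  bind_rows(lapply(kept, function(i) {
    thr <- max(tau, s[i] / 2)
    lo <- i; while (lo > 1 && s[lo - 1] >= thr) lo <- lo - 1
    hi <- i; while (hi < n && s[hi + 1] >= thr) hi <- hi + 1
    tibble(start = profile$pos[lo], end = profile$pos[hi] + 1,
           apex = profile$pos[i], apex_value = s[i])
  }))
}

match_peaks <- function(called_pos, truth_pos, radius = 150) {
  if (!length(called_pos)) {
    return(list(sensitivity = 0, fdr = NA_real_, n_called = 0L))
  }
  hit_truth <- vapply(truth_pos, function(t)
    any(abs(called_pos - t) <= radius), logical(1))
  hit_call <- vapply(called_pos, function(p)
    any(abs(truth_pos - p) <= radius), logical(1))
  list(sensitivity = mean(hit_truth), fdr = mean(!hit_call),
       n_called = length(called_pos))
}

#' Grid optimization of the spline peak-caller operating point
#'
#' Sweeps a lambda x tau grid, computing against a set of true peak
#' positions the sensitivity (fraction of true peaks with a called apex
#' within `match_radius`) and FDR (fraction of called apexes with no true
#' peak within `match_radius`), and selects the point that maximizes
#' sensitivity subject to `FDR <= fdr_cap`. If no grid point meets the cap,
#' the point with the lowest FDR (then highest sensitivity) is returned and
#' flagged.
#'
#' @param profiles List of imputed profiles ([impute_profile()]).
#' @param truth_pos True peak positions (genomic bp).
#' @param lambda_grid,tau_grid Grids; `tau_grid = NULL` uses quantiles of the
#'   pooled profile values.
#' @param fdr_cap Maximum acceptable FDR (default 0.10).
#' @param match_radius Peak-truth matching radius, bp (default 150).
#' @return An `hd_tuning` list: `params` (chosen lambda/tau), `curve`
#'   (full grid with sensitivity and FDR), `met_cap`.
#' @export
optimize_hd_params <- function(profiles, truth_pos,
                               lambda_grid = 10^seq(-6, -1, by = 1),
                               tau_grid = NULL, fdr_cap = 0.10,
                               match_radius = 150) {
  if (!length(profiles) || !length(truth_pos)) abort("empty profiles or truth")
  if (is.null(tau_grid)) {
    pooled <- unlist(lapply(profiles, `[[`, "value"))
    tau_grid <- unique(quantile(pooled, c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7)))
  }
  grid <- tidyr::expand_grid(lambda = lambda_grid, tau = tau_grid)
  res <- map(seq_len(nrow(grid)), function(i) {
    apexes <- unlist(lapply(profiles, function(pr)
      call_peaks(pr, grid$lambda[i], grid$tau[i], merge_dist = match_radius)$apex))
    match_peaks(apexes, truth_pos, match_radius)
  })
  grid$sensitivity <- map_dbl(res, "sensitivity")
  grid$fdr <- map_dbl(res, "fdr")
  grid$n_called <- map_int(res, "n_called")
  ok <- !is.na(grid$fdr) & grid$fdr <= fdr_cap
  if (any(ok)) {
    cand <- grid[ok, ]
    best <- cand[order(-cand$sensitivity, cand$fdr)[1], ]
    met <- TRUE
  } else {
    best <- grid[order(grid$fdr, -grid$sensitivity)[1], ]
    met <- FALSE
  }
  structure(list(params = best[, c("lambda", "tau")],
                 sensitivity = best$sensitivity, fdr = best$fdr,
                 curve = grid, met_cap = met),
            class = "hd_tuning")
}

#' @export
print.hd_tuning <- function(x, ...) {
  cat(sprintf("<hd_tuning> lambda=%.3g tau=%.3g: sensitivity %.3f, FDR %.3f%s\n",
              x$params$lambda, x$params$tau, x$sensitivity, x$fdr,
              if (x$met_cap) "" else " (FDR cap not met)"))
  invisible(x)
}

#' @rdname optimize_hd_params
#' @param x An `hd_tuning` object.
#' @param ... Unused.
#' @export
tidy.hd_tuning <- function(x, ...) x$curve
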