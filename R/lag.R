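#' Resample a loading curve with a natural cubic spline
#'
#' Sample-eigenvector loadings are observed at the (unified) sampling times;
#' for sub-sample lag estimation they are interpolated by a natural cubic
#' spline (second derivative zero at both ends) onto a uniform grid at high
#' resolution, 0.001 h by default.
#'
#' @param times Strictly increasing times in hours (>= 4 points).
#' @param loadings Numeric loadings, same length.
#' @param resolution Grid step in hours (default 0.001).
#' @return List with `times` (uniform grid spanning the input range),
#'   `values`, and `resolution`.
#' @export
resample_spline <- function(times, loadings, resolution = 0.001) {
  times <- as.numeric(times); loadings <- as.numeric(loadings)
  if (length(times) != length(loadings)) stop("length mismatch")
  if (length(times) < 4L) stop("need at least 4 points")
  if (any(duplicated(times))) stop("duplicate times")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  grid <- seq(times[1], times[length(times)], by = resolution)
  f <- stats::splinefun(times, loadings, method = "natural")
  list(times = grid, values = f(grid), resolution = resolution)
}

# Pearson correlation of a vs b at every integer shift in [-K, K] on a
# shared uniform grid, computed on the overlapping support only (no
# zero-padding). Cross terms for all shifts come from one FFT
# cross-correlation; means and variances over the overlap windows come from
# cumulative sums, so the whole scan is O(N log N).
xcorr_all_lags <- function(a, b, K) {
  n <- length(a)
  if (length(b) != n) stop("curves must share the grid")
  K <- min(K, n - 2L)
  nf <- stats::nextn(2L * n, 2)
  fa <- stats::fft(c(a, rep(0, nf - n)))
  fb <- stats::fft(c(b, rep(0, nf - n)))
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / nf
  # cc[1 + k mod nf] = sum_i a[i + k] * b[i]  (k = shift of a relative to b)
  shift <- (-K):K
  cross <- cc[(shift %% nf) + 1L]
  ca <- c(0, cumsum(a)); ca2 <- c(0, cumsum(a^2))
  cb <- c(0, cumsum(b)); cb2 <- c(0, cumsum(b^2))
  m <- n - abs(shift) # overlap length per shift
  # windows: k >= 0 pairs a[(k+1)..n] with b[1..(n-k)];
  #          k <  0 pairs a[1..(n+k)] with b[(-k+1)..n]
  pos <- shift >= 0L
  k <- shift
  sa <- sb <- sa2 <- sb2 <- numeric(length(shift))
  sa[pos] <- ca[n + 1L] - ca[k[pos] + 1L]
  sa2[pos] <- ca2[n + 1L] - ca2[k[pos] + 1L]
  sb[pos] <- cb[n - k[pos] + 1L]
  sb2[pos] <- cb2[n - k[pos] + 1L]
  sa[!pos] <- ca[n + k[!pos] + 1L]
  sa2[!pos] <- ca2[n + k[!pos] + 1L]
  sb[!pos] <- cb[n + 1L] - cb[-k[!pos] + 1L]
  sb2[!pos] <- cb2[n + 1L] - cb2[-k[!pos] + 1L]
  va <- sa2 - sa^2 / m
  vb <- sb2 - sb^2 / m
  num <- cross - sa * sb / m
  denom <- sqrt(pmax(va, 0) * pmax(vb, 0))
  rho <- ifelse(denom > 1e-14 * pmax(sa2, sb2, 1), num / denom, NA_real_)
  list(shift = shift, rho = rho, overlap = m)
}

#' Lag of maximum cross-correlation between two dense curves
#'
#' One curve is shifted relative to the other over every lag on the
#' resolution grid within `[-max_lag, +max_lag]`; at each lag the Pearson
#' correlation is computed on the overlapping support (no zero-padding, so
#' short overlaps are not biased toward zero). The returned lag is positive
#' when `a` runs later than `b` (a(t) matches b(t - lag)). Among ties within
#' 1e-9 of the maximum, the smallest |lag| wins, then the negative one.
#'
#' @param a,b Dense curves from [resample_spline()] on the same resolution.
#' @param max_lag Maximum |lag| scanned, hours.
#' @param min_overlap_frac Minimum overlap as a fraction of the shorter
#'   curve for a lag to be admissible (default 0.5).
#' @return List with `lag` (hours), `rho` (correlation at the optimum) and
#'   the full `scan` (data.frame lag/rho).
#' @export
xcorr_lag <- function(a, b, max_lag, min_overlap_frac = 0.5) {
  if (abs(a$resolution - b$resolution) > 1e-12)
    stop("curves must share a resolution")
  res <- a$resolution
  # place both on a common origin: shift counts grid steps between series
  # starts plus the scanned offset
  if (abs(a$times[1] - b$times[1]) > 1e-9) {
    # align starts by trimming the earlier curve
    off <- round((b$times[1] - a$times[1]) / res)
    if (off > 0) { a <- trim_curve(a, off); } else if (off < 0) b <- trim_curve(b, -off)
  }
  n <- min(length(a$values), length(b$values))
  av <- a$values[seq_len(n)]; bv <- b$values[seq_len(n)]
  K <- as.integer(round(max_lag / res))
  sc <- xcorr_all_lags(av, bv, K)
  ok <- !is.na(sc$rho) & sc$overlap >= min_overlap_frac * n
  if (!any(ok))
    stop("no admissible lag: overlap below minimum everywhere")
  lags <- sc$shift[ok] * res
  rho <- sc$rho[ok]
  top <- max(rho)
  tie <- which(rho >= top - 1e-9)
  tie <- tie[order(abs(lags[tie]), lags[tie])]
  best <- tie[1]
  list(lag = lags[best], rho = rho[best],
       scan = data.frame(lag = lags, rho = rho))
}

# Orientation matching for sign-ambiguous eigenvector series. Because
# eigenvector signs are arbitrary, the scan is evaluated for both
# orientations of the query (flipping only negates every correlation, so a
# single scan serves both). Within each orientation the optimum follows the
# exact argmax rule of xcorr_lag. Across the two orientation candidates the
# larger peak correlation wins, unless the peaks differ by no more than
# `rho_tie`, in which case the smaller |lag| does: for near-sinusoidal
# loading curves a sign flip is almost equivalent to a half-period shift,
# so the flipped alias of a small true lag is a competing near-tie at a
# large lag, and resolving the ambiguity toward the smallest shift matches
# the convention the half-period scan window already embodies.
oriented_xcorr_lag <- function(a, b, max_lag, rho_tie = 0.05) {
  r <- xcorr_lag(a, b, max_lag)
  sc <- r$scan
  pick <- function(rho) {
    top <- max(rho)
    cand <- which(rho >= top - 1e-9)
    cand[order(abs(sc$lag[cand]), sc$lag[cand])][1]
  }
  ip <- pick(sc$rho)
  im <- pick(-sc$rho)
  amp_p <- sc$rho[ip]          # peak correlation, query as-is
  amp_m <- -sc$rho[im]         # peak correlation, query negated
  use_minus <- if (abs(amp_p - amp_m) <= rho_tie)
    abs(sc$lag[im]) < abs(sc$lag[ip]) ||
      (abs(sc$lag[im]) == abs(sc$lag[ip]) && sc$lag[im] < sc$lag[ip])
  else amp_m > amp_p
  if (use_minus)
    list(lag = sc$lag[im], rho = amp_m, flipped = TRUE)
  else
    list(lag = sc$lag[ip], rho = amp_p, flipped = FALSE)
}

trim_curve <- function(x, k) {
  list(times = x$times[-seq_len(k)], values = x$values[-seq_len(k)],
       resolution = x$resolution)
}

# Loading series of both datasets for the requested levels, on mapped
# times, with (optional) cross-dataset orientation matching. Eigenvector
# SIGNS are always arbitrary; beyond that, noise rotates each dataset's
# (v_1, v_2) pair within its own eigen-subspace, which for quadrature-like
# temporal patterns acts as a common time shift of both levels — the
# dominant error of a per-level lag estimator. Because the corresponding
# molecule-eigenvectors carry the same rotation and no time information,
# the relative orientation of the two datasets is estimable from the
# common molecules: an orthogonal Procrustes fit of dataset 1's
# [u_1, u_2] onto dataset 2's (reflections allowed, absorbing sign flips)
# gives the rotation applied to dataset 1's sample-loading pair.
pair_loading_series <- function(dec1, dec2, timeline1, timeline2, levels,
                                match_rotation = TRUE) {
  t1 <- mapped_times(dec1, timeline1)
  t2 <- mapped_times(dec2, timeline2)
  j1 <- level_col(dec1, levels); j2 <- level_col(dec2, levels)
  if (dec1$s < max(j1) || dec2$s < max(j2))
    stop("requested level(s) missing from a decomposition")
  Y1 <- dec1$v[, j1, drop = FALSE]
  Y2 <- dec2$v[, j2, drop = FALSE]
  rotated <- FALSE
  if (match_rotation && length(levels) > 1L) {
    common <- intersect(dec1$molecule_ids, dec2$molecule_ids)
    if (length(common) >= 2L * length(levels)) {
      M <- crossprod(dec1$u[match(common, dec1$molecule_ids), j1, drop = FALSE],
                     dec2$u[match(common, dec2$molecule_ids), j2, drop = FALSE])
      sv <- svd(M)
      Y1 <- Y1 %*% (sv$u %*% t(sv$v))
      rotated <- TRUE
    }
  }
  list(t1 = t1, t2 = t2, Y1 = Y1, Y2 = Y2, rotated = rotated)
}

#' Estimate the time lag between two datasets' eigen-levels
#'
#' For each requested level the two sample-eigenvector loading series (on
#' the unified timeline) are spline-resampled and the lag of maximum
#' cross-correlation is found, after orientation matching. Orientation
#' matching has two layers: when both datasets cover the same molecules and
#' more than one level is requested, the relative orientation of the two
#' eigen-level pairs is first estimated from the molecule-eigenvectors
#' (orthogonal Procrustes over common molecules) and applied to dataset 1's
#' loading pair — this cancels the noise-induced within-subspace rotation
#' that otherwise shifts both levels' apparent timing in common; then any
#' residual sign ambiguity per level is resolved by scanning both
#' orientations, the larger peak correlation winning unless the peaks are
#' near-tied, in which case the smaller |lag| does. The "averaged" lag is
#' the unweighted mean of the per-level lags. Positive lag means dataset 1
#' runs later than dataset 2.
#'
#' @param dec1,dec2 `eigen_decomposition` objects.
#' @param timeline1,timeline2 `unified_timeline`s mapping each dataset's
#'   sample times onto the shared reference clock; `NULL` means the times
#'   are already on it.
#' @param levels Integer levels to use (default `c(1, 2)`).
#' @param resolution Spline grid step, hours (default 0.001).
#' @param max_lag Maximum |lag| scanned, hours; default a quarter of the
#'   shorter spanned range (supply the half-period for periodic data).
#' @param match_rotation Apply the Procrustes orientation matching when
#'   possible (default TRUE).
#' @return An object of class `lag_estimate`: list with `pair`, `per_level`
#'   (data.frame level/lag/rho/flipped), `lag` (averaged), `rho` (mean
#'   |rho*|), `levels`, `resolution`, `max_lag`, `rotation_matched`.
#' @export
estimate_pair_lag <- function(dec1, dec2, timeline1 = NULL, timeline2 = NULL,
                              levels = c(1L, 2L), resolution = 0.001,
                              max_lag = NULL, match_rotation = TRUE) {
  stopifnot(inherits(dec1, "eigen_decomposition"),
            inherits(dec2, "eigen_decomposition"))
  ser <- pair_loading_series(dec1, dec2, timeline1, timeline2, levels,
                             match_rotation)
  if (is.null(max_lag)) {
    span <- min(diff(range(ser$t1)), diff(range(ser$t2)))
    max_lag <- span / 4
  }
  per <- lapply(seq_along(levels), function(li) {
    a <- resample_spline(ser$t1, ser$Y1[, li], resolution)
    b <- resample_spline(ser$t2, ser$Y2[, li], resolution)
    r <- oriented_xcorr_lag(a, b, max_lag)
    data.frame(level = levels[li], lag = r$lag, rho = r$rho,
               flipped = r$flipped)
  })
  per <- do.call(rbind, per)
  structure(list(pair = c(dec1$omics_label, dec2$omics_label),
                 per_level = per, lag = mean(per$lag),
                 rho = mean(abs(per$rho)), levels = levels,
                 resolution = resolution, max_lag = max_lag,
                 rotation_matched = ser$rotated),
            class = "lag_estimate")
}

mapped_times <- function(dec, timeline) {
  if (is.null(timeline)) return(dec$sample_times)
  stopifnot(inherits(timeline, "unified_timeline"))
  m <- timeline$map
  tt <- stats::approx(m$original_time_h, m$mapped_time_h,
                      xout = dec$sample_times, rule = 2)$y
  # warp flats can tie consecutive mapped times; spread such samples by a
  # lag-grid-scale spacing so the interpolating spline stays well behaved
  for (i in seq_along(tt)[-1])
    if (tt[i] <= tt[i - 1] + 1e-4) tt[i] <- tt[i - 1] + 1e-3
  tt
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("<lag_estimate> %s vs %s: lag = %.4f h (%.2f min), mean |rho*| = %.3f\n",
              x$pair[1], x$pair[2], x$lag, 60 * x$lag, x$rho))
  print(x$per_level, row.names = FALSE)
  if (!is.null(x$ci))
    cat(sprintf("  95%% perturbation CI: [%.4f, %.4f] h (R = %d)\n",
                x$ci[1], x$ci[2], x$n_perturbations))
  invisible(x)
}

#' Perturbation confidence interval for an inter-dataset lag
#'
#' Robustness of the lag estimate is assessed by adding independent Gaussian
#' perturbations to both loading series — standard deviation equal to
#' `fraction` (default 10%) of each series' own standard deviation — and
#' re-estimating the lag `R` times. The interval is the 2.5/97.5 percentile
#' range of the replicate averaged lags. Deterministic under a fixed seed.
#'
#' @inheritParams estimate_pair_lag
#' @param R Number of perturbation replicates (>= 100).
#' @param fraction Perturbation sd as a fraction of the data sd (default 0.1).
#' @param seed Integer seed.
#' @return A `lag_estimate` with extra elements `ci` (length-2 numeric),
#'   `replicate_lags`, `n_perturbations`, `perturb_fraction`.
#' @export
lag_ci <- function(dec1, dec2, timeline1 = NULL, timeline2 = NULL,
                   levels = c(1L, 2L), R = 1000, fraction = 0.10,
                   seed = 1, resolution = 0.001, max_lag = NULL,
                   match_rotation = TRUE) {
  if (R < 100) stop("R must be >= 100")
  point <- estimate_pair_lag(dec1, dec2, timeline1, timeline2, levels,
                             resolution, max_lag, match_rotation)
  if (is.null(max_lag)) max_lag <- point$max_lag
  ser <- pair_loading_series(dec1, dec2, timeline1, timeline2, levels,
                             match_rotation)
  s1 <- apply(ser$Y1, 2, stats::sd)
  s2 <- apply(ser$Y2, 2, stats::sd)
  set.seed(seed)
  reps <- numeric(R)
  failed <- 0L
  for (r in seq_len(R)) {
    lags <- vapply(seq_along(levels), function(li) {
      y1 <- ser$Y1[, li] + stats::rnorm(length(ser$t1), 0, fraction * s1[li])
      y2 <- ser$Y2[, li] + stats::rnorm(length(ser$t2), 0, fraction * s2[li])
      a <- resample_spline(ser$t1, y1, resolution)
      b <- resample_spline(ser$t2, y2, resolution)
      r <- tryCatch(oriented_xcorr_lag(a, b, max_lag),
                    error = function(e) NULL)
      if (is.null(r)) NA_real_ else r$lag
    }, numeric(1))
    if (any(is.na(lags))) { reps[r] <- NA_real_; failed <- failed + 1L }
    else reps[r] <- mean(lags)
  }
  if (failed > 0.2 * R)
    stop("more than 20% of perturbation replicates failed")
  reps_ok <- reps[!is.na(reps)]
  ci <- unname(stats::quantile(reps_ok, c(0.025, 0.975), type = 7))
  out <- point
  out$ci <- ci
  out$replicate_lags <- reps_ok
  out$n_perturbations <- as.integer(R)
  out$perturb_fraction <- fraction
  out
}
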