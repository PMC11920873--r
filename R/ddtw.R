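#' Local derivative estimate for derivative dynamic time warping
#'
#' The interior estimate at point i is
#' `d_i = ((x_i - x_{i-1}) + (x_{i+1} - x_{i-1}) / 2) / 2`
#' on the index scale — the average of the left difference and the centred
#' half-difference, which is exact for affine series. Endpoints copy their
#' adjacent interior estimate.
#'
#' @param curve An [indicator_curve()] or numeric vector (length >= 3).
#' @return Numeric vector of derivative estimates, same length as input.
#' @export
ddtw_derivative <- function(curve) {
  x <- if (inherits(curve, "indicator_curve")) curve$values else as.numeric(curve)
  n <- length(x)
  if (n < 3L) stop("need at least 3 points for a derivative estimate")
  i <- 2:(n - 1)
  d <- numeric(n)
  d[i] <- ((x[i] - x[i - 1]) + (x[i + 1] - x[i - 1]) / 2) / 2
  d[1] <- d[2]
  d[n] <- d[n - 1]
  d
}

#' Align two indicator curves by derivative dynamic time warping
#'
#' Dynamic-programming minimum of the summed squared derivative differences
#' over monotone warping paths with steps (1,1), (1,0), (0,1), full boundary
#' conditions (the path runs corner to corner) and no window constraint.
#' Warping raw derivatives rather than raw values makes the alignment track
#' the shape (rising/falling trend) of the curves, which is what matters
#' when two instruments record the same oscillation at different gains.
#' Ties between predecessors are broken deterministically: diagonal first,
#' then the vertical (reference) step, then the horizontal (query) step.
#'
#' @param ref,query [indicator_curve()] objects (length >= 3 each).
#' @return An object of class `warp_path`: list with `pairs` (two-column
#'   integer matrix of 1-based (ref index, query index) pairs from (1,1) to
#'   (n_ref, n_query)) and `total_cost`.
#' @export
ddtw_align <- function(ref, query) {
  dr <- ddtw_derivative(ref)
  dq <- ddtw_derivative(query)
  nr <- length(dr); nq <- length(dq)
  cost <- outer(dr, dq, function(a, b) (a - b)^2)
  D <- matrix(Inf, nr, nq)
  step <- matrix(NA_integer_, nr, nq) # 1 = diag, 2 = from (i-1,j), 3 = from (i,j-1)
  D[1, 1] <- cost[1, 1]
  for (i in 2:nr) { D[i, 1] <- D[i - 1, 1] + cost[i, 1]; step[i, 1] <- 2L }
  for (j in 2:nq) { D[1, j] <- D[1, j - 1] + cost[1, j]; step[1, j] <- 3L }
  for (i in 2:nr) for (j in 2:nq) {
    cand <- c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
    b <- which.min(cand) # which.min takes the first minimum: diag preferred
    D[i, j] <- cand[b] + cost[i, j]
    step[i, j] <- b
  }
  # backtrack
  i <- nr; j <- nq
  path <- list(c(i, j))
  while (i > 1L || j > 1L) {
    s <- step[i, j]
    if (is.na(s)) break
    if (s == 1L) { i <- i - 1L; j <- j - 1L }
    else if (s == 2L) i <- i - 1L
    else j <- j - 1L
    path[[length(path) + 1L]] <- c(i, j)
  }
  pairs <- do.call(rbind, rev(path))
  colnames(pairs) <- c("ref_index", "query_index")
  structure(list(pairs = pairs, total_cost = D[nr, nq]), class = "warp_path")
}

#' @export
print.warp_path <- function(x, ...) {
  cat(sprintf("<warp_path> %d pairs, total cost %.6g\n",
              nrow(x$pairs), x$total_cost))
  invisible(x)
}

#' Resample an indicator curve to a uniform time grid
#'
#' DDTW derivatives are computed on the index scale, so near-uniform spacing
#' is assumed; digitized curves with ragged spacing are first interpolated
#' linearly onto a uniform grid at the curve's median spacing.
#'
#' @param curve An [indicator_curve()].
#' @param spacing Grid spacing in hours; default the median spacing of the
#'   input.
#' @return A new [indicator_curve()] on the uniform grid.
#' @export
resample_curve <- function(curve, spacing = NULL) {
  stopifnot(inherits(curve, "indicator_curve"))
  if (is.null(spacing)) spacing <- stats::median(diff(curve$times))
  lo <- min(curve$times); hi <- max(curve$times)
  n <- max(2L, round((hi - lo) / spacing) + 1L)
  grid <- seq(lo, hi, length.out = n) # endpoints exact
  vals <- stats::approx(curve$times, curve$values, xout = grid)$y
  indicator_curve(grid, vals, curve$dataset_label)
}

# Moving-average smoothing of the discrete warp function (reference index
# as a function of query index), with linear extension at the ends so an
# exactly linear warp (e.g. self-alignment) passes through unchanged, and
# a running-maximum pass to keep the result monotone. A warping path is a
# staircase whose deviation from the true smooth warp oscillates around
# zero on the scale of the curve's features; averaging over a window
# cancels most of that quantization and matching bias.
smooth_warp <- function(full, w) {
  n <- length(full)
  if (w <= 1L || n < 3L) return(full)
  w <- min(w, n - (1 - n %% 2)) # odd, at most n
  if (w %% 2 == 0L) w <- w - 1L
  if (w <= 1L) return(full)
  k <- (w - 1L) %/% 2L
  sl1 <- (full[min(w, n)] - full[1]) / (min(w, n) - 1)
  sl2 <- (full[n] - full[n - min(w, n) + 1]) / (min(w, n) - 1)
  padded <- c(full[1] - sl1 * (k:1), full, full[n] + sl2 * (1:k))
  sm <- as.numeric(stats::filter(padded, rep(1 / w, w)))[(k + 1):(k + n)]
  sm[1] <- full[1]
  sm[n] <- full[n]
  cummax(sm)
}

#' Map sample times through a warp path onto the reference timeline
#'
#' Each query sample time is located on the query index axis by linear
#' interpolation of the query curve's time grid, carried through the warp
#' path (when one query index is paired with several reference indices
#' their reference indices are averaged), and converted back to hours by
#' linear interpolation of the reference curve's time grid. An optional
#' moving-average window smooths the discrete warp function before
#' interpolation; see [align_to_reference()] for the rationale.
#'
#' @param path A `warp_path` from [ddtw_align()].
#' @param ref,query The [indicator_curve()]s that produced the path.
#' @param query_sample_times Sample times (hours) within the query curve's
#'   span.
#' @param dataset_label Label recorded for the mapped dataset; default the
#'   query curve's.
#' @param smooth_window Odd moving-average window (in query samples) applied
#'   to the warp function; 1 (default) uses the raw averaged path.
#' @return An object of class `unified_timeline`: data.frame `map` with
#'   columns `original_time_h`, `mapped_time_h`, plus `reference_label`.
#' @export
map_sample_times <- function(path, ref, query, query_sample_times,
                             dataset_label = query$dataset_label,
                             smooth_window = 1L) {
  stopifnot(inherits(path, "warp_path"))
  qt <- query$times; rt <- ref$times
  tol <- 1e-6 * diff(range(qt))
  out_of_span <- query_sample_times < min(qt) - tol |
    query_sample_times > max(qt) + tol
  if (any(out_of_span))
    stop("sample time(s) outside query curve span: ",
         paste(signif(query_sample_times[out_of_span], 6), collapse = ", "))
  query_sample_times <- pmin(pmax(query_sample_times, min(qt)), max(qt))
  # query time -> fractional query index (1-based)
  qidx <- stats::approx(qt, seq_along(qt), xout = query_sample_times)$y
  # per query index, average the paired reference indices
  agg <- tapply(path$pairs[, "ref_index"], path$pairs[, "query_index"], mean)
  jq <- as.numeric(names(agg))
  warp <- stats::approx(jq, as.numeric(agg), xout = seq_along(qt),
                        rule = 2)$y
  warp <- smooth_warp(warp, smooth_window)
  ridx <- stats::approx(seq_along(qt), warp, xout = qidx, rule = 2)$y
  mapped <- stats::approx(seq_along(rt), rt, xout = ridx, rule = 2)$y
  structure(list(
    map = data.frame(original_time_h = query_sample_times,
                     mapped_time_h = mapped),
    dataset_label = dataset_label,
    reference_label = ref$dataset_label),
    class = "unified_timeline")
}

#' @export
print.unified_timeline <- function(x, ...) {
  cat(sprintf("<unified_timeline> %s -> %s: %d sample times\n",
              x$dataset_label, x$reference_label, nrow(x$map)))
  invisible(x)
}

#' Identity timeline (dataset already on the reference clock)
#'
#' @param sample_times Sample times in hours.
#' @param dataset_label,reference_label Labels.
#' @return A `unified_timeline` mapping each time to itself.
#' @export
identity_timeline <- function(sample_times, dataset_label = "dataset",
                              reference_label = "reference") {
  structure(list(
    map = data.frame(original_time_h = sample_times,
                     mapped_time_h = sample_times),
    dataset_label = dataset_label, reference_label = reference_label),
    class = "unified_timeline")
}

#' Crop an indicator curve to a time window
#'
#' Corner-to-corner warping assumes both curves cover comparable spans;
#' when a reference trace covers several cycles and the query a single
#' one, the reference is cropped to the query's window first (alignment
#' of like spans, as when single-cycle datasets are aligned to
#' single-cycle references and multi-cycle to multi-cycle).
#'
#' @param curve An [indicator_curve()].
#' @param lo,hi Window bounds in hours.
#' @return The cropped [indicator_curve()].
#' @export
crop_curve <- function(curve, lo, hi) {
  keep <- curve$times >= lo - 1e-9 & curve$times <= hi + 1e-9
  indicator_curve(curve$times[keep], curve$values[keep],
                  curve$dataset_label)
}

#' Align a dataset's samples to a reference via oxygen curves
#'
#' Convenience wrapper: resample both curves to uniform grids, run
#' [ddtw_align()], then [map_sample_times()] with warp smoothing.
#'
#' Smoothing rationale: a warp path is an integer staircase, and matching
#' derivative values is locally biased wherever a clock distortion also
#' modulates the derivative's amplitude; both effects oscillate around the
#' true smooth warp on the scale of the curve's features. Averaging the
#' warp function over a short window (default 9 samples, about a sixth of
#' a cycle at the ~60-points-per-cycle digitization density of typical
#' dissolved-oxygen traces) cancels most of this error while preserving
#' smooth monotone distortions.
#'
#' @param ref_curve,query_curve [indicator_curve()]s.
#' @param query_sample_times Sample times of the query dataset (hours).
#' @param resample Resample curves to uniform grids first (default TRUE).
#' @param smooth_window Warp smoothing window, see [map_sample_times()]
#'   (default 9).
#' @return A `unified_timeline`.
#' @export
align_to_reference <- function(ref_curve, query_curve, query_sample_times,
                               resample = TRUE, smooth_window = 9L) {
  if (resample) {
    ref_curve <- resample_curve(ref_curve)
    query_curve <- resample_curve(query_curve)
  }
  path <- ddtw_align(ref_curve, query_curve)
  map_sample_times(path, ref_curve, query_curve, query_sample_times,
                   smooth_window = smooth_window)
}

#' Merge LC-MS and GC-TOF metabolome matrices on the LC-MS time points
#'
#' GC-TOF rows are linearly interpolated at the LC-MS sampling times (both
#' on the unified timeline), then the two platforms are row-stacked into a
#' single matrix at the LC-MS times. LC-MS times outside the GC-TOF span use
#' the nearest endpoint value with a warning. A metabolite present on both
#' platforms keeps its LC-MS row; the GC-TOF duplicate is dropped with a
#' warning.
#'
#' @param lcms,gctof [omics_matrix()] objects on the unified timeline.
#' @return A merged [omics_matrix()] at the LC-MS sample times.
#' @export
merge_metabolome <- function(lcms, gctof) {
  stopifnot(inherits(lcms, "omics_matrix"), inherits(gctof, "omics_matrix"))
  tt <- lcms$sample_times
  gt <- gctof$sample_times
  if (any(tt < min(gt) | tt > max(gt)))
    warning("LC-MS time(s) outside GC-TOF span: endpoint values used")
  gi <- t(apply(gctof$values, 1, function(row)
    stats::approx(gt, row, xout = tt, rule = 2)$y))
  dup <- intersect(rownames(gi), rownames(lcms$values))
  if (length(dup)) {
    warning("metabolite(s) on both platforms, LC-MS kept: ",
            paste(utils::head(dup, 10), collapse = ", "))
    gi <- gi[setdiff(rownames(gi), dup), , drop = FALSE]
  }
  vals <- rbind(lcms$values, gi)
  omics_matrix(vals, rownames(vals), colnames(lcms$values), tt,
               omics_label = lcms$omics_label,
               provenance = c(lcms$provenance,
                              list(merged_platforms = c(lcms$omics_label,
                                                        gctof$omics_label))))
}
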