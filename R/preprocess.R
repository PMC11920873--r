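#' Log2 transform with pseudocount
#'
#' Replaces every value by `log2(value + pseudocount)`. A provenance flag
#' guards against double application, which would silently change the scale
#' the downstream eigen-analysis assumes.
#'
#' @param mat An [omics_matrix()] with non-negative values.
#' @param pseudocount Non-negative offset added before the log (default 1).
#' @return The transformed [omics_matrix()].
#' @export
log_transform <- function(mat, pseudocount = 1) {
  stopifnot(inherits(mat, "omics_matrix"))
  if (isTRUE(mat$provenance$log_transformed))
    stop("matrix is already log-transformed")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(mat$values < 0)) stop("negative values: log transform undefined")
  v <- log2(mat$values + pseudocount)
  if (any(!is.finite(v)))
    stop("log transform produced non-finite values (zero with pseudocount 0?)")
  mat$values <- v
  mat$provenance$log_transformed <- TRUE
  mat$provenance$pseudocount <- pseudocount
  mat
}

# Adjusted Fisher-Pearson sample skewness, g1 * sqrt(n(n-1))/(n-2).
# Zero-variance input is degenerate: by convention contributes 0.
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- sum((x - m)^2) / n
  if (s2 < .Machine$double.eps * max(1, m^2)) return(NA_real_)
  g1 <- (sum((x - m)^3) / n) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Select the normalization reference sample
#'
#' For each sample j the score is the sum over the other samples j' of the
#' skewness of the per-molecule difference column_j - column_j'. The sample
#' with the largest total skewness is the reference; differences whose
#' skewness is undefined (constant difference vectors) contribute 0 with a
#' warning. Ties go to the earliest sample in time order.
#'
#' @param mat A log-scale [omics_matrix()].
#' @return The reference sample id (character scalar), with the score vector
#'   attached as attribute `scores`.
#' @export
select_reference_sample <- function(mat) {
  stopifnot(inherits(mat, "omics_matrix"))
  v <- mat$values
  n <- ncol(v)
  if (n < 2L) stop("need at least 2 samples")
  degenerate <- FALSE
  scores <- vapply(seq_len(n), function(j) {
    s <- vapply(seq_len(n)[-j], function(jp) {
      sk <- sample_skewness(v[, j] - v[, jp])
      if (is.na(sk)) { degenerate <<- TRUE; 0 } else sk
    }, numeric(1))
    sum(s)
  }, numeric(1))
  if (degenerate)
    warning("constant difference vector(s): skewness treated as 0")
  # ties broken by first sample in time order (columns are time-sorted)
  best <- which(scores >= max(scores) - 1e-12 * max(1, abs(max(scores))))
  ref <- colnames(v)[best[1]]
  names(scores) <- colnames(v)
  attr(ref, "scores") <- scores
  ref
}

#' Normalize samples to a reference by median of differences
#'
#' A robust per-sample location shift on the log scale: from each column j
#' the median of (column_j - column_ref) is subtracted, so the median
#' difference of every sample to the reference becomes zero and the
#' reference column itself is unchanged. The method name is recorded in the
#' provenance so a different normalizer can be plugged into the same slot.
#'
#' @param mat A log-scale [omics_matrix()].
#' @param ref Reference sample id, e.g. from [select_reference_sample()].
#' @return The normalized [omics_matrix()].
#' @export
normalize_to_reference <- function(mat, ref) {
  stopifnot(inherits(mat, "omics_matrix"))
  if (!ref %in% colnames(mat$values)) stop("unknown reference sample: ", ref)
  refcol <- mat$values[, ref]
  shifts <- apply(mat$values, 2, function(col) stats::median(col - refcol))
  mat$values <- sweep(mat$values, 2, shifts, "-")
  mat$provenance$normalization <- "median_difference_to_reference"
  mat$provenance$reference_sample <- ref
  mat$provenance$shifts <- shifts
  mat
}

#' QC: modes of pairwise difference densities
#'
#' After a successful normalization the per-molecule difference distribution
#' of every sample pair should have its density mode near zero. The mode is
#' located by a Gaussian kernel density (Silverman bandwidth) on a 512-point
#' grid spanning the data range.
#'
#' @param mat A log-scale [omics_matrix()].
#' @param tolerance Pass threshold on |mode| (default 0.1).
#' @return A data.frame with columns `sample_1`, `sample_2`, `mode`, `pass`.
#' @export
qc_pairwise_modes <- function(mat, tolerance = 0.1) {
  stopifnot(inherits(mat, "omics_matrix"))
  v <- mat$values
  if (nrow(v) < 10L)
    warning("fewer than 10 molecules: density mode estimates are unstable")
  pairs <- utils::combn(colnames(v), 2)
  modes <- apply(pairs, 2, function(p) {
    d <- v[, p[1]] - v[, p[2]]
    if (diff(range(d)) < .Machine$double.eps) return(d[1])
    den <- stats::density(d, bw = "nrd0", n = 512)
    den$x[which.max(den$y)]
  })
  data.frame(sample_1 = pairs[1, ], sample_2 = pairs[2, ],
             mode = modes, pass = abs(modes) <= tolerance,
             row.names = NULL)
}
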