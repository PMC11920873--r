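#' Gene-set enrichment of molecule loadings by rank-sum scoring
#'
#' Molecule loadings of an eigen-level are treated as a weighted
#' differential profile and each gene set is scored by a two-sample
#' Wilcoxon rank-sum test of in-set versus out-of-set loadings. The
#' statistic is reported as a signed z (positive means the set concentrates
#' at the positive pole), with one-sided p-values for each pole and
#' Benjamini-Hochberg adjustment across sets within each pole. Small,
#' tie-free comparisons (min group size <= 10) use the exact rank-sum
#' distribution; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param loadings Named numeric vector of molecule loadings (names are
#'   molecule ids).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param min_size Minimum number of set members present in the matrix for
#'   a set to be tested (default 5).
#' @param exact_max Largest min-group size for which the exact distribution
#'   is used in the absence of ties (default 10).
#' @return data.frame with columns `set_id`, `set_size`, `direction`
#'   ("positive"/"negative"), `z`, `p`, `q`; two rows per tested set.
#' @export
wilcoxon_enrich <- function(loadings, gene_sets, min_size = 5, exact_max = 10) {
  if (is.null(names(loadings))) stop("loadings must be named by molecule id")
  universe <- names(loadings)
  sizes <- vapply(gene_sets, function(g) sum(g %in% universe), integer(1))
  keep <- sizes >= min_size
  if (!any(keep)) {
    warning("no gene set has >= ", min_size, " members in the matrix")
    return(data.frame(set_id = character(), set_size = integer(),
                      direction = character(), z = numeric(),
                      p = numeric(), q = numeric()))
  }
  rows <- lapply(names(gene_sets)[keep], function(nm) {
    inset <- universe %in% gene_sets[[nm]]
    n1 <- sum(inset); n2 <- sum(!inset)
    if (n2 == 0L) {
      # empty complement: degenerate, no contrast possible
      return(data.frame(set_id = nm, set_size = n1,
                        direction = c("positive", "negative"),
                        z = 0, p = 1, stringsAsFactors = FALSE))
    }
    r <- rank(loadings)
    w <- sum(r[inset]) # rank-sum of the in-set group
    ties <- any(duplicated(loadings))
    if (!ties && min(n1, n2) <= exact_max) {
      ustat <- w - n1 * (n1 + 1) / 2
      p_pos <- stats::pwilcox(ustat - 1, n1, n2, lower.tail = FALSE)
      p_neg <- stats::pwilcox(ustat, n1, n2, lower.tail = TRUE)
      mu <- n1 * (n1 + n2 + 1) / 2
      sig <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
      z <- (w - mu) / sig
    } else {
      mu <- n1 * (n1 + n2 + 1) / 2
      ntot <- n1 + n2
      tie_tab <- table(r)
      corr <- sum(tie_tab^3 - tie_tab) / (ntot * (ntot - 1))
      sig <- sqrt(n1 * n2 / 12 * ((ntot + 1) - corr))
      z <- (w - mu) / sig
      cc <- 0.5
      p_pos <- stats::pnorm((w - mu - cc) / sig, lower.tail = FALSE)
      p_neg <- stats::pnorm((w - mu + cc) / sig, lower.tail = TRUE)
    }
    data.frame(set_id = nm, set_size = n1,
               direction = c("positive", "negative"),
               z = z, p = pmin(1, c(p_pos, p_neg)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (d in c("positive", "negative")) {
    i <- out$direction == d
    out$q[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Draw a random unit sample-vector orthogonal to the leading eigenvectors
#'
#' The marker-randomization null replaces the k-th sample-eigenvector with a
#' random unit vector constrained, like the true one, to be orthogonal to
#' all sample-eigenvectors up to and including level k. A standard normal
#' draw is projected onto that orthogonal complement and normalized;
#' numerically degenerate draws (residual norm below 1e-8) are redrawn.
#'
#' @param dec An `eigen_decomposition`.
#' @param k Level whose null is being built.
#' @param seed Optional integer seed (set once before repeated draws).
#' @return Unit numeric vector of length n.
#' @export
random_orthogonal_vector <- function(dec, k, seed = NULL) {
  stopifnot(inherits(dec, "eigen_decomposition"))
  if (!is.null(seed)) set.seed(seed)
  j <- level_col(dec, k)
  n <- nrow(dec$v)
  V <- dec$v[, seq_len(j), drop = FALSE] # v_0 (or v_1) .. v_k
  if (ncol(V) >= n) stop("no orthogonal complement: k = n - 1")
  repeat {
    x <- stats::rnorm(n)
    x <- x - V %*% crossprod(V, x)
    nx <- sqrt(sum(x^2))
    if (nx >= 1e-8) return(as.numeric(x) / nx)
  }
}

#' Marker molecules by randomization of the sample-eigenvector
#'
#' Exploits the duality lambda_k u_k = A v_k: replacing v_k by random unit
#' vectors v_k^r orthogonal to v_0..v_k yields null molecule-eigenvectors
#' u_k^r = A v_k^r / ||A v_k^r||, against which each observed loading u_ki
#' is compared. The one-sided pole p-value follows the sign of the observed
#' loading — upper tail for positive loadings, lower tail for negative —
#' with a +1 correction in numerator and denominator so p >= 1/(R+1). A
#' two-sided version `p_two = min(1, 2 p_pole)`, uniform under the null, is
#' reported alongside. Markers are molecules passing both a p threshold and
#' a loading-magnitude threshold.
#'
#' @param dec An `eigen_decomposition` (must carry its source matrix).
#' @param k Level to test.
#' @param R Number of randomizations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param p_max Marker threshold on the pole p-value (default 0.01).
#' @param u_min Marker threshold on |loading|; default the 95th percentile
#'   of the level's |loadings|.
#' @return data.frame with columns `molecule_id`, `level`, `loading`, `p`
#'   (pole p-value), `p_two`, `marker`; attributes `R`, `u_min`, `redraws`.
#' @export
marker_randomization <- function(dec, k, R = 1000, seed = 1,
                                 p_max = 0.01, u_min = NULL) {
  stopifnot(inherits(dec, "eigen_decomposition"))
  if (R < 100) stop("R must be >= 100")
  j <- level_col(dec, k)
  A <- dec$A
  u <- dec$u[, j]
  if (is.null(u_min)) u_min <- stats::quantile(abs(u), 0.95, names = FALSE)
  set.seed(seed)
  n <- nrow(dec$v)
  V <- dec$v[, seq_len(j), drop = FALSE]
  if (ncol(V) >= n) stop("no orthogonal complement: k = n - 1")
  Ur <- matrix(NA_real_, nrow(A), R)
  redraws <- 0L
  r <- 1L
  while (r <= R) {
    x <- stats::rnorm(n)
    x <- x - V %*% crossprod(V, x)
    nx <- sqrt(sum(x^2))
    if (nx < 1e-8) { redraws <- redraws + 1L; next }
    y <- A %*% (x / nx)
    ny <- sqrt(sum(y^2))
    if (ny < 1e-12) { redraws <- redraws + 1L; next }
    Ur[, r] <- y / ny
    r <- r + 1L
  }
  if (redraws > 0.01 * R)
    warning(redraws, " degenerate randomization draw(s) redrawn")
  pos <- u > 1e-12
  neg <- u < -1e-12
  count <- integer(length(u))
  count[pos] <- rowSums(Ur[pos, , drop = FALSE] >= u[pos])
  count[neg] <- rowSums(Ur[neg, , drop = FALSE] <= u[neg])
  p <- (1 + count) / (1 + R)
  p[!pos & !neg] <- 1
  p_two <- pmin(1, 2 * p)
  p_two[!pos & !neg] <- 1
  out <- data.frame(molecule_id = dec$molecule_ids, level = k,
                    loading = u, p = p, p_two = p_two,
                    marker = p <= p_max & abs(u) >= u_min,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "R") <- as.integer(R)
  attr(out, "u_min") <- u_min
  attr(out, "p_max") <- p_max
  attr(out, "redraws") <- redraws
  out
}

#' Phase-contribution decomposition of a signal matrix
#'
#' Quantifies how much a signal matrix (e.g. one histone modification)
#' contributes to each of the four transcriptomic eigen-phases. The
#' transcriptome's eigenvectors at levels 1 and 2 are split into
#' non-negative parts, `u+ = max(u, 0)` and `u- = max(-u, 0)` (likewise for
#' v), each normalized to sum 1 so it acts as a weight vector over
#' molecules or samples. After interpolating the signal matrix to the
#' transcriptomic sampling times, the contribution to phase 1A is
#' `u1+' A v1+`, to 1B `u1-' A v1-`, to 2A `u2+' A v2+` and to 2B
#' `u2-' A v2-`. The coefficient of variation (sd/mean) of the four
#' contributions measures how phase-specific the signal is.
#'
#' @param signal An [omics_matrix()] of the signal (rows intersected with
#'   the transcriptome's molecule ids; times on the unified timeline).
#' @param tdec The transcriptome `eigen_decomposition`.
#' @param transcript_times Transcriptomic sampling times (hours); default
#'   `tdec$sample_times`.
#' @return List with `contributions` (named numeric: 1A, 1B, 2A, 2B), `cv`,
#'   `n_common` (molecules used), `label`.
#' @export
phase_contributions <- function(signal, tdec,
                                transcript_times = tdec$sample_times) {
  stopifnot(inherits(signal, "omics_matrix"),
            inherits(tdec, "eigen_decomposition"))
  common <- intersect(tdec$molecule_ids, rownames(signal$values))
  if (length(common) < 2L) stop("fewer than 2 molecules in common")
  if (length(common) < length(tdec$molecule_ids))
    message(length(common), " of ", length(tdec$molecule_ids),
            " transcriptome molecules present in the signal matrix")
  # per-molecule linear interpolation to the transcriptomic time points
  st <- signal$sample_times
  S <- t(apply(signal$values[common, , drop = FALSE], 1, function(row)
    stats::approx(st, row, xout = transcript_times, rule = 2)$y))
  half <- function(x, sign) {
    h <- pmax(sign * x, 0)
    tot <- sum(h)
    if (tot <= 0) return(NULL)
    h / tot
  }
  idx <- match(common, tdec$molecule_ids)
  ju <- level_col(tdec, c(1L, 2L))
  parts <- list(
    `1A` = list(u = half(tdec$u[idx, ju[1]], 1), v = half(tdec$v[, ju[1]], 1)),
    `1B` = list(u = half(tdec$u[idx, ju[1]], -1), v = half(tdec$v[, ju[1]], -1)),
    `2A` = list(u = half(tdec$u[idx, ju[2]], 1), v = half(tdec$v[, ju[2]], 1)),
    `2B` = list(u = half(tdec$u[idx, ju[2]], -1), v = half(tdec$v[, ju[2]], -1)))
  bad <- names(parts)[vapply(parts, function(p)
    is.null(p$u) || is.null(p$v), logical(1))]
  if (length(bad))
    stop("one-signed eigenvector: no weight mass for phase(s) ",
         paste(bad, collapse = ", "))
  contrib <- vapply(parts, function(p)
    as.numeric(crossprod(p$u, S %*% p$v)), numeric(1))
  cv <- stats::sd(contrib) / mean(contrib)
  list(contributions = contrib, cv = cv, n_common = length(common),
       label = signal$omics_label)
}
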