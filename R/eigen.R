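#' Stratify an omics matrix into ranked eigen-levels by SVD
#'
#' The singular value decomposition A = sum_k lambda_k u_k v_k' splits the
#' matrix into principal eigen-components ("levels") ordered by decreasing
#' singular value. After normalization the level with the largest singular
#' value carries nearly constant sample loadings and represents the
#' per-molecule average signal; it is indexed 0 and treated as the baseline,
#' so the biologically informative levels start at k = 1.
#'
#' Sign conventions are fixed deterministically: level 0 is oriented so the
#' sum of its sample loadings is positive (baseline tracks the mean, not its
#' negation); every level k >= 1 is oriented so the skewness of its molecule
#' loadings is non-negative, falling back to making the largest-magnitude
#' molecule loading positive when the skewness is numerically zero.
#'
#' @param mat An [omics_matrix()] (or a bare numeric matrix plus
#'   `sample_times`).
#' @param sample_times Required only when `mat` is a bare matrix.
#' @param rank_tol Levels with singular value below `rank_tol * lambda_0`
#'   are discarded as numerical noise (default 1e-10).
#' @return An object of class `eigen_decomposition`: list with `lambda`
#'   (length s), `u` (m x s), `v` (n x s), `s`, `sample_times`,
#'   `omics_label`, `orientation` (the sign flips applied) and
#'   `molecule_ids`/`sample_ids`.
#' @export
stratify <- function(mat, sample_times = NULL, rank_tol = 1e-10) {
  if (inherits(mat, "omics_matrix")) {
    A <- mat$values
    sample_times <- mat$sample_times
    label <- mat$omics_label
  } else {
    A <- as.matrix(mat)
    if (is.null(sample_times)) sample_times <- seq_len(ncol(A))
    label <- "matrix"
  }
  if (any(!is.finite(A))) stop("non-finite entries in matrix")
  if (nrow(A) < 2L || ncol(A) < 3L) stop("need m >= 2 molecules, n >= 3 samples")
  sv <- svd(A)
  keep <- sv$d > rank_tol * sv$d[1]
  lambda <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  s <- length(lambda)
  flips <- rep(1, s)
  # level 0: baseline points along +1 direction of samples
  if (sum(v[, 1]) < 0) flips[1] <- -1
  if (s > 1) for (k in 2:s) {
    sk <- sample_skewness(u[, k])
    if (is.na(sk) || abs(sk) < 1e-12) {
      i <- which.max(abs(u[, k]))
      if (u[i, k] < 0) flips[k] <- -1
    } else if (sk < 0) flips[k] <- -1
  }
  u <- sweep(u, 2, flips, "*")
  v <- sweep(v, 2, flips, "*")
  rownames(u) <- rownames(A)
  rownames(v) <- colnames(A)
  structure(
    list(lambda = lambda, u = u, v = v, s = s,
         sample_times = sample_times, omics_label = label,
         orientation = flips,
         molecule_ids = rownames(A), sample_ids = colnames(A),
         A = A, index_origin = 0L),
    class = "eigen_decomposition"
  )
}

#' @export
print.eigen_decomposition <- function(x, ...) {
  cat(sprintf("<eigen_decomposition> %s: %d x %d, s = %d levels (index from %d)\n",
              x$omics_label, nrow(x$u), nrow(x$v), x$s, x$index_origin))
  k <- seq_len(min(5, x$s))
  cat("  lambda:", paste(signif(x$lambda[k], 4), collapse = ", "),
      if (x$s > 5) ", ..." else "", "\n")
  invisible(x)
}

# map a user-facing level index (starting at index_origin) to a column
level_col <- function(dec, k) {
  j <- k - dec$index_origin + 1L
  if (any(j < 1L | j > dec$s)) stop("invalid level index: ",
                                    paste(k[j < 1L | j > dec$s], collapse = ", "))
  j
}

#' Baseline diagnostics for level 0
#'
#' Checks that the top level really is a clean baseline: the coefficient of
#' variation of |v_0| should be small (sample loadings nearly identical) and
#' lambda_0 u_0 / sqrt(n) should track the row-mean vector mu.
#'
#' @param dec An `eigen_decomposition` with index origin 0.
#' @param cv_max Pass threshold on the CV of |v_0| (default 0.1).
#' @return List with `cv_v0`, `mu_max_rel_dev`, `pass`.
#' @export
baseline_diagnostics <- function(dec, cv_max = 0.1) {
  stopifnot(inherits(dec, "eigen_decomposition"))
  if (dec$index_origin != 0L) stop("decomposition has no baseline level")
  v0 <- abs(dec$v[, 1])
  cv <- stats::sd(v0) / mean(v0)
  n <- nrow(dec$v)
  mu <- rowMeans(dec$A)
  approx_mu <- dec$lambda[1] * dec$u[, 1] / sqrt(n)
  scale <- max(abs(mu), 1e-12)
  dev <- max(abs(approx_mu - mu)) / scale
  pass <- is.finite(cv) && cv <= cv_max
  if (!pass)
    warning(sprintf("level 0 is not a clean baseline (CV of |v0| = %.3g > %g)",
                    cv, cv_max))
  list(cv_v0 = cv, mu_max_rel_dev = dev, pass = pass)
}

#' Remove the baseline eigen-component
#'
#' Returns Abar = A - lambda_0 u_0 v_0', the matrix with the average level
#' removed; its squared Frobenius norm equals the sum of the remaining
#' squared singular values (the total variance).
#'
#' @param dec An `eigen_decomposition` with index origin 0.
#' @return Numeric matrix Abar with the source dimnames.
#' @export
remove_baseline <- function(dec) {
  stopifnot(inherits(dec, "eigen_decomposition"))
  if (dec$index_origin != 0L) stop("baseline already removed")
  dec$A - dec$lambda[1] * tcrossprod(dec$u[, 1], dec$v[, 1])
}

#' Relative level contributions and eigen-entropy
#'
#' The contribution of level k >= 1 is p_k = lambda_k^2 / sum_{k'>=1}
#' lambda_k'^2, the share of the total (baseline-removed) variance carried
#' by that level. The eigen-entropy is the Shannon entropy of the p_k in
#' nats; it is 0 when one level dominates completely and ln(s-1) when all
#' levels contribute equally, so a normalized variant H / ln(s-1) is also
#' reported when more than one level exists.
#'
#' @param dec An `eigen_decomposition`.
#' @return List with `ratios` (named by level index), `entropy`,
#'   `normalized_entropy` (NA when only one non-baseline level), `top2`
#'   (p_1 + p_2, NA if fewer than two levels).
#' @export
relative_contributions <- function(dec) {
  stopifnot(inherits(dec, "eigen_decomposition"))
  lam <- if (dec$index_origin == 0L) dec$lambda[-1] else dec$lambda
  if (!length(lam)) stop("no variance beyond baseline")
  p <- lam^2 / sum(lam^2)
  names(p) <- as.character(seq_along(p) + max(dec$index_origin - 1L, 0L))
  H <- eigen_entropy(p)
  list(ratios = p, entropy = H,
       normalized_entropy = if (length(p) > 1) H / log(length(p)) else NA_real_,
       top2 = if (length(p) >= 2) p[1] + p[2] else NA_real_)
}

#' Shannon entropy of a contribution distribution (nats)
#'
#' @param p Non-negative weights; normalized to sum 1 internally.
#'   The convention 0 * log(0) = 0 applies.
#' @return Entropy in nats.
#' @export
eigen_entropy <- function(p) {
  if (any(p < 0)) stop("negative weights")
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Polarize a level's loadings
#'
#' Sorts molecule and sample loadings in ascending order, exposing the
#' negative and positive poles of the eigenvector.
#'
#' @param dec An `eigen_decomposition`.
#' @param k Level index.
#' @return List of two data.frames, `molecules` and `samples`, each with
#'   columns `id`, `loading`, `rank`, `pole` ("negative"/"positive";
#'   exact zeros are tagged "zero").
#' @export
polarize <- function(dec, k) {
  stopifnot(inherits(dec, "eigen_decomposition"))
  j <- level_col(dec, k)
  tab <- function(ids, x) {
    o <- order(x)
    data.frame(id = ids[o], loading = x[o], rank = seq_along(x),
               pole = ifelse(x[o] < 0, "negative",
                             ifelse(x[o] > 0, "positive", "zero")),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(molecules = tab(dec$molecule_ids, dec$u[, j]),
       samples = tab(dec$sample_ids, dec$v[, j]))
}

#' Call the four eigen-phases from sample loading signs
#'
#' Each sample receives a level-1 label (1A when its loading v_1j is
#' positive, 1B when negative) and a level-2 label (2A / 2B likewise), so
#' the top two levels define four overlapping half-cycle eigen-phases. The
#' cyclic order of the four phases is inferred from the data: each sample's
#' phase angle is atan2(v_2j, v_1j), the traversal direction is taken from
#' the sign of the median wrapped angle step along time, and the four labels
#' are ordered by their circular mean angles in that direction, starting
#' from the label whose members occur earliest.
#'
#' @param dec An `eigen_decomposition` with at least baseline + two levels.
#' @param label_positive_pole Which pole gets the "A" label (default TRUE:
#'   A = positive pole). The pole-to-letter mapping is a presentation
#'   option; the phase structure does not depend on it.
#' @param zero_tol Loadings below this magnitude are flagged "boundary" and
#'   excluded from order inference (default 1e-12).
#' @return An object of class `phase_calls`: data.frame `calls` (sample_id,
#'   time_h, sign1, sign2, label1, label2, boundary), character vector
#'   `cyclic_order` (the four labels in cycle order), logical `degenerate`
#'   flag (duplicated midpoints), and `direction` (+1/-1 sign of time
#'   traversal in the loading plane).
#' @export
call_phases <- function(dec, label_positive_pole = TRUE, zero_tol = 1e-12) {
  stopifnot(inherits(dec, "eigen_decomposition"))
  ks <- c(1L, 2L)
  j <- level_col(dec, ks)
  if (dec$s < max(j)) stop("need at least levels 1 and 2 (s >= 3 with baseline)")
  v1 <- dec$v[, j[1]]; v2 <- dec$v[, j[2]]
  s1 <- ifelse(v1 > 0, 1L, ifelse(v1 < 0, -1L, 0L))
  s2 <- ifelse(v2 > 0, 1L, ifelse(v2 < 0, -1L, 0L))
  lab <- function(sgn, lv) {
    ab <- if (label_positive_pole) c("A", "B") else c("B", "A")
    ifelse(sgn > 0, paste0(lv, ab[1]), ifelse(sgn < 0, paste0(lv, ab[2]), NA))
  }
  boundary <- abs(v1) < zero_tol | abs(v2) < zero_tol
  calls <- data.frame(sample_id = dec$sample_ids, time_h = dec$sample_times,
                      sign1 = s1, sign2 = s2,
                      label1 = lab(s1, "1"), label2 = lab(s2, "2"),
                      boundary = boundary,
                      row.names = NULL, stringsAsFactors = FALSE)
  ok <- !boundary
  theta <- atan2(v2[ok], v1[ok])
  wrap <- function(x) atan2(sin(x), cos(x))
  dth <- wrap(diff(theta))
  direction <- if (length(dth) && sum(sign(dth)) != 0)
    sign(sum(sign(dth))) else 1
  circ_mean <- function(a) atan2(mean(sin(a)), mean(cos(a)))
  # phase-label centre angles in the loading plane
  centres <- c(
    `1` = circ_mean(theta[v1[ok] > 0]),            # level-1 positive pole at 0
    `2` = circ_mean(theta[v1[ok] < 0]),
    `3` = circ_mean(theta[v2[ok] > 0]),
    `4` = circ_mean(theta[v2[ok] < 0]))
  label_names <- c(lab(1L, "1"), lab(-1L, "1"), lab(1L, "2"), lab(-1L, "2"))
  degenerate <- any(is.na(centres)) ||
    any(duplicated(round(centres, 8)))
  if (any(is.na(centres))) {
    warning("one-signed level: cyclic order inferred from available labels")
    centres[is.na(centres)] <- 0
  }
  ang <- if (direction >= 0) centres else -centres
  o <- order(wrap(ang - ang[1]) %% (2 * pi))
  ord <- label_names[o]
  # rotate so the earliest-occurring label leads
  first_time <- vapply(ord, function(lb) {
    hit <- calls$label1 == lb | calls$label2 == lb
    if (!any(hit, na.rm = TRUE)) Inf else min(calls$time_h[which(hit)])
  }, numeric(1))
  ord <- c(ord, ord)[seq(which.min(first_time), length.out = 4)]
  if (degenerate)
    warning("duplicated or undefined phase midpoints: cyclic order is ambiguous")
  structure(list(calls = calls, cyclic_order = ord,
                 degenerate = degenerate, direction = direction),
            class = "phase_calls")
}

#' @export
print.phase_calls <- function(x, ...) {
  cat("<phase_calls>", nrow(x$calls), "samples; cyclic order:",
      paste(x$cyclic_order, collapse = " -> "), "\n")
  invisible(x)
}

#' Reconstruct a matrix from selected levels
#'
#' Computes sum_{k in keep} lambda_k u_k v_k' and the residual A minus that
#' sum. With `keep_levels = 0:2` this realizes the cyclic-signal
#' decomposition a(i, t) = mu(i) + lambda_1 u_1(i) v_1(t) +
#' lambda_2 u_2(i) v_2(t) + epsilon(i, t) at the sampled times.
#'
#' @param dec An `eigen_decomposition`.
#' @param keep_levels Integer level indices to retain (may be empty).
#' @return List with `reconstruction` and `residual` matrices.
#' @export
reconstruct <- function(dec, keep_levels) {
  stopifnot(inherits(dec, "eigen_decomposition"))
  if (length(keep_levels)) {
    j <- level_col(dec, as.integer(keep_levels))
    rec <- dec$u[, j, drop = FALSE] %*%
      (dec$lambda[j] * t(dec$v[, j, drop = FALSE]))
  } else {
    rec <- matrix(0, nrow(dec$u), nrow(dec$v),
                  dimnames = list(dec$molecule_ids, dec$sample_ids))
  }
  dimnames(rec) <- list(dec$molecule_ids, dec$sample_ids)
  list(reconstruction = rec, residual = dec$A - rec)
}

#' Prepare a matrix for cross-dataset concatenation
#'
#' Removes the baseline eigen-component, rescales the remainder to unit
#' Frobenius norm (equalizing the variance of the datasets), then divides by
#' sqrt(n) so that sample-rich datasets do not dominate. The output norm is
#' exactly 1/sqrt(n).
#'
#' @param mat An [omics_matrix()].
#' @return Numeric matrix ready for [concat_and_stratify()], with attribute
#'   `sample_times`.
#' @export
concat_prepare <- function(mat) {
  stopifnot(inherits(mat, "omics_matrix"))
  dec <- stratify(mat)
  Abar <- remove_baseline(dec)
  nf <- sqrt(sum(Abar^2))
  if (nf < 1e-12) stop("pure baseline matrix: no variance to concatenate")
  out <- Abar / nf / sqrt(ncol(Abar))
  attr(out, "sample_times") <- mat$sample_times
  attr(out, "omics_label") <- mat$omics_label
  out
}

#' Concatenate two prepared matrices and stratify
#'
#' Column-binds two baseline-free, norm-equalized matrices over a common
#' ordered molecule list and applies the SVD. Because the baselines were
#' removed before concatenation the level indexing of the result starts at
#' 1, not 0. Each sample-eigenvector is partitioned back into per-dataset
#' segments.
#'
#' @param m1,m2 Matrices from [concat_prepare()], row-indexed by the same
#'   ordered molecule ids.
#' @param common_molecules Optional explicit molecule id list; default the
#'   row names of `m1`.
#' @return An `eigen_decomposition` with `index_origin = 1` and an extra
#'   element `segments`: per-dataset row indices into `v`.
#' @export
concat_and_stratify <- function(m1, m2, common_molecules = rownames(m1)) {
  if (is.null(rownames(m1)) || is.null(rownames(m2)))
    stop("prepared matrices must carry molecule ids as rownames")
  if (!identical(rownames(m1), common_molecules) ||
      !identical(rownames(m2), common_molecules)) {
    bad <- union(setdiff(rownames(m1), common_molecules),
                 union(setdiff(rownames(m2), common_molecules),
                       union(setdiff(common_molecules, rownames(m1)),
                             setdiff(common_molecules, rownames(m2)))))
    stop("molecule lists do not match; offending ids: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  lab1 <- attr(m1, "omics_label") %||% "dataset1"
  lab2 <- attr(m2, "omics_label") %||% "dataset2"
  t1 <- attr(m1, "sample_times") %||% seq_len(ncol(m1))
  t2 <- attr(m2, "sample_times") %||% seq_len(ncol(m2))
  colnames(m1) <- paste0(lab1, ".", colnames(m1))
  colnames(m2) <- paste0(lab2, ".", colnames(m2))
  AA <- cbind(m1, m2)
  dec <- stratify(AA, sample_times = seq_len(ncol(AA)))
  # concatenated matrices are baseline-free: indexing starts at 1, and the
  # leading level takes the same skewness orientation as the others
  sk <- sample_skewness(dec$u[, 1])
  flip <- if (is.na(sk) || abs(sk) < 1e-12) {
    if (dec$u[which.max(abs(dec$u[, 1])), 1] < 0) -1 else 1
  } else if (sk < 0) -1 else 1
  dec$u[, 1] <- flip * dec$u[, 1]
  dec$v[, 1] <- flip * dec$v[, 1]
  dec$orientation[1] <- flip * dec$orientation[1]
  dec$index_origin <- 1L
  dec$sample_times <- c(t1, t2)
  dec$omics_label <- paste(lab1, lab2, sep = "+")
  dec$segments <- list(seq_len(ncol(m1)), ncol(m1) + seq_len(ncol(m2)))
  names(dec$segments) <- c(lab1, lab2)
  dec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a decomposition to a directory of text files
#'
#' Writes `levels.tsv` (k, lambda), `u.tsv` and `v.tsv` (loadings by level),
#' `contributions.json` and, when phase calls are supplied, `phases.tsv`.
#'
#' @param dec An `eigen_decomposition`.
#' @param dir Output directory (created if needed).
#' @param phases Optional `phase_calls` object.
#' @return Invisibly, `dir`.
#' @export
write_decomposition <- function(dec, dir, phases = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ks <- seq_len(dec$s) - 1L + dec$index_origin
  utils::write.table(data.frame(k = ks, lambda = dec$lambda),
                     file.path(dir, "levels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  u <- data.frame(molecule_id = dec$molecule_ids, dec$u, check.names = FALSE)
  colnames(u)[-1] <- paste0("u", ks)
  utils::write.table(u, file.path(dir, "u.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  v <- data.frame(sample_id = dec$sample_ids, time_h = dec$sample_times,
                  dec$v, check.names = FALSE)
  colnames(v)[-(1:2)] <- paste0("v", ks)
  utils::write.table(v, file.path(dir, "v.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  contrib <- relative_contributions(dec)
  jsonlite::write_json(contrib, file.path(dir, "contributions.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(phases))
    utils::write.table(phases$calls, file.path(dir, "phases.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
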