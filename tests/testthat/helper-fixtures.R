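# Shared fixtures, built in code at test time.

# random omics matrix with named molecules/samples and regular times
rand_omics <- function(m = 10, n = 4, seed = 1, label = "test") {
  set.seed(seed)
  vals <- matrix(rnorm(m * n), m,
                 dimnames = list(sprintf("g%02d", seq_len(m)),
                                 sprintf("s%02d", seq_len(n))))
  omics_matrix(vals, sample_times = seq_len(n) * 0.25, omics_label = label)
}

# equispaced sampling times covering whole cycles, first sample one
# interval after zero (matches the generator's convention)
cycle_times <- function(cycles, per_cycle = 16, period = 3) {
  seq(0, period * cycles, length.out = per_cycle * cycles + 1)[-1]
}

# is `ord` a rotation of `target` (both length-4 character vectors)?
is_rotation <- function(ord, target) {
  any(vapply(0:3, function(r)
    identical(c(ord, ord)[seq(r + 1, length.out = 4)], target), logical(1)))
}

# orient a decomposition's levels 1..2 to planted periodic functions
orient_to_planted <- function(dec, truth, times) {
  for (k in 1:2) {
    pv <- if (k == 1) truth$v1_fun(times) else truth$v2_fun(times)
    j <- k + 1L
    if (cor(dec$v[, j], pv) < 0) {
      dec$v[, j] <- -dec$v[, j]
      dec$u[, j] <- -dec$u[, j]
    }
  }
  dec
}

# hand-built decomposition object for white-box tests of interpreters
manual_dec <- function(u, v, lambda, sample_times = seq_len(nrow(v)),
                       A = NULL, label = "manual") {
  if (is.null(A)) A <- u %*% (lambda * t(v))
  structure(list(lambda = lambda, u = u, v = v, s = length(lambda),
                 sample_times = sample_times, omics_label = label,
                 orientation = rep(1, length(lambda)),
                 molecule_ids = rownames(u) %||% sprintf("g%d", seq_len(nrow(u))),
                 sample_ids = rownames(v) %||% sprintf("s%d", seq_len(nrow(v))),
                 A = A, index_origin = 0L),
            class = "eigen_decomposition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
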