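test_that("stratification satisfies the SVD identities", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    A <- matrix(rnorm(50 * 20, mean = 2), 50,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
    dec <- stratify(A, sample_times = 1:20)
    # reconstruction
    rec <- reconstruct(dec, 0:(dec$s - 1))
    expect_lt(norm(rec$residual, "F") / norm(A, "F"), 1e-8)
    # orthonormality
    expect_equal(crossprod(dec$u), diag(dec$s), tolerance = 1e-8)
    expect_equal(crossprod(dec$v), diag(dec$s), tolerance = 1e-8)
    # lambda_k u_k = A v_k, elementwise
    expect_equal(sweep(dec$u, 2, dec$lambda, "*"), A %*% dec$v,
                 tolerance = 1e-8, ignore_attr = TRUE)
    # variance identities
    Abar <- remove_baseline(dec)
    expect_equal(sum(Abar^2), sum(dec$lambda[-1]^2), tolerance = 1e-8)
    # lambda_k^2 = ||Abar v_k||^2 for k >= 1
    expect_equal(unname(colSums((Abar %*% dec$v[, -1])^2)),
                 dec$lambda[-1]^2, tolerance = 1e-8)
    # ordering
    expect_true(all(diff(dec$lambda) <= 0))
  }
})

test_that("singular values and loadings match an independent AtA eigen-solver", {
  set.seed(9)
  A <- matrix(rnorm(24), 6, 4)
  rownames(A) <- paste0("g", 1:6); colnames(A) <- paste0("s", 1:4)
  dec <- stratify(A, sample_times = 1:4)
  ev <- eigen(crossprod(A), symmetric = TRUE)
  expect_equal(dec$lambda, sqrt(pmax(ev$values, 0)), tolerance = 1e-8)
  for (k in seq_len(dec$s)) {
    expect_equal(abs(sum(dec$v[, k] * ev$vectors[, k])), 1, tolerance = 1e-8)
    uk <- A %*% ev$vectors[, k] / sqrt(ev$values[k])
    expect_equal(abs(sum(dec$u[, k] * uk)), 1, tolerance = 1e-8)
  }
})

test_that("constant-column matrices reduce to an exact baseline level", {
  mu <- c(3, 1, 4, 1.5, 9)
  A <- outer(mu, rep(1, 4))
  dimnames(A) <- list(paste0("g", 1:5), paste0("s", 1:4))
  dec <- stratify(A, sample_times = 1:4)
  expect_identical(dec$s, 1L)
  expect_equal(dec$v[, 1], rep(1 / 2, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(dec$lambda[1] * dec$u[, 1], sqrt(4) * mu, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(remove_baseline(dec), matrix(0, 5, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  diag0 <- baseline_diagnostics(dec)
  expect_true(diag0$pass)
  expect_lt(diag0$cv_v0, 1e-10)
  expect_lt(diag0$mu_max_rel_dev, 1e-10)
})

test_that("baseline diagnostics flag a mean-centered matrix without failing", {
  set.seed(4)
  A <- matrix(rnorm(40), 8, 5)
  A <- A - rowMeans(A) # near-zero baseline
  dimnames(A) <- list(paste0("g", 1:8), paste0("s", 1:5))
  dec <- stratify(A, sample_times = 1:5)
  expect_warning(d <- baseline_diagnostics(dec), "baseline")
  expect_false(d$pass)
})

test_that("orientation of a repeated stratification is bit-identical", {
  set.seed(21)
  A <- matrix(rnorm(60, 1), 12, 5)
  dimnames(A) <- list(paste0("g", 1:12), paste0("s", 1:5))
  d1 <- stratify(A, sample_times = 1:5)
  d2 <- stratify(A, sample_times = 1:5)
  expect_identical(d1$u, d2$u)
  expect_identical(d1$v, d2$v)
  # the baseline-removed projection is orthogonal to v0
  expect_equal(as.numeric(remove_baseline(d1) %*% d1$v[, 1]),
               rep(0, 12), tolerance = 1e-8)
})

test_that("relative contributions and eigen-entropy behave at the edges", {
  # one non-baseline level: p = 1, H = 0
  u <- qr.Q(qr(matrix(rnorm(12), 6)))[, 1:2]
  v <- qr.Q(qr(matrix(rnorm(8), 4)))[, 1:2]
  A <- 10 * tcrossprod(u[, 1], v[, 1]) + 2 * tcrossprod(u[, 2], v[, 2])
  dimnames(A) <- list(paste0("g", 1:6), paste0("s", 1:4))
  dec <- stratify(A, sample_times = 1:4)
  cc <- relative_contributions(dec)
  expect_equal(unname(cc$ratios), 1)
  expect_equal(cc$entropy, 0)

  # three equal non-baseline levels: H = ln 3. Sample directions built
  # orthogonal to the constant baseline direction.
  set.seed(2)
  U <- qr.Q(qr(matrix(rnorm(8 * 4), 8)))[, 1:4]
  V <- qr.Q(qr(cbind(1, matrix(rnorm(6 * 3), 6))))[, 1:4]
  v0 <- rep(1 / sqrt(6), 6)
  A2 <- 50 * tcrossprod(U[, 1], v0) +
    5 * (tcrossprod(U[, 2], V[, 2]) + tcrossprod(U[, 3], V[, 3]) +
           tcrossprod(U[, 4], V[, 4]))
  dimnames(A2) <- list(paste0("g", 1:8), paste0("s", 1:6))
  dec2 <- stratify(A2, sample_times = 1:6)
  p <- relative_contributions(dec2)$ratios[1:3]
  expect_equal(unname(p), rep(1 / 3, 3), tolerance = 1e-8)
  expect_equal(relative_contributions(dec2)$entropy, log(3), tolerance = 1e-8)

  # direct-formula value (recomputed, not copied): -sum p log p
  p3 <- c(0.5, 0.3, 0.2)
  expect_equal(eigen_entropy(p3), -sum(p3 * log(p3)), tolerance = 1e-12)
  expect_equal(eigen_entropy(p3), 1.0297, tolerance = 5e-5)
  # 0 * log 0 convention
  expect_equal(eigen_entropy(c(1, 0, 0)), 0)
  # pure baseline: no variance beyond it
  cA <- outer(1:5, rep(1, 4)); dimnames(cA) <- list(paste0("g", 1:5), paste0("s", 1:4))
  expect_error(relative_contributions(stratify(cA, sample_times = 1:4)),
               "no variance")
})

test_that("polarized loading tables are sorted with pole tags", {
  dec <- manual_dec(u = cbind(c(0.3, -0.1, 0.2) / sqrt(0.14)),
                    v = cbind(rep(0.5, 4)), lambda = 2)
  tab <- polarize(dec, 0)$molecules
  expect_equal(tab$loading, sort(c(0.3, -0.1, 0.2) / sqrt(0.14)))
  expect_identical(tab$pole, c("negative", "positive", "positive"))
  expect_identical(tab$rank, 1:3)
  # permutation property: same multiset
  m <- rand_omics(15, 5, seed = 8)
  dec2 <- stratify(m)
  p <- polarize(dec2, 1)
  expect_equal(sort(p$molecules$loading), sort(unname(dec2$u[, 2])))
  expect_setequal(p$molecules$id, rownames(m$values))
})

test_that("reconstruction respects kept levels and the noise budget", {
  m <- rand_omics(30, 6, seed = 10)
  dec <- stratify(m)
  expect_equal(reconstruct(dec, integer(0))$residual, m$values,
               tolerance = 1e-12)
  expect_error(reconstruct(dec, c(0, 99)), "invalid level")

  # planted rank-3 + noise: residual after keeping levels 0..2 carries the
  # noise not absorbed by the three fitted levels
  mm <- 200; nn <- 16; sigma <- 0.3
  ratios <- replicate(10, {
    U <- qr.Q(qr(matrix(rnorm(mm * 3), mm)))
    V <- qr.Q(qr(cbind(1, matrix(rnorm(nn * 2), nn))))
    A <- 60 * tcrossprod(U[, 1], V[, 1]) + 20 * tcrossprod(U[, 2], V[, 2]) +
      10 * tcrossprod(U[, 3], V[, 3]) + matrix(rnorm(mm * nn, 0, sigma), mm)
    dimnames(A) <- list(sprintf("g%03d", 1:mm), sprintf("s%02d", 1:nn))
    dec <- stratify(A, sample_times = 1:nn)
    sum(reconstruct(dec, 0:2)$residual^2) / (mm * nn * sigma^2)
  })
  expect_gt(mean(ratios), 0.75)
  expect_lt(mean(ratios), 1.0)

  # doubling sigma doubles the residual norm (ratio within 10% over seeds)
  set.seed(99)
  rr <- replicate(20, {
    U <- qr.Q(qr(matrix(rnorm(mm * 3), mm)))
    V <- qr.Q(qr(cbind(1, matrix(rnorm(nn * 2), nn))))
    S <- 60 * tcrossprod(U[, 1], V[, 1]) + 20 * tcrossprod(U[, 2], V[, 2]) +
      10 * tcrossprod(U[, 3], V[, 3])
    E <- matrix(rnorm(mm * nn), mm)
    f <- function(sig) {
      A <- S + sig * E
      dimnames(A) <- list(sprintf("g%03d", 1:mm), sprintf("s%02d", 1:nn))
      norm(reconstruct(stratify(A, sample_times = 1:nn), 0:2)$residual, "F")
    }
    f(0.4) / f(0.2)
  })
  expect_equal(mean(rr), 2, tolerance = 0.1)
})

test_that("concatenation preparation equalizes scale and sample-size weight", {
  m <- rand_omics(25, 5, seed = 12)
  prep <- concat_prepare(m)
  expect_equal(sqrt(sum(prep^2)), 1 / sqrt(5), tolerance = 1e-10)
  # different raw scales end with identical second moments (up to 1/sqrt(n))
  m2 <- m; m2$values <- m2$values * 37
  prep2 <- concat_prepare(m2)
  expect_equal(sum(prep^2) * 5, sum(prep2^2) * 5, tolerance = 1e-10)
  cA <- outer(1:5, rep(1, 4)); dimnames(cA) <- list(paste0("g", 1:5), paste0("s", 1:4))
  cm <- omics_matrix(cA, sample_times = 1:4)
  expect_error(concat_prepare(cm), "pure baseline")
})

test_that("concatenating a duplicated matrix reproduces the single-matrix level", {
  m <- rand_omics(25, 5, seed = 14)
  prep <- concat_prepare(m)
  dec1 <- stratify(m)
  cc <- concat_and_stratify(prep, prep)
  expect_identical(cc$index_origin, 1L)
  # level-1 molecule-eigenvector equals the single-matrix one (up to sign)
  expect_equal(abs(sum(cc$u[, 1] * dec1$u[, 2])), 1, tolerance = 1e-8)
  # the two sample-eigenvector segments are equal
  seg <- cc$segments
  expect_equal(cc$v[seg[[1]], 1], cc$v[seg[[2]], 1], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("concatenation recovers shared molecular structure and dilutes with noise", {
  tr <- generate_truth(seed = 6)
  set.seed(61)
  m1 <- simulate_omics(tr, "transcriptome", cycle_times(3))
  t2 <- cycle_times(3, per_cycle = 12) + 0.07 # different grid
  m2v <- simulate_omics(tr, "transcriptome", t2)
  p1 <- concat_prepare(m1); p2 <- concat_prepare(m2v)
  cc <- concat_and_stratify(p1, p2)
  expect_gt(abs(cor(cc$u[, 1], tr$u1)), 0.99)

  # concatenating with pure noise of equal norm dilutes the level-1 share
  set.seed(62)
  noise <- matrix(rnorm(tr$m * 12), tr$m,
                  dimnames = list(tr$molecule_ids, sprintf("n%02d", 1:12)))
  noise <- noise / sqrt(sum(noise^2)) / sqrt(12)
  attr(noise, "sample_times") <- seq_len(12)
  cn <- concat_and_stratify(p1, noise)
  contrib_alone <- relative_contributions(stratify(m1))$ratios[1]
  contrib_diluted <- relative_contributions(cn)$ratios[1]
  expect_lt(contrib_diluted, contrib_alone)

  # molecule mismatch errors name offenders
  bad <- p2[-(1:2), , drop = FALSE]
  expect_error(concat_and_stratify(p1, bad), "mol000[12]")
})
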