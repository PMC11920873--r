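test_that("rank-sum enrichment matches the exhaustive permutation distribution", {
  # oracle: enumerate every assignment of set membership and tabulate the
  # exact null distribution of the in-set rank sum
  perm_pvals <- function(loadings, inset) {
    r <- rank(loadings)
    w <- sum(r[inset])
    combos <- combn(length(loadings), sum(inset))
    ws <- apply(combos, 2, function(idx) sum(r[idx]))
    c(pos = mean(ws >= w), neg = mean(ws <= w))
  }
  set.seed(17)
  loadings <- rnorm(18)
  names(loadings) <- sprintf("g%02d", 1:18)
  for (size in c(5, 8)) {
    members <- sample(names(loadings), size)
    res <- wilcoxon_enrich(loadings, list(S = members), min_size = 5)
    oracle <- perm_pvals(loadings, names(loadings) %in% members)
    expect_equal(res$p[res$direction == "positive"], unname(oracle["pos"]),
                 tolerance = 1e-10)
    expect_equal(res$p[res$direction == "negative"], unname(oracle["neg"]),
                 tolerance = 1e-10)
  }
})

test_that("enrichment flags planted extreme sets and degenerate ones", {
  set.seed(18)
  loadings <- rnorm(1000)
  names(loadings) <- sprintf("g%04d", 1:1000)
  top <- names(sort(loadings, decreasing = TRUE))[1:10]
  res <- wilcoxon_enrich(loadings, list(top = top, all = names(loadings)))
  expect_lt(res$p[res$set_id == "top" & res$direction == "positive"], 1e-6)
  expect_gt(res$z[res$set_id == "top"][1], 0)
  # empty complement: degenerate, z = 0, p = 1
  expect_equal(res$z[res$set_id == "all"], c(0, 0))
  expect_equal(res$p[res$set_id == "all"], c(1, 1))
  # undersized sets are skipped with a warning
  expect_warning(empty <- wilcoxon_enrich(loadings, list(tiny = top[1:3])),
                 "no gene set")
  expect_equal(nrow(empty), 0L)
})

test_that("enrichment p-values are rank statistics and BH-adjusted per pole", {
  set.seed(19)
  loadings <- rnorm(200)
  names(loadings) <- sprintf("g%03d", 1:200)
  sets <- lapply(1:6, function(i) sample(names(loadings), 10 + i))
  names(sets) <- paste0("S", 1:6)
  a <- wilcoxon_enrich(loadings, sets)
  b <- wilcoxon_enrich(exp(2 * loadings), sets) # strictly monotone transform
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$z, b$z, tolerance = 1e-12)
  for (d in c("positive", "negative")) {
    i <- a$direction == d
    expect_equal(a$q[i], p.adjust(a$p[i], "BH"))
  }
})

test_that("random orthogonal sample-vectors satisfy their constraints", {
  m <- rand_omics(30, 12, seed = 23)
  dec <- stratify(m)
  set.seed(1)
  x <- random_orthogonal_vector(dec, k = 1)
  expect_equal(sqrt(sum(x^2)), 1, tolerance = 1e-12)
  expect_lt(max(abs(crossprod(dec$v[, 1:2], x))), 1e-10)
  expect_identical(random_orthogonal_vector(dec, 1, seed = 4),
                   random_orthogonal_vector(dec, 1, seed = 4))
  expect_error(random_orthogonal_vector(dec, k = 11), "complement")

  # isotropy in the complement: empirical second moment ~ projector / dim
  set.seed(2)
  draws <- replicate(4000, random_orthogonal_vector(dec, 1))
  emp <- tcrossprod(draws) / ncol(draws)
  P <- diag(12) - tcrossprod(dec$v[, 1:2])
  expect_lt(max(abs(emp - P / 10)), 0.02)
})

test_that("marker randomization obeys the sign-split p-value contract", {
  # a zero row gives loading 0 at every level and the stated p = 1
  set.seed(31)
  vals <- rbind(matrix(rnorm(19 * 8, 5), 19), 0)
  dimnames(vals) <- list(sprintf("g%02d", 1:20), sprintf("s%d", 1:8))
  dec <- stratify(omics_matrix(vals, sample_times = 1:8))
  mk <- marker_randomization(dec, 1, R = 200, seed = 3)
  expect_equal(mk$p[20], 1)
  expect_equal(mk$p_two[20], 1)
  expect_true(all(mk$p >= 1 / 201))
  expect_true(all(mk$p_two >= mk$p))
  expect_identical(marker_randomization(dec, 1, R = 200, seed = 3)$p, mk$p)
})

test_that("null marker p-values are uniform and planted blocks are recovered", {
  set.seed(32)
  A <- matrix(rnorm(200 * 12), 200,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:12)))
  dec <- stratify(A, sample_times = 1:12)
  mk <- marker_randomization(dec, 1, R = 500, seed = 5)
  ks <- suppressWarnings(ks.test(mk$p_two, "punif"))$statistic
  expect_lt(unname(ks), 0.1)

  tr <- generate_truth(seed = 33)
  set.seed(331)
  dec2 <- stratify(simulate_omics(tr, "transcriptome", cycle_times(1)))
  mk2 <- marker_randomization(dec2, 1, R = 1000, seed = 7)
  expect_true(all(mk2$marker[tr$marker_block]))
  expect_lte(sum(mk2$marker) - length(tr$marker_block), 2)
})

test_that("phase contributions weight the signal by the four eigen-phases", {
  # hand-worked 3x4 example against direct arithmetic
  u <- cbind(c(0.9, 0.3, 0.3), c(0.6, -0.7, 0.3), c(-0.2, 0.5, 0.8))
  v <- cbind(rep(0.5, 4), c(0.6, 0.2, -0.4, -0.6), c(-0.5, 0.5, 0.5, -0.5))
  dec <- manual_dec(u = u, v = v, lambda = c(9, 4, 2),
                    sample_times = c(0.5, 1, 1.5, 2))
  sig_vals <- matrix(c(1, 2, 3, 4, 2, 1, 0, 1, 5, 4, 3, 2), 3, byrow = TRUE,
                     dimnames = list(dec$molecule_ids, paste0("h", 1:4)))
  sig <- omics_matrix(sig_vals, sample_times = c(0.5, 1, 1.5, 2),
                      omics_label = "H3K9ac")
  ct <- phase_contributions(sig, dec)
  norm1 <- function(x) x / sum(x)
  up1 <- norm1(pmax(u[, 2], 0)); un1 <- norm1(pmax(-u[, 2], 0))
  vp1 <- norm1(pmax(v[, 2], 0)); vn1 <- norm1(pmax(-v[, 2], 0))
  up2 <- norm1(pmax(u[, 3], 0)); un2 <- norm1(pmax(-u[, 3], 0))
  vp2 <- norm1(pmax(v[, 3], 0)); vn2 <- norm1(pmax(-v[, 3], 0))
  manual <- c(`1A` = drop(up1 %*% sig_vals %*% vp1),
              `1B` = drop(un1 %*% sig_vals %*% vn1),
              `2A` = drop(up2 %*% sig_vals %*% vp2),
              `2B` = drop(un2 %*% sig_vals %*% vn2))
  expect_equal(ct$contributions, manual, tolerance = 1e-12)
  expect_equal(ct$cv, sd(manual) / mean(manual), tolerance = 1e-12)

  # constant signal: all four contributions equal the constant, CV = 0
  sig_const <- omics_matrix(matrix(4.2, 3, 4,
                                   dimnames = list(dec$molecule_ids, paste0("h", 1:4))),
                            sample_times = c(0.5, 1, 1.5, 2))
  ctc <- phase_contributions(sig_const, dec)
  expect_equal(unname(ctc$contributions), rep(4.2, 4), tolerance = 1e-12)
  expect_equal(ctc$cv, 0)

  # scale equivariance: doubling the signal doubles contributions, CV fixed
  sig2 <- sig; sig2$values <- sig2$values * 2
  ct2 <- phase_contributions(sig2, dec)
  expect_equal(ct2$contributions, 2 * ct$contributions, tolerance = 1e-12)
  expect_equal(ct2$cv, ct$cv, tolerance = 1e-12)

  # gene reordering leaves contributions unchanged
  sig_perm <- omics_matrix(sig_vals[c(3, 1, 2), ],
                           sample_times = c(0.5, 1, 1.5, 2))
  expect_equal(phase_contributions(sig_perm, dec)$contributions,
               ct$contributions, tolerance = 1e-12)

  # one-signed eigenvector errors out naming the problem
  dec_bad <- dec
  dec_bad$v[, 2] <- abs(dec_bad$v[, 2])
  expect_error(phase_contributions(sig, dec_bad), "one-signed")

  # sign-convention invariance: flipping level 1 swaps 1A and 1B
  dec_f <- dec
  dec_f$u[, 2] <- -dec_f$u[, 2]; dec_f$v[, 2] <- -dec_f$v[, 2]
  ctf <- phase_contributions(sig, dec_f)
  expect_equal(unname(ctf$contributions[c("1A", "1B")]),
               unname(ct$contributions[c("1B", "1A")]), tolerance = 1e-12)
})

test_that("histone-like signals are interpolated to the transcriptome clock", {
  tr <- generate_truth(seed = 35)
  tt_t <- cycle_times(1)
  tt_h <- cycle_times(1) + 0.05
  set.seed(351)
  tdec <- stratify(simulate_omics(tr, "transcriptome", tt_t))
  sig <- simulate_omics(tr, "epigenome", tt_h)
  ct <- phase_contributions(sig, tdec)
  expect_equal(ct$n_common, tr$m)
  expect_true(is.finite(ct$cv) && ct$cv >= 0)
})
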