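test_that("scm matches the divisor-(Nt-1) covariance on hand cases", {
  # variance of a +/-1 sequence
  expect_equal(scm(matrix(c(1, -1, 1, -1), 1, 4))[1, 1], 4 / 3)
  # constant rows are annihilated by centering and flagged PSD
  C <- scm(matrix(1, 3, 10))
  expect_equal(unname(C[,]), matrix(0, 3, 3), ignore_attr = TRUE)
  expect_true(attr(C, "psd"))
  # centering off reproduces the raw cross-product
  X <- matrix(rnorm(2 * 8), 2, 8)
  expect_equal(scm(X, center = FALSE), tcrossprod(X) / 7, ignore_attr = TRUE)
})

test_that("scm of a full-rank tall trial is symmetric positive definite", {
  set.seed(1)
  for (i in 1:20) {
    X <- matrix(rnorm(4 * 256), 4, 256)
    C <- scm(X)
    expect_equal(C, t(C))
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_false(attr(C, "psd"))
  }
  expect_error(scm(matrix(1, 2, 1)), "degenerate")
  expect_error(scm(matrix(c(1, NA, 1, 1), 2, 2)), "non-finite")
})

test_that("reeig_rectify floors the spectrum exactly and is idempotent", {
  expect_equal(reeig_rectify(diag(c(1e-8, 1)), 1e-4), diag(c(1e-4, 1)),
               ignore_attr = TRUE)
  set.seed(2)
  for (i in 1:25) {
    S <- rand_spd(5, spread = 3)
    eps <- 1e-2
    R <- reeig_rectify(S, eps)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), eps * (1 - 1e-12))
    expect_equal(reeig_rectify(R, eps), R, tolerance = 1e-12, ignore_attr = TRUE)
    # above-threshold input is untouched
    S2 <- S + diag(5) * (eps - min(eigen(S, symmetric = TRUE)$values) + 1)
    expect_equal(reeig_rectify(S2, eps), S2, tolerance = 1e-10, ignore_attr = TRUE)
  }
  # spectral surgery on a known rotated spectrum
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  S <- Q %*% diag(c(1e-6, 2, 3)) %*% t(Q)
  expect_equal(reeig_rectify(S, 1e-3), Q %*% diag(c(1e-3, 2, 3)) %*% t(Q),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("logeig_map inverts expm and handles diagonal cases", {
  expect_equal(logeig_map(diag(2)), matrix(0, 2, 2))
  expect_equal(logeig_map(diag(c(exp(1), exp(2)))), diag(c(1, 2)))
  set.seed(4)
  for (i in 1:25) {
    S <- rand_spd(4, spread = 2)
    expect_equal(expm_spd(logeig_map(S)), S, tolerance = 1e-8)
  }
  expect_error(logeig_map(diag(c(1, -1))), "positive definite")
})

test_that("vect_spd preserves the Frobenius norm and has the stated layout", {
  expect_equal(vect_spd(diag(2)), c(1, 0, 1))
  v <- vect_spd(matrix(c(1, 2, 2, 5), 2, 2))
  expect_equal(v, c(1, 2 * sqrt(2), 5))
  expect_equal(sum(v^2), 34)
  expect_length(vect_spd(diag(10)), 55)
  set.seed(5)
  for (i in 1:30) {
    S <- rand_spd(sample(2:7, 1))
    expect_equal(sqrt(sum(vect_spd(S)^2)), sqrt(sum(S^2)), tolerance = 1e-10)
    expect_equal(riemnet:::unvect_spd(vect_spd(S)), S, tolerance = 1e-12)
  }
  expect_error(vect_spd(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("conc_spd is block-diagonal with the union spectrum", {
  expect_equal(unname(conc_spd(list(diag(2), diag(3)))[,]), diag(5),
               ignore_attr = TRUE)
  C <- conc_spd(list(diag(c(1, 2)), matrix(3)))
  expect_equal(sort(eigen(C, symmetric = TRUE)$values), c(1, 2, 3))
  set.seed(6)
  for (i in 1:20) {
    blocks <- lapply(sample(2:4, 3, replace = TRUE), rand_spd)
    C <- conc_spd(blocks)
    expect_equal(attr(C, "block_sizes"), vapply(blocks, nrow, integer(1)))
    expect_silent(chol(C))  # PD preserved
    got <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    want <- sort(unlist(lapply(blocks, function(b)
      eigen(b, symmetric = TRUE, only.values = TRUE)$values)))
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(conc_spd(list()), "non-empty")
})

test_that("interband covariance reduces to per-band concatenation without IC", {
  set.seed(7)
  T1 <- matrix(rnorm(3 * 50), 3, 50)
  # duplicated bands: every block of the stacked covariance equals the SCM
  C <- interband_scm(rbind(T1, T1), c(3, 3))
  S1 <- scm(T1)
  for (bi in list(1:3, 4:6)) for (bj in list(1:3, 4:6)) {
    expect_equal(unname(C[bi, bj]), unname(S1[,]), tolerance = 1e-12)
  }
  # zeroed interband equals conc of per-band SCMs, element-wise exactly
  T2 <- matrix(rnorm(3 * 50), 3, 50)
  Cz <- interband_scm(rbind(T1, T2), c(3, 3), keep_interband = FALSE)
  Cc <- conc_spd(list(scm(T1), scm(T2)))
  expect_equal(unname(Cz[,]), unname(Cc[,]))
  expect_error(interband_scm(rbind(T1, T2), c(3, 4)), "inconsistent")
})

test_that("interband blocks of independent bands vanish at large Nt", {
  set.seed(8)
  T1 <- matrix(rnorm(2 * 1e4), 2, 1e4)
  T2 <- matrix(rnorm(2 * 1e4), 2, 1e4)
  C <- interband_scm(rbind(T1, T2), c(2, 2))
  ic <- C[1:2, 3:4]
  # sample cross-covariance of independent unit-variance series ~ N(0, 1/Nt)
  expect_lt(max(abs(ic)), 5 / sqrt(1e4))
  expect_gt(min(diag(C)), 0.9)
})

test_that("regularize_spd turns PSD matrices into PD ones", {
  expect_equal(unname(regularize_spd(matrix(0, 3, 3), 1e-4)[,]), 1e-4 * diag(3),
               ignore_attr = TRUE)
  set.seed(9)
  v <- rnorm(4)
  S <- tcrossprod(v)  # rank one
  R <- regularize_spd(S, 1e-4)
  expect_silent(chol(R))
  S2 <- rand_spd(4) + diag(4)
  expect_equal(regularize_spd(S2, 1e-4), S2, tolerance = 1e-10, ignore_attr = TRUE)
})
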