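test_that("distances satisfy metric axioms on random PD pairs", {
  set.seed(1)
  for (metric in c("airm", "lem")) {
    for (i in 1:15) {
      S1 <- rand_spd(3)
      S2 <- rand_spd(3)
      S3 <- rand_spd(3)
      expect_equal(spd_dist(S1, S1, metric), 0, tolerance = 1e-8)
      expect_equal(spd_dist(S1, S2, metric), spd_dist(S2, S1, metric),
                   tolerance = 1e-10)
      expect_gt(spd_dist(S1, S2, metric), 0)
      expect_lte(spd_dist(S1, S3, metric),
                 spd_dist(S1, S2, metric) + spd_dist(S2, S3, metric) + 1e-8)
    }
  }
  expect_equal(spd_dist(diag(2), exp(1) * diag(2), "lem"), sqrt(2))
  expect_error(spd_dist(diag(2), diag(3)), "dimension")
})

test_that("AIRM distance is invariant to congruence transforms", {
  set.seed(2)
  for (i in 1:10) {
    S1 <- rand_spd(3); S2 <- rand_spd(3)
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 1e-3) A <- matrix(rnorm(9), 3, 3)
    d0 <- spd_dist(S1, S2, "airm")
    d1 <- spd_dist(A %*% S1 %*% t(A), A %*% S2 %*% t(A), "airm")
    expect_equal(d1, d0, tolerance = 1e-8)
  }
})

test_that("Frechet means agree with closed forms on degenerate families", {
  set.seed(3)
  S <- rand_spd(3)
  for (metric in c("airm", "lem")) {
    expect_equal(frechet_mean(list(S, S), metric), S, tolerance = 1e-7)
  }
  # commuting pair: geodesic midpoint under both metrics
  A <- diag(c(1, 1)); B <- exp(2) * diag(c(1, 1))
  expect_equal(frechet_mean(list(A, B), "lem"), exp(1) * diag(2), tolerance = 1e-8)
  expect_equal(frechet_mean(list(A, B), "airm"), exp(1) * diag(2), tolerance = 1e-7)
  # commuting family: AIRM mean equals expm of the log-mean
  D <- lapply(1:4, function(i) diag(exp(rnorm(3))))
  expect_equal(frechet_mean(D, "airm"), frechet_mean(D, "lem"), tolerance = 1e-8)
})

test_that("AIRM mean satisfies the Karcher stationarity condition", {
  set.seed(4)
  Ss <- lapply(1:6, function(i) rand_spd(3))
  M <- frechet_mean(Ss, "airm")
  Misq <- riemnet:::powm_spd(M, -0.5)
  resid <- Reduce(`+`, lapply(Ss, function(S) logeig_map(Misq %*% S %*% Misq)))
  expect_lt(sqrt(sum((resid / length(Ss))^2)), 1e-6)
})

test_that("tangent projection is an isometry at the reference", {
  set.seed(5)
  S <- rand_spd(3)
  # AIRM at identity reference is the plain matrix log
  V <- tangent_project(list(S), "airm", reference = diag(3))
  expect_equal(as.numeric(V), vect_spd(logeig_map(S)), tolerance = 1e-10)
  # LEM projection of the identity is the zero vector
  V0 <- tangent_project(list(diag(3)), "lem")
  expect_equal(as.numeric(V0), rep(0, 6))
  # vector norm equals AIRM distance to the reference
  Ss <- lapply(1:5, function(i) rand_spd(3))
  Vp <- tangent_project(Ss, "airm")
  R <- attr(Vp, "reference")
  for (i in seq_along(Ss)) {
    expect_equal(sqrt(sum(Vp[i, ]^2)), spd_dist(Ss[[i]], R, "airm"),
                 tolerance = 1e-8)
  }
  # vectors at the Frechet mean average to ~0 (stationarity)
  expect_lt(max(abs(colMeans(Vp))), 1e-6)
})

test_that("rMDM classifies, ties break low, and matches Euclidean MDM in log domain", {
  set.seed(6)
  d <- two_class_spd()
  # self-assignment with one sample per class
  pred <- rmdm_fit_predict(d$S[c(1, 9)], d$y[c(1, 9)], d$S[c(1, 9)], "lem")
  expect_equal(as.character(pred), c("a", "b"))
  # LEM rMDM == Euclidean MDM on log-mapped matrices (independent oracle)
  pred_lem <- rmdm_fit_predict(d$S, d$y, d$S, "lem")
  logs <- lapply(d$S, logeig_map)
  mu_a <- Reduce(`+`, logs[d$y == "a"]) / sum(d$y == "a")
  mu_b <- Reduce(`+`, logs[d$y == "b"]) / sum(d$y == "b")
  euclid <- vapply(logs, function(L) {
    c(sqrt(sum((L - mu_a)^2)), sqrt(sum((L - mu_b)^2)))
  }, numeric(2))
  expect_equal(as.character(pred_lem),
               c("a", "b")[apply(euclid, 2, which.min)])
  # exact tie goes to the lowest class index
  tie <- rmdm_fit_predict(list(diag(2), 4 * diag(2)), factor(c("a", "b")),
                          list(2 * diag(2)), "lem")
  expect_equal(as.character(tie), "a")
  expect_error(rmdm_fit(d$S[1:3], factor(c("a", "a", "a"), levels = c("a", "b"))),
               "class")
})

test_that("rMDM decisions are invariant to joint congruence under AIRM", {
  set.seed(7)
  d <- two_class_spd(n_per_class = 5)
  A <- matrix(rnorm(9), 3, 3) + 3 * diag(3)
  warp <- function(S) A %*% S %*% t(A)
  p0 <- rmdm_fit_predict(d$S, d$y, d$S, "airm")
  p1 <- rmdm_fit_predict(lapply(d$S, warp), d$y, lapply(d$S, warp), "airm")
  expect_equal(as.character(p0), as.character(p1))
})

test_that("rSVM separates synthetic SPD classes and is deterministic", {
  d <- two_class_spd(n_per_class = 10, seed = 8)
  for (metric in c("lem", "airm")) {
    pred <- rsvm_fit_predict(d$S, d$y, d$S, metric)
    expect_equal(as.character(pred), as.character(d$y))
  }
  # identical runs give identical labels
  p1 <- rsvm_fit_predict(d$S, d$y, d$S, "lem")
  p2 <- rsvm_fit_predict(d$S, d$y, d$S, "lem")
  expect_identical(p1, p2)
  # LEM rSVM is a plain linear SVM on vect(logm S) by construction
  V <- t(vapply(d$S, function(S) vect_spd(logeig_map(S)), numeric(6)))
  ref <- predict(e1071::svm(V, d$y, kernel = "linear", cost = 1, scale = FALSE,
                            type = "C-classification"), V)
  expect_equal(as.character(p1), as.character(ref))
  expect_error(rsvm_fit(d$S[1:3], factor(rep("a", 3))), "two classes")
})
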