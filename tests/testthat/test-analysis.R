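test_that("identity filtering has zero frequency gain", {
  set.seed(1)
  trials <- lapply(1:8, function(i) matrix(rnorm(2 * 128), 2, 128))
  ts <- trial_set(trials, rep(1:2, 4), fs = 64)
  cfg <- network_config(ne = 2, n_classes = 2, fs = 64, nf = 1, n_bire = 0,
                        kind = "conv", kernel_len = 1, seed = 1)
  m <- spdnet_init(cfg)
  m$params$kernels[] <- 1
  g <- frequency_gain(m, ts)
  expect_true(all(abs(g$gain_db) < 0.1))
  expect_false(any(g$discarded))
})

test_that("a sinc bandpass shows in-band ~0 dB gain and strong stopband loss", {
  set.seed(2)
  trials <- lapply(1:16, function(i) matrix(rnorm(2 * 512), 2, 512))
  ts <- trial_set(trials, rep(1:2, 8), fs = 250)
  cfg <- network_config(ne = 2, n_classes = 2, fs = 250, nf = 1, n_bire = 0,
                        kind = "sinc", kernel_len = 101, seed = 1)
  m <- spdnet_init(cfg)
  m$params$sinc_a <- riemnet:::softplus_inv(8)
  m$params$sinc_b <- riemnet:::softplus_inv(30 - 8 - 1)
  g <- frequency_gain(m, ts)
  inband <- g$gain_db[g$freq >= 12 & g$freq <= 26]
  stop_hi <- g$gain_db[g$freq >= 60 & g$freq <= 120]
  expect_lt(mean(abs(inband)), 3)
  expect_lt(mean(stop_hi), -20)
})

test_that("zero-signal input is discarded rather than raising an error", {
  trials <- lapply(1:4, function(i) matrix(0, 2, 64) + 0)
  # tiny jitter on one electrode so trial_set accepts finite input but the
  # filtered spectrum of the silent rows still collapses
  ts <- trial_set(trials, rep(1:2, 2), fs = 64)
  cfg <- network_config(ne = 2, n_classes = 2, fs = 64, nf = 1, n_bire = 0,
                        kind = "conv", kernel_len = 1, seed = 1)
  m <- spdnet_init(cfg)
  g <- frequency_gain(m, ts)
  expect_true(all(g$discarded))
  expect_true(all(is.na(g$gain_db)))
  expect_true(all(is.na(count_peaks(g)$n_peaks)))
})

test_that("peak counting separates unimodal, multiband and flat spectra", {
  freq <- seq(0, 64, by = 0.5)
  mk <- function(g) {
    structure(tibble::tibble(filter = 1L, freq = freq, gain_db = g,
                             interpolated = FALSE, discarded = FALSE),
              class = c("gain_spectrum", class(tibble::tibble())))
  }
  bump <- function(mu, h = 12, w = 3) h * exp(-(freq - mu)^2 / (2 * w^2))
  expect_equal(count_peaks(mk(bump(20)))$n_peaks, 1)
  two <- count_peaks(mk(bump(12) + bump(45)))
  expect_equal(two$n_peaks, 2)
  expect_true(two$multiband)
  set.seed(3)
  expect_equal(count_peaks(mk(rnorm(length(freq), sd = 0.3)))$n_peaks, 0)
  # median-zeroing: adding a constant changes nothing
  expect_equal(count_peaks(mk(bump(20) + 50))$n_peaks, 1)
})

test_that("layer-by-layer probing reports both probes per SPD stage", {
  d <- tiny_net_data(seed = 4, n_bire = 1)
  sp <- split_trials(d$trials, 0.7, seed = 1)
  m <- spdnet_init(d$config)
  fit <- spdnet_train(m, sp$train, train_config(epochs = 8, seed = 1))
  lbl <- layer_by_layer(fit, sp$train, sp$test)
  expect_equal(nrow(lbl), 2 * 3)  # pool, bimap1, reeig1 x {rsvm, svm}
  expect_setequal(unique(lbl$probe), c("rsvm", "svm"))
  net_acc <- attr(lbl, "network_accuracy")
  expect_equal(lbl$delta_vs_network, lbl$accuracy - net_acc)
  # the planted structure is decodable from the raw pooled covariance:
  # chance is 50%, binomial 3 sigma at the test size
  n_te <- length(sp$test$trials)
  first_rsvm <- lbl$accuracy[lbl$stage == "pool" & lbl$probe == "rsvm"]
  expect_gt(first_rsvm, 50 + 3 * 100 * sqrt(0.25 / n_te))
})

test_that("identity null network probes equal probes on raw SCMs", {
  d <- tiny_net_data(seed = 5)
  sp <- split_trials(d$trials, 0.7, seed = 1)
  cfg <- network_config(ne = 4, n_classes = 2, fs = 128, nf = 1, n_bire = 0,
                        kind = "conv", kernel_len = 1, seed = 1)
  m <- spdnet_init(cfg)
  m$params$kernels[] <- 1
  m$levels <- levels(sp$train$labels)
  lbl <- layer_by_layer(m, sp$train, sp$test)
  raw_tr <- lapply(sp$train$trials, function(X) regularize_spd(scm(X), 1e-4))
  raw_te <- lapply(sp$test$trials, function(X) regularize_spd(scm(X), 1e-4))
  ref <- rsvm_fit_predict(raw_tr, sp$train$labels, raw_te, "lem")
  ref_acc <- 100 * mean(as.character(ref) == as.character(sp$test$labels))
  expect_equal(lbl$accuracy[lbl$stage == "pool" & lbl$probe == "rsvm"], ref_acc)
})

test_that("eigenvalues below threshold vanish after every ReEig stage", {
  d <- tiny_net_data(seed = 6, n_bire = 2, nf = 2)
  m <- spdnet_init(d$config)
  tab <- eig_below_threshold(m, riemnet:::ts_subset(d$trials, 1:6))
  re <- tab$pct_below[grepl("^reeig", tab$stage)]
  expect_equal(re, rep(0, 2))
  # rank-deficient pooling shows up before the first rectification
  set.seed(6)
  short <- trial_set(lapply(1:3, function(i) matrix(rnorm(4 * 3), 4, 3)),
                     c(1, 2, 1), fs = 16)
  cfg <- network_config(ne = 4, n_classes = 2, fs = 16, nf = 1, n_bire = 1,
                        kind = "conv", kernel_len = 1, seed = 1)
  m2 <- spdnet_init(cfg)
  tab2 <- eig_below_threshold(m2, short)
  expect_equal(tab2$pct_below[tab2$stage == "pool"], 50)  # rank 2 of 4
  expect_equal(tab2$pct_below[tab2$stage == "reeig1"], 0)
})

test_that("bimap gain has the rank-one closed form", {
  # identity weight: all-ones gain matrix
  expect_equal(bimap_gain(diag(3))$G, matrix(1, 3, 3))
  set.seed(7)
  for (i in 1:10) {
    W <- qr.Q(qr(matrix(rnorm(6 * 3), 6, 3)))
    G <- bimap_gain(W)$G
    # independent oracle: the literal double sum over outer products
    G_ref <- matrix(0, 6, 6)
    for (p in 1:6) for (q in 1:6) {
      G_ref[p, q] <- sum(outer(W[p, ], W[q, ]))
    }
    expect_equal(G, G_ref, tolerance = 1e-12)
    expect_equal(G, t(G), tolerance = 1e-12)
  }
  # electrode aggregation maps band-major rows back to electrodes
  d <- tiny_net_data(seed = 7, nf = 2, n_bire = 1)
  m <- spdnet_init(d$config)
  eg <- bimap_gain(m)$electrode_gain
  expect_equal(nrow(eg), 4)
  rg <- bimap_gain(m)$row_gain
  expect_equal(eg$gain[1], rg[1] + rg[5])
})

test_that("relevance maps are zero under a zero head and localise planted bands", {
  d <- tiny_net_data(seed = 8)
  m <- spdnet_init(d$config)
  m$params$A[] <- 0
  m$params$b[] <- 0
  sub <- riemnet:::ts_subset(d$trials, 1:4)
  rel0 <- electrode_frequency_relevance(m, sub)
  expect_equal(dim(rel0$rel), c(2, 4, length(rel0$freq)))
  expect_true(all(rel0$rel == 0))
  # trained model: relevance mass should sit on the informative electrodes
  sp <- split_trials(d$trials, 0.7, seed = 1)
  fit <- spdnet_train(spdnet_init(d$config), sp$train,
                      train_config(epochs = 10, seed = 1))
  rel <- electrode_frequency_relevance(fit, riemnet:::ts_subset(sp$train, 1:10))
  td <- tidy(rel)
  expect_s3_class(td, "tbl_df")
  cut <- quantile(abs(td$relevance), 0.9)
  top <- td[abs(td$relevance) >= cut, ]
  # classes are planted at electrodes 1-2 (10-20 Hz) and 3-4 (30-45 Hz);
  # top-decile relevance should not be spread uniformly
  expect_gt(max(table(top$electrode)) / nrow(top), 0.3)
})
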