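test_that("class covariances are trace-normalised means over class trials", {
  eeg <- random_epoched(M = 6L, L = 3L, N = 40L, seed = 21L)
  cov <- class_covariances(eeg$data, eeg$labels)
  expect_equal(sum(diag(cov$B1)), 1, tolerance = 1e-12)
  expect_equal(sum(diag(cov$B2)), 1, tolerance = 1e-12)
  expect_lt(max(abs(cov$B1 - t(cov$B1))), 1e-10)
  expect_gte(min(eigen(cov$B1, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_lt(max(abs(cov$B1 - oracle_class_cov(eeg$data, eeg$labels, 1L))),
            1e-10)
  expect_lt(max(abs(cov$B2 - oracle_class_cov(eeg$data, eeg$labels, 2L))),
            1e-10)
})

test_that("single trial per class gives that trial's normalised covariance", {
  eeg <- random_epoched(M = 2L, L = 3L, N = 30L, seed = 22L)
  cov <- class_covariances(eeg$data, eeg$labels)
  X <- matrix(eeg$data[1, , ], nrow = 3)
  C <- tcrossprod(X)
  expect_equal(cov$B1, C / sum(diag(C)), tolerance = 1e-12)
})

test_that("degenerate covariance inputs are rejected with context", {
  eeg <- random_epoched(M = 4L, L = 2L, N = 20L)
  expect_error(class_covariances(eeg$data, rep(1L, 4)), "class 2")
  eeg$data[3, , ] <- 0
  expect_error(class_covariances(eeg$data, eeg$labels), "trial 3")
})

test_that("diagonal covariances recover the analytic eigenstructure", {
  cov <- structure(list(B1 = diag(c(2, 1)) / 3, B2 = diag(c(1, 2)) / 3, L = 2L),
                   class = "class_covariances")
  model <- fit_csp(cov, V = 1L, reg = 0)
  expect_equal(model$eigenvalues, c(2 / 3, 1 / 3), tolerance = 1e-10)
  # filters align with the coordinate axes
  aligned <- apply(abs(model$W) / sqrt(colSums(model$W^2)), 2, max)
  expect_true(all(aligned > 1 - 1e-8))
})

test_that("identical class covariances admit no discriminative direction", {
  B <- random_spd(4L, seed = 23L); B <- B / sum(diag(B))
  cov <- structure(list(B1 = B, B2 = B, L = 4L), class = "class_covariances")
  model <- fit_csp(cov, V = 2L, reg = 0)
  expect_equal(model$eigenvalues, rep(0.5, 4), tolerance = 1e-10)
})

test_that("returned filters satisfy the Rayleigh-quotient identity and scaling", {
  for (seed in 1:10) {
    L <- sample(3:8, 1)
    B1 <- random_spd(L, seed); B1 <- B1 / sum(diag(B1))
    B2 <- random_spd(L, seed + 100); B2 <- B2 / sum(diag(B2))
    cov <- structure(list(B1 = B1, B2 = B2, L = L),
                     class = "class_covariances")
    V <- sample(seq_len(L %/% 2), 1)
    model <- fit_csp(cov, V = V, reg = 0)
    expect_true(all(model$eigenvalues >= -1e-10 &
                    model$eigenvalues <= 1 + 1e-10))
    for (j in seq_len(2 * V)) {
      w <- model$W[, j]
      quot <- drop(t(w) %*% B1 %*% w) / drop(t(w) %*% (B1 + B2) %*% w)
      expect_equal(quot, model$eigenvalues[j], tolerance = 1e-8)
      expect_equal(drop(t(w) %*% (B1 + B2) %*% w), 1, tolerance = 1e-8)
    }
    # paired spectrum: swapping class roles mirrors the eigenvalues
    cov_sw <- structure(list(B1 = B2, B2 = B1, L = L),
                        class = "class_covariances")
    model_sw <- fit_csp(cov_sw, V = V, reg = 0)
    expect_equal(sort(model_sw$eigenvalues), sort(1 - model$eigenvalues),
                 tolerance = 1e-8)
  }
})

test_that("filter count limits are enforced", {
  cov <- structure(list(B1 = diag(2) / 2, B2 = diag(2) / 2, L = 2L),
                   class = "class_covariances")
  expect_error(fit_csp(cov, V = 2L), "2V <= L")
})

test_that("log-variance features match a brute-force projection oracle", {
  eeg <- random_epoched(M = 5L, L = 4L, N = 60L, seed = 24L)
  cov <- class_covariances(eeg$data, eeg$labels)
  model <- fit_csp(cov, V = 2L)
  feats <- band_features(eeg$data, model)
  expect_identical(dim(feats), c(5L, 4L))
  for (m in 1:5) for (v in 1:4) {
    tc <- numeric(60)
    for (n in 1:60) tc[n] <- sum(model$W[, v] * eeg$data[m, , n])
    expect_equal(feats[m, v], log(stats::var(tc)), tolerance = 1e-10)
  }
})

test_that("features obey the log identities", {
  eeg <- random_epoched(M = 2L, L = 3L, N = 50L, seed = 25L)
  cov <- class_covariances(eeg$data, eeg$labels)
  model <- fit_csp(cov, V = 1L)
  base <- band_features(eeg$data, model)
  # scaling a trial by c shifts every feature of that trial by 2 log c
  scaled <- eeg$data
  scaled[1, , ] <- 5 * scaled[1, , ]
  f2 <- band_features(scaled, model)
  expect_equal(f2[1, ] - base[1, ], rep(2 * log(5), 2), tolerance = 1e-10)
  expect_equal(f2[2, ], base[2, ], tolerance = 1e-12)
  # unit projected variance maps to 0
  w <- model$W[, 1]
  tc <- drop(crossprod(w, matrix(eeg$data[1, , ], 3)))
  unit <- eeg$data[1, , , drop = FALSE] / sqrt(stats::var(tc))
  expect_equal(band_features(unit, model)[1, 1], 0, tolerance = 1e-10)
})

test_that("zero-variance projections are floored and flagged, not -Inf", {
  flat <- array(1, c(2L, 2L, 30L))  # constant: zero variance on any projection
  model <- structure(list(W = diag(2), eigenvalues = c(1, 0), V = 1L, L = 2L),
                     class = "csp_model")
  feats <- band_features(flat, model)
  expect_true(all(is.finite(feats)))
  expect_true(attr(feats, "floored"))
})

test_that("multiband models hold one filter set per band and fuse to S*2V columns", {
  sim <- simulate_mi_eeg(sim_config(n_channels = 6L, informative_channels = 1:2,
                                    trials_per_class = 10L, trial_len_s = 2,
                                    seed = 26L))
  sb <- apply_filterbank(sim$epoched)
  model <- fit_multiband(sb, V = 2L)
  expect_length(model$models, 4L)
  expect_true(all(vapply(model$models, function(m) ncol(m$W), 0L) == 4L))

  feats <- extract_features(sb, model)
  expect_identical(ncol(feats), 16L)
  expect_identical(attr(feats, "labels"), sim$epoched$labels)

  # block assembly: column (s, v) is band_features of band s, column v
  for (s in c(1L, 3L)) {
    bf <- band_features(array(sb$data[s, , , ], dim = dim(sb$data)[2:4]),
                        model$models[[s]])
    expect_equal(unname(feats[, ((s - 1) * 4 + 1):(s * 4)]), unname(bf),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # S = 2, V = 1 -> 4 columns
  sb2 <- apply_filterbank(sim$epoched,
                          filterbank_spec(list(c(8, 13), c(13, 22))))
  m2 <- fit_multiband(sb2, V = 1L)
  expect_identical(ncol(extract_features(sb2, m2)), 4L)
})

test_that("a single-band bank reduces to the plain CSP path", {
  eeg <- random_epoched(M = 6L, L = 3L, N = 200L, seed = 27L)
  sb <- apply_filterbank(eeg, filterbank_spec(list(c(8, 35))))
  mb <- fit_multiband(sb, V = 1L)
  cov <- class_covariances(array(sb$data[1, , , ], dim = dim(eeg$data)),
                           eeg$labels)
  single <- fit_csp(cov, V = 1L)
  expect_equal(mb$models[[1]]$W, single$W, tolerance = 1e-12)
})

test_that("fitting on channel-permuted data permutes filter rows", {
  eeg <- random_epoched(M = 8L, L = 4L, N = 100L, seed = 28L)
  perm <- c(3L, 1L, 4L, 2L)
  permuted <- epoched_eeg(eeg$data[, perm, , drop = FALSE], eeg$fs,
                          labels = eeg$labels)
  m1 <- fit_csp(class_covariances(eeg$data, eeg$labels), V = 2L)
  m2 <- fit_csp(class_covariances(permuted$data, eeg$labels), V = 2L)
  for (j in 1:4) {
    a <- m1$W[perm, j]; b <- m2$W[, j]
    expect_equal(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1,
                 tolerance = 1e-8)
  }
})

test_that("mismatched feature extraction inputs are rejected", {
  sim <- simulate_mi_eeg(sim_config(n_channels = 4L, informative_channels = 1:2,
                                    trials_per_class = 5L, trial_len_s = 2,
                                    seed = 29L))
  sb <- apply_filterbank(sim$epoched)
  model <- fit_multiband(sb, V = 1L)
  sb2 <- apply_filterbank(sim$epoched,
                          filterbank_spec(list(c(8, 13), c(13, 22))))
  expect_error(extract_features(sb2, model), "bands")
})
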