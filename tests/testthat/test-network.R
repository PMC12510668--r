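test_that("decoder code schemes impose the documented column norms", {
  nm <- sample_decoder(6, 40, code = "M", seed = 1)
  expect_lt(max(abs(sqrt(colSums(nm$D^2)) - 1)), 1e-12)
  # conjunctive: every 2-row pair of every column at norm 1/sqrt(Y/2)
  nc <- sample_decoder(4, 40, code = "C", seed = 2)
  for (j in 1:2) {
    rows <- (j - 1) * 2 + 1:2
    expect_lt(max(abs(sqrt(colSums(nc$D[rows, ]^2)) - 1 / sqrt(2))), 1e-12)
  }
  expect_lt(max(abs(sqrt(colSums(nc$D^2)) - 1)), 1e-12)
  # conjunctive-mixed: positional pairs equal, block norms 1/sqrt(2) each
  ncm <- sample_decoder(8, 40, code = "CM", seed = 3, p_rows = 4)
  expect_lt(max(abs(sqrt(colSums(ncm$D[1:4, ]^2)) - 1 / sqrt(2))), 1e-12)
  expect_lt(max(abs(sqrt(colSums(ncm$D[5:8, ]^2)) - 1 / sqrt(2))), 1e-12)
  expect_lt(max(abs(sqrt(colSums(ncm$D[1:2, ]^2)) - 1 / sqrt(4))), 1e-12)
  # pure-and-mixed: zero blocks where prescribed, unit columns overall
  np <- sample_decoder(4, 20, code = "pM", seed = 4, p_rows = 2,
                       pure_P = 5, pure_C = 3)
  expect_true(all(np$D[3:4, 1:5] == 0))
  expect_true(all(np$D[1:2, 6:8] == 0))
  expect_lt(max(abs(sqrt(colSums(np$D^2)) - 1)), 1e-12)
  expect_error(sample_decoder(4, 10, code = "pM", p_rows = 2,
                              pure_P = 8, pure_C = 8), "exceeds")
  expect_error(sample_decoder(8, 4, code = "M"), "at least as many")
})

test_that("default thresholds are half the squared column norms", {
  D <- random_unit_decoder(4, 12, seed = 5)
  expect_equal(default_thresholds(D), rep(0.5, 12), tolerance = 1e-12)
  D2 <- D
  D2[, 3] <- 2 * D2[, 3]
  expect_equal(default_thresholds(D2)[3], 2, tolerance = 1e-12)
  expect_equal(default_thresholds(diag(6)), rep(0.5, 6))
})

test_that("threshold modulation suppresses the right number of neurons", {
  T0 <- rep(0.5, 48)
  m1 <- modulate_thresholds(T0, spar = 1, seed = 1)
  expect_identical(m1$T, T0)
  expect_length(m1$suppressed, 0)
  m0 <- modulate_thresholds(T0, spar = 0, seed = 1)
  expect_true(all(m0$T == 10))
  mh <- modulate_thresholds(T0, spar = 0.5, seed = 1)
  expect_length(mh$suppressed, 24)
  expect_true(all(mh$T[mh$suppressed] == 10))
  expect_true(all(mh$T[-mh$suppressed] == 0.5))
  expect_error(modulate_thresholds(T0, spar = 1.5), "spar")
})

test_that("solver matches the separable closed form for diagonal decoders", {
  r <- solve_rates(c(0.7, 0.2), diag(2), c(0.5, 0.5))
  expect_equal(r, c(0.2, 0), tolerance = 1e-12)
  set.seed(8)
  y <- rnorm(6, sd = 2)
  T <- runif(6, 0.1, 1)
  r <- solve_rates(y, diag(6), T)
  expect_equal(r, pmax(y - T, 0), tolerance = 1e-12)
  expect_equal(solve_rates(rep(0, 6), diag(6), T), rep(0, 6))
})

test_that("solver matches the brute-force active-set enumeration oracle", {
  set.seed(21)
  worst_obj <- 0
  worst_kkt <- 0
  for (i in 1:200) {
    Y <- sample(2:4, 1)
    N <- sample(6:10, 1)
    D <- random_unit_decoder(Y, N, seed = 1000 + i)
    y <- rnorm(Y, sd = 2)
    T <- runif(N, 0.2, 0.8)
    r <- solve_rates(y, D, T)
    oracle <- brute_force_nnqp(D, y, T)
    worst_obj <- max(worst_obj,
                     abs(nnqp_objective(r, D, y, T) - oracle$objective))
    worst_kkt <- max(worst_kkt, kkt_residual(y, D, T, r))
  }
  expect_lt(worst_obj, 1e-8)
  expect_lt(worst_kkt, 1e-6)
})

test_that("solver satisfies KKT on larger random instances", {
  set.seed(31)
  for (i in 1:20) {
    D <- random_unit_decoder(6, 32, seed = 2000 + i)
    y <- rnorm(6, sd = 3)
    T <- rep(0.5, 32)
    r <- solve_rates(y, D, T)
    expect_true(all(r >= 0))
    expect_lt(kkt_residual(y, D, T, r), 1e-6)
  }
})

test_that("permuting neurons permutes the solution identically", {
  D <- random_unit_decoder(4, 16, seed = 77)
  y <- rnorm(4, sd = 2)
  T <- runif(16, 0.3, 0.7)
  r <- solve_rates(y, D, T)
  perm <- sample(16)
  r_perm <- solve_rates(y, D[, perm], T[perm])
  expect_equal(r_perm, r[perm], tolerance = 1e-9)
})

test_that("raising a neuron's threshold never increases its rate", {
  set.seed(55)
  for (i in 1:15) {
    D <- random_unit_decoder(4, 12, seed = 300 + i)
    y <- rnorm(4, sd = 2)
    T <- rep(0.5, 12)
    r0 <- solve_rates(y, D, T)
    j <- which.max(r0)
    T2 <- T
    T2[j] <- T[j] + runif(1, 0.1, 1)
    r1 <- solve_rates(y, D, T2)
    expect_lte(r1[j], r0[j] + 1e-9)
  }
})

test_that("batch solve fills the rate-map invariants", {
  D <- random_unit_decoder(4, 24, seed = 9)
  T <- default_thresholds(D)
  Ymat <- matrix(rnorm(4 * 15, sd = 2), 4)
  rm <- batch_solve(Ymat, D, T)
  expect_true(all(rm$rates >= 0))
  expect_equal(rm$decoded, D %*% rm$rates, tolerance = 1e-12)
  expect_lt(max(abs(D %*% rm$null_component)), 1e-8)
  # constant input gives identical rate columns
  rc <- batch_solve(matrix(rep(Ymat[, 1], 5), 4), D, T)
  expect_lt(max(abs(rc$rates - rc$rates[, 1])), 1e-9)
})

test_that("pseudo-inverse encoder satisfies its defining identities", {
  D <- random_unit_decoder(5, 20, seed = 10)
  E <- pseudo_inverse_encoder(D)
  expect_lt(max(abs(D %*% E - diag(5))), 1e-10)
  P <- E %*% D
  expect_lt(max(abs(P %*% P - P)), 1e-8)
  # orthonormal rows: E is just the transpose
  Do <- orthonormal_row_decoder(3, 10, seed = 11)
  expect_equal(pseudo_inverse_encoder(Do), t(Do), tolerance = 1e-10)
  expect_error(pseudo_inverse_encoder(matrix(0, 2, 4)), "rank")
})

test_that("decoding latents inverts the encoder when rates have no null part", {
  D <- random_unit_decoder(4, 16, seed = 12)
  E <- pseudo_inverse_encoder(D)
  z <- rnorm(4)
  dec <- decode_latents(E %*% z, D)
  expect_equal(drop(dec$y_hat), z, tolerance = 1e-10)
  m <- sample_multichart_map(4, 2, seed = 13)
  dec2 <- decode_latents(E %*% (m$R %*% c(1, 0)), D, map = m)
  expect_equal(drop(dec2$z_hat), c(1, 0), tolerance = 1e-10)
})
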