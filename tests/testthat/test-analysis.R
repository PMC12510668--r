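test_that("preprocessing zeroes sub-threshold rates and computes means", {
  rates <- matrix(c(5e-4, 2e-3, 0.5, 0.5, 0, 0), 3, 2, byrow = TRUE)
  pp <- preprocess_ratemaps(rates)
  expect_equal(pp$rates[1, ], c(0, 2e-3))
  expect_equal(pp$rates[2, ], c(0.5, 0.5))
  expect_equal(pp$mean[2], 0.5)
  expect_error(preprocess_ratemaps(matrix(-1, 1, 1)), "nonnegative")
})

test_that("overlap is the cosine of mean vectors with the expected edge cases", {
  v <- c(1, 2, 3, 0)
  expect_equal(overlap(v, v), 1)
  expect_equal(overlap(c(1, 0, 2, 0), c(0, 3, 0, 4)), 0)
  expect_error(overlap(v, rep(0, 4)), "zero vector")
  # exchangeable vector: every permutation identical, shuffle overlap exactly 1
  expect_equal(overlap_shuffle(rep(2, 8), rep(2, 8), seed = 1), 1)
  # shuffle is permutation-equivariant in distribution: relabeling the neurons
  # leaves the shuffle mean unchanged up to Monte Carlo error
  set.seed(3)
  a <- runif(12); b <- runif(12)
  perm <- sample(12)
  expect_equal(overlap_shuffle(a, b, n_shuffle = 4000L, seed = 5),
               overlap_shuffle(a[perm], b[perm], n_shuffle = 4000L, seed = 6),
               tolerance = 0.01)
  # overlap is symmetric
  expect_equal(overlap(a, b), overlap(b, a))
})

test_that("spatial correlation averages co-active neurons only", {
  A <- rbind(c(1, 0, 0, 0), c(0, 1, 1, 0), c(0.2, 0.2, 0.2, 0.2))
  B <- rbind(c(0, 0, 0, 0),   # silent in B: excluded
             c(0, 1, 1, 0),   # identical map
             c(0.2, 0.2, 0.2, 0.2))
  expect_equal(spatial_correlation(A, B), 1, tolerance = 1e-12)
  # a co-active neuron with disjoint-support fields contributes 0
  A2 <- rbind(c(1, 1, 0, 0), c(1, 1, 1, 1))
  B2 <- rbind(c(0, 0, 1, 1), c(1, 1, 1, 1))
  expect_equal(spatial_correlation(A2, B2), 0.5, tolerance = 1e-12)
  expect_equal(spatial_correlation(A2, B2), spatial_correlation(B2, A2))
  expect_error(spatial_correlation(matrix(0, 2, 3), matrix(1, 2, 3)),
               "active in both")
  # all identical maps: shuffle also 1 exactly
  C3 <- matrix(1, 5, 4)
  expect_equal(spatial_correlation_shuffle(C3, C3, seed = 2), 1)
})

test_that("significance testing follows the Bonferroni-corrected one-sample t-test", {
  # all pair means equal the shuffle mean: t = 0, p = 1
  s0 <- significance(rep(0.4, 10), 0.4)
  expect_equal(s0$p_value, 1)
  expect_false(s0$significant)
  # threshold arithmetic
  expect_equal(significance(c(0.1, 0.2, 0.3), 0.2, n_tests = 21)$p_thresh,
               0.05 / 21, tolerance = 1e-12)
  # power sanity check: means 5 sd above the shuffle mean, 45 pairs
  set.seed(17)
  x <- rnorm(45, mean = 0.3 + 5 * 0.02, sd = 0.02)
  s1 <- significance(x, 0.3)
  expect_true(s1$significant)
  expect_equal(s1$direction, 1)
  expect_error(significance(0.5, 0.3), "at least two")
})

test_that("remapping-norm decomposition is exact for orthonormal encoders", {
  D <- orthonormal_row_decoder(4, 16, seed = 19)
  E <- pseudo_inverse_encoder(D)
  set.seed(20)
  A <- matrix(runif(16 * 30), 16)
  B <- matrix(runif(16 * 30), 16)
  nm <- remap_norms(A, B, D, E, p_rows = 2)
  expect_true(all(unlist(nm) >= 0))
  # Pythagoras: total^2 = decoded^2 + null^2 with orthonormal E columns
  lhs <- nm$total^2
  rhs <- nm$spatial^2 + nm$cognitive^2 + nm$null_space^2
  expect_lt(abs(lhs - rhs) / lhs, 1e-6)
  # identical maps give all-zero norms
  nz <- remap_norms(A, A, D, E, p_rows = 2)
  expect_true(all(unlist(nz) == 0))
  # C = 0 layout reports cognitive as zero
  n0 <- remap_norms(A, B, D, E, p_rows = NULL)
  expect_equal(n0$cognitive, 0)
})

test_that("place-field statistics follow the peak-fraction definition", {
  # one neuron active on exactly 10% of positions
  r <- matrix(0, 2, 100)
  r[1, 1:10] <- 1
  st <- place_field_stats(r)
  expect_equal(st$pct_active, 50)
  expect_equal(unname(st$field_size_pct["1"]), 10)
  # a neuron active everywhere has a 100% field
  r2 <- matrix(1, 1, 50)
  expect_equal(place_field_stats(r2)$mean_field_size_pct, 100)
  # silent population
  s0 <- place_field_stats(matrix(0, 3, 10))
  expect_equal(s0$pct_active, 0)
  expect_true(is.na(s0$mean_field_size_pct))
  # sub-peak positions below the fraction cutoff are excluded
  r3 <- matrix(c(1, 1, 0.05, 0.05), 1)
  expect_equal(place_field_stats(r3, field_fraction = 0.1)$mean_field_size_pct, 50)
})

test_that("pairwise analysis aggregates statistics and flags silent environments", {
  set.seed(23)
  D <- random_unit_decoder(3, 18, seed = 23)
  E <- pseudo_inverse_encoder(D)
  maps <- lapply(1:4, function(k) matrix(runif(18 * 12), 18))
  maps[[4]] <- matrix(0, 18, 12) # silent environment
  st <- analyze_ratemaps(maps, D, E, seed = 1)
  expect_s3_class(st, "remapping_stats")
  expect_equal(nrow(st$pairs), 6)
  silent_rows <- st$pairs$env_a == 4 | st$pairs$env_b == 4
  expect_true(all(is.na(st$pairs$overlap[silent_rows])))
  expect_true(all(st$pairs$note[silent_rows] == "silent environment"))
  expect_equal(st$summary$n_pairs_used, 3)
  expect_true(all(st$pairs$overlap[!silent_rows] >= 0 &
                    st$pairs$overlap[!silent_rows] <= 1))
  # vs_first pairing compares everything against environment 1
  st1 <- analyze_ratemaps(maps[1:3], D, E, pairs = "vs_first", seed = 1)
  expect_equal(st1$pairs$env_a, c(1, 1))
  expect_equal(st1$pairs$env_b, c(2, 3))
})
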