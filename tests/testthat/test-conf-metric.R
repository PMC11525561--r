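test_that("distance series reproduces textbook geometry and units", {
  # 3-4-5 triangle: 5 Angstrom = 0.5 nm
  tr <- make_pair_trajectory(rbind(c(0, 0, 0), c(0, 0, 0)),
                             rbind(c(3, 4, 0), c(0, 0, 0)))
  s_nm <- distance_series(tr)
  expect_equal(s_nm$values, c(0.5, 0))  # coincident CAs give exactly 0
  expect_equal(s_nm$unit, "nm")
  s_a <- distance_series(tr, unit = "angstrom")
  expect_equal(s_a$values, c(5, 0))
  expect_equal(s_nm$pair_label, "CYS50-ASN65")
})

test_that("distance matches a brute-force recomputation on random frames", {
  set.seed(31)
  ca <- matrix(rnorm(300, sd = 10), 100, 3)
  cb <- matrix(rnorm(300, sd = 10), 100, 3)
  tr <- make_pair_trajectory(ca, cb)
  got <- distance_series(tr, unit = "angstrom")$values
  manual <- vapply(1:100, function(i)
    sqrt(sum((ca[i, ] - cb[i, ])^2)), numeric(1))
  expect_lt(max(abs(got - manual) / manual), 1e-12)
  # symmetry is exact
  expect_identical(got, distance_series(tr, residue_a = 65, residue_b = 50,
                                        unit = "angstrom")$values)
})

test_that("distances are invariant under rigid-body transforms", {
  set.seed(32)
  tr <- make_pair_trajectory(matrix(rnorm(60, sd = 5), 20, 3),
                             matrix(rnorm(60, sd = 5) + 10, 20, 3))
  d0 <- distance_series(tr)$values
  for (rep in 1:5) {
    tr2 <- rigid_transform(tr, random_rotation(), rnorm(3, sd = 50))
    d1 <- distance_series(tr2)$values
    expect_lt(max(abs(d1 - d0) / d0), 1e-9)
  }
})

test_that("window selection is half-open and matches a counting oracle", {
  s <- series_from_values(rnorm(200, 2, 0.1))  # times 0..199
  w <- window_select(s, 100, 200)
  expect_equal(w$times, 100:199)            # exactly the second half
  expect_equal(w$values, s$values[101:200])
  # "half".."end" shorthand selects the last half including the final frame
  w2 <- window_select(s, "half", "end")
  expect_equal(w2$times, window_select(s, 99.5, 199.5 + 1)$times)
  # full span is the identity
  full <- window_select(s, 0, "end")
  expect_equal(full$values, s$values)
  # retained count equals a brute-force count for arbitrary windows
  for (win in list(c(13.5, 77), c(0, 1), c(150, 199.2))) {
    expect_equal(length(window_select(s, win[1], win[2])$values),
                 sum(s$times >= win[1] & s$times < win[2]))
  }
  expect_error(window_select(s, 500, 600), "spans \\[0, 199\\]")
})

test_that("block summary has the stated closed-form behaviour", {
  s_const <- series_from_values(rep(2, 100))
  b <- block_summary(s_const, 10)
  expect_equal(b$mean, 2)
  expect_equal(b$sem, 0)
  expect_equal(b$n, 10L)
  # member means {1,2,3}: mean 2, SEM = SD/sqrt(3) = 1/sqrt(3)
  b3 <- block_summary(series_from_values(c(1, 2, 3)), 3)
  expect_equal(b3$member_means, c(1, 2, 3))
  expect_equal(b3$mean, 2)
  expect_equal(b3$sem, 1 / sqrt(3))
})

test_that("block partition matches direct recomputation, remainder to last block", {
  set.seed(33)
  v <- rnorm(103, 5, 0.5)  # 103 frames, 10 blocks -> 9 blocks of 10 + last of 13
  b <- block_summary(series_from_values(v), 10)
  direct <- c(vapply(0:8, function(k) mean(v[(10 * k + 1):(10 * k + 10)]),
                     numeric(1)), mean(v[91:103]))
  expect_lt(max(abs(b$member_means - direct)), 1e-12)
  expect_equal(b$mean, mean(direct))
  expect_equal(b$sem, sd(direct) / sqrt(10))
  # n_blocks = frame count degenerates to per-frame values
  bf <- block_summary(series_from_values(v), length(v))
  expect_equal(bf$member_means, v)
  expect_lt(abs(bf$mean - mean(v)), 1e-12)
  expect_error(block_summary(series_from_values(v), 104), "exceeds")
  expect_error(block_summary(series_from_values(v), 1), ">= 2")
})

test_that("replicate summary reproduces the closed-form example", {
  reps <- lapply(c(2.0, 2.1, 2.2, 2.3, 2.4), function(m)
    series_from_values(rep(m, 20)))
  r <- replicate_summary(reps, window = "last_half")
  expect_equal(r$member_means, c(2.0, 2.1, 2.2, 2.3, 2.4))
  expect_equal(r$mean, 2.2)
  expect_equal(r$sem, sd(c(2.0, 2.1, 2.2, 2.3, 2.4)) / sqrt(5))
  expect_equal(round(r$sem, 4), 0.0707)
  # identical replicates: SEM exactly 0
  same <- replicate_summary(lapply(1:5, function(i) series_from_values(rep(2, 20))))
  expect_equal(same$sem, 0)
  # a replicate with an empty window is named in the error
  short <- series_from_values(rep(2, 5), rep_id = "odd-one")
  expect_error(replicate_summary(list(series_from_values(rep(2, 20)), short),
                                 window = c(10, 20)),
               "odd-one")
})

test_that("replicate summary covers the OU stationary mean", {
  hits <- vapply(1:50, function(seed) {
    tr <- gen_trajectory(mean_distance = 2, stationary_sd = 0.1,
                         correlation_time = 5, n_frames = 100,
                         n_replicates = 5, seed = seed)
    r <- replicate_summary(lapply(tr, distance_series))
    abs(r$mean - 2) <= 3 * r$sem
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("block SEM is unbiased for i.i.d. data", {
  # 1000 simulated white-noise series: the mean of the block-SEM estimates
  # must match the empirical SD of the series means within 10%
  set.seed(34)
  sems <- numeric(1000); means <- numeric(1000)
  for (i in 1:1000) {
    b <- block_summary(series_from_values(rnorm(100, 5, 0.5)), 10)
    sems[i] <- b$sem; means[i] <- b$mean
  }
  expect_lt(abs(mean(sems) / sd(means) - 1), 0.10)
})

test_that("summary tables serialize member means as JSON", {
  b <- block_summary(series_from_values(c(1, 2, 3)), 3)
  tab <- summary_table(list(b), labels = "demo")
  expect_equal(tab$n, 3L)
  expect_equal(jsonlite::fromJSON(tab$member_means), c(1, 2, 3))
  expect_equal(tab$unit, "nm")
})
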