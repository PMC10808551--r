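test_that("spatial information matches the literal-formula oracle", {
  set.seed(101)
  beh <- constant_run(speed = 17, laps = 6)
  n <- nrow(beh)
  for (i in 1:100) {
    a <- rexp(n, 1 / (0.1 + runif(1)))
    m <- spatial_map(a, beh$position, rep(TRUE, n))
    got <- spatial_information(m)$si
    want <- si_oracle(m$lambda[m$occupied], m$p[m$occupied] /
                        sum(m$p[m$occupied]))
    expect_lt(abs(got - want), 1e-10)
  }
})

test_that("two-bin analytic case gives exactly 1 bit", {
  m <- map_from_values(c(2, 0), p = c(0.5, 0.5))
  expect_equal(spatial_information(m)$si, 1.0)
  # uniform map carries zero information
  mu <- map_from_values(rep(3, 80))
  expect_equal(spatial_information(mu)$si, 0)
})

test_that("SI scales linearly with the map while si_norm is invariant", {
  set.seed(7)
  lam <- rexp(80)
  m1 <- map_from_values(lam, mean_activity = mean(lam))
  m2 <- map_from_values(5 * lam, mean_activity = 5 * mean(lam))
  s1 <- spatial_information(m1); s2 <- spatial_information(m2)
  expect_equal(s2$si, 5 * s1$si, tolerance = 1e-12)
  expect_equal(s2$si_norm, s1$si_norm, tolerance = 1e-12)
})

test_that("SI is nonnegative and zero only for uniform maps", {
  set.seed(8)
  for (i in 1:50) {
    m <- map_from_values(rexp(40))
    expect_gte(spatial_information(m)$si, 0)
  }
  expect_equal(spatial_information(map_from_values(rep(1, 40)))$si, 0)
})

test_that("negative bin means are clamped and reported", {
  m <- map_from_values(c(-0.5, 2, 1, 0.5))
  s <- spatial_information(m)
  expect_true(is.finite(s$si))
  expect_equal(s$clamped_fraction, 0.25)
  expect_gte(s$si, 0)
})

test_that("coherence reflects local smoothness of the map", {
  theta <- 2 * pi * (seq_len(80) - 0.5) / 80
  smooth <- map_from_values(2 + sin(theta))
  expect_gt(spatial_coherence(smooth), 0.95)
  set.seed(11)
  rs <- replicate(50, spatial_coherence(map_from_values(rnorm(80, 5, 1))))
  expect_lt(abs(mean(rs)), 0.1)  # iid noise: near zero on average
  expect_true(is.na(spatial_coherence(map_from_values(rep(2, 80)))))
})

test_that("vector tuning follows circular-statistics closed forms", {
  # single active bin at angle pi/2
  lam <- rep(0, 80); lam[20] <- 4  # bin 20 center = 97.5 cm
  m <- map_from_values(lam)
  vt <- vector_tuning(m)
  expect_equal(vt$vector_length, 1)
  expect_equal(vt$vector_angle, 2 * pi * 97.5 / 400, tolerance = 1e-12)
  # uniform map has zero resultant
  expect_lt(vector_tuning(map_from_values(rep(1, 80)))$vector_length, 1e-12)
  # von Mises map: length ~ I1(kappa)/I0(kappa)
  for (kappa in c(0.5, 2, 8)) {
    theta <- 2 * pi * (seq_len(80) - 0.5) / 80
    vm <- map_from_values(exp(kappa * cos(theta - 1)))
    expect_equal(vector_tuning(vm)$vector_length,
                 besselI(kappa, 1) / besselI(kappa, 0), tolerance = 1e-3)
  }
})

test_that("vector tuning is rotation-equivariant", {
  set.seed(12)
  lam <- rexp(80)
  m <- map_from_values(lam)
  k <- 11
  mrot <- map_from_values(lam[((seq_len(80) - 1 - k) %% 80) + 1])
  v0 <- vector_tuning(m); v1 <- vector_tuning(mrot)
  expect_equal(v1$vector_length, v0$vector_length, tolerance = 1e-12)
  expect_equal((v1$vector_angle - v0$vector_angle) %% (2 * pi),
               2 * pi * k / 80, tolerance = 1e-9)
})

test_that("stability is the zero-lag correlation of half maps", {
  set.seed(13)
  lam <- rexp(80)
  m1 <- map_from_values(lam)
  expect_equal(within_session_stability(m1, m1), 1)
  flipped <- map_from_values(2 * mean(lam) - lam)
  expect_equal(within_session_stability(m1, flipped), -1)
})

test_that("speed tuning recovers an exact linear relation", {
  set.seed(14)
  speed <- runif(2000, 0, 25)
  dff <- 0.1 * speed
  st <- speed_tuning(dff, speed, fs = 10)
  expect_equal(st$slope, 0.1, tolerance = 1e-10)
  expect_equal(st$pearson_r, 1, tolerance = 1e-10)
  expect_equal(st$modulation_class, "positive")
  g <- glance(st)
  expect_equal(g$slope, st$slope)
  # negative relation classified negative
  stn <- speed_tuning(1 - 0.02 * speed, speed, fs = 10)
  expect_equal(stn$modulation_class, "negative")
})

test_that("speed-independent activity is classed 'none' at about alpha", {
  set.seed(15)
  cls <- replicate(200, {
    speed <- runif(400, 0, 25)
    speed_tuning(rnorm(400), speed, fs = 10)$modulation_class
  })
  # false-positive fraction within a generous binomial band around 0.05
  expect_lt(mean(cls != "none"), 0.12)
})

test_that("sparse speed bins are dropped from the binned fit", {
  speed <- c(rep(5.5, 100), rep(6.5, 100), rep(24.5, 3))
  dff <- c(rep(1, 100), rep(2, 100), rep(100, 3))
  st <- speed_tuning(dff, speed, min_bin_time = 1, fs = 10)
  expect_equal(nrow(st$bins), 2)  # the 3-frame bin is excluded
  expect_equal(st$slope, 1, tolerance = 1e-10)
})

test_that("moving/immobile ratio follows its definition", {
  act <- c(rep(2, 50), rep(4, 50))
  moving <- c(rep(TRUE, 50), rep(FALSE, 50))
  expect_equal(move_immobile_ratio(act, moving, !moving), 0.5)
  expect_equal(move_immobile_ratio(rep(3, 100), moving, !moving), 1)
  expect_true(is.na(move_immobile_ratio(act, rep(TRUE, 100),
                                        rep(FALSE, 100))))
})
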