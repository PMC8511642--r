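test_that("two-parameter fit inverts noiseless decays", {
  f <- fit2(100 * exp(-c(0, 25, 55) / 46), c(0, 25, 55))
  expect_true(f$valid)
  expect_equal(f$t2_ms, 46, tolerance = 1e-6)
  expect_equal(f$a, 100, tolerance = 1e-4)
  # two points: exact log-ratio solution
  f2 <- fit2(c(80, 30), c(10, 40))
  expect_equal(f2$t2_ms, 30 / log(80 / 30), tolerance = 1e-12)
  # rising signals are masked invalid, not an error
  expect_false(fit2(c(10, 20, 30), c(0, 25, 55))$valid)
  expect_error(fit2(c(1, 2), c(5, 5)), "increasing")
})

test_that("three-parameter fit solves exact triples and nests fit2", {
  f <- fit3(80 * exp(-c(0, 30, 60) / 50) + 20, c(0, 30, 60))
  expect_true(f$valid)
  expect_equal(f$a, 80, tolerance = 1e-6)
  expect_equal(f$b, 20, tolerance = 1e-6)
  expect_equal(f$t2_ms, 50, tolerance = 1e-6)
  # degenerate flat signals are invalid
  expect_false(fit3(c(5, 5, 5), c(0, 30, 60))$valid)
  # B = 0 data agree with the two-parameter model
  set.seed(21)
  for (i in 1:20) {
    t2 <- runif(1, 20, 300); A <- runif(1, 10, 200)
    s <- A * exp(-c(0, 30, 60) / t2)
    expect_equal(fit3(s, c(0, 30, 60))$t2_ms,
                 fit2(s, c(0, 30, 60))$t2_ms, tolerance = 1e-6)
  }
})

test_that("noisy offset fits match a brute-force grid-search oracle", {
  set.seed(9)
  n <- 10000
  t <- c(0, 30, 60)
  true_t2 <- 50
  clean <- 80 * exp(-t / true_t2) + 20
  sigma <- 0.02 * clean[1]
  # Rician-like magnitude noise
  S <- t(vapply(seq_len(n), function(i) {
    sqrt((clean + rnorm(3, sd = sigma))^2 + rnorm(3, sd = sigma)^2)
  }, numeric(3)))
  fits <- vapply(seq_len(n), function(i) fit3(S[i, ], t)$t2_ms, numeric(1))
  # oracle: profiled least squares on a T2 grid of step 0.01 ms
  grid <- seq(1, 500, by = 0.01)
  E <- cbind(exp(outer(-1 / grid, t[1])), exp(outer(-1 / grid, t[2])),
             exp(outer(-1 / grid, t[3])))
  se <- rowSums(E); see <- rowSums(E^2)
  det <- 3 * see - se^2
  oracle <- vapply(seq_len(n), function(i) {
    sy <- sum(S[i, ]); sey <- E %*% S[i, ]
    A <- (3 * sey - se * sy) / det
    B <- (sy - A * se) / 3
    sse <- rowSums((matrix(S[i, ], nrow = length(grid), ncol = 3,
                           byrow = TRUE) - A %*% t(rep(1, 3)) * E -
                      matrix(B, length(grid), 3))^2)
    grid[which.min(sse)]
  }, numeric(1))
  expect_lt(abs(median(fits, na.rm = TRUE) - median(oracle)) /
              median(oracle), 0.02)
})

test_that("map fitting inverts synthetic prep volumes voxel-wise", {
  set.seed(10)
  M <- 10
  t2v <- array(46, rep(M, 3)); t2v[3:5, 3:5, 3:5] <- 120
  A <- array(1, rep(M, 3)); B <- array(0.1, rep(M, 3))
  times <- c(0, 30, 60)
  vols <- lapply(times, function(t) A * exp(-t / t2v) + B)
  map <- map_volume(vols, times_ms = times, voxel_mm = 2)
  expect_true(all(map$mask))
  expect_lt(max(abs(map$t2_ms - t2v)), 0.01)
  # explicit mask excludes voxels from fitting
  msk <- array(TRUE, rep(M, 3)); msk[1, , ] <- FALSE
  map2 <- map_volume(vols, times_ms = times, mask = msk)
  expect_true(all(is.na(map2$t2_ms[1, , ])))
  expect_true(all(!map2$mask[1, , ]))
})

test_that("voxel-wise fitting commutes with voxel permutations", {
  set.seed(12)
  M <- 6
  t2v <- array(runif(M^3, 30, 200), rep(M, 3))
  times <- c(0, 30, 60)
  vols <- lapply(times, function(t) exp(-t / t2v) + 0.05)
  perm <- sample(M^3)
  vols_p <- lapply(vols, function(v) array(as.vector(v)[perm], rep(M, 3)))
  m1 <- map_volume(vols, times_ms = times,
                   mask = array(TRUE, rep(M, 3)))
  m2 <- map_volume(vols_p, times_ms = times,
                   mask = array(TRUE, rep(M, 3)))
  expect_equal(as.vector(m2$t2_ms), as.vector(m1$t2_ms)[perm],
               tolerance = 1e-9)
})

test_that("region statistics implement the coefficient of variation", {
  M <- 4
  t2 <- array(NA_real_, rep(M, 3))
  t2[1, 1, 1:3] <- c(40, 50, 60)
  map <- structure(list(t2_ms = t2, a = t2, b = t2,
                        mask = !is.na(t2), residual = t2 * 0,
                        model = "three_param", times_ms = c(0, 30, 60),
                        voxel_mm = 1), class = "t2_map")
  roi <- !is.na(t2)
  st <- region_stats(map, roi)
  expect_equal(st$mean_t2_ms, 50)
  expect_equal(st$sd_t2_ms, 10)
  expect_equal(st$cov_percent, 20)
  # constant region: zero CoV; scaling leaves CoV unchanged
  map$t2_ms[1, 1, 1:3] <- 70
  expect_equal(region_stats(map, roi)$cov_percent, 0)
  map$t2_ms[1, 1, 1:3] <- 3.7 * c(40, 50, 60)
  expect_equal(region_stats(map, roi)$cov_percent, 20, tolerance = 1e-12)
  expect_error(region_stats(map, roi & FALSE), "2 valid")
})

# synthetic map with a sigmoid edge along x
sigmoid_map <- function(M = 32, a = 200, b = -5, c0 = 45, k = 1.5,
                        voxel_mm = 1) {
  x_mm <- (seq_len(M) - 1) * voxel_mm
  prof <- a / (1 + exp(-k * (b + x_mm))) + c0
  t2 <- array(rep(prof, times = M * M), rep(M, 3))
  structure(list(t2_ms = t2, a = t2 * 0 + 1, b = NULL,
                 mask = array(TRUE, rep(M, 3)), residual = t2 * 0,
                 model = "three_param", times_ms = c(0, 30, 60),
                 voxel_mm = voxel_mm), class = "t2_map")
}

test_that("the sigmoid profile fit is exact on noiseless profiles", {
  x <- seq(0, 20, by = 0.5)
  y <- 200 / (1 + exp(-1.5 * (-5 + x))) + 45
  cf <- fit_sigmoid(x, y)
  expect_equal(unname(cf["k"]), 1.5, tolerance = 1e-6)
  expect_equal(unname(cf["a"]), 200, tolerance = 1e-4)
  expect_equal(unname(cf["c"]), 45, tolerance = 1e-5)
  expect_null(fit_sigmoid(x, rep(50, length(x))))   # flat profile
})

test_that("sigmoid sharpness recovers a known edge steepness from a map", {
  # voxels fine relative to the edge width; the residual deviation is the
  # trilinear sampling of the gridded map
  map <- sigmoid_map(M = 48, a = 200, b = -5, c0 = 45, k = 1.5,
                     voxel_mm = 0.25)
  fit <- sharpness(map, c(1, 24, 24), c(45, 24, 24))
  expect_true(fit$valid)
  expect_equal(length(fit$k_per_line), 5)
  expect_equal(fit$mean_k, 1.5, tolerance = 0.01)
  expect_false(fit$saturated)
})

test_that("an ideal step edge saturates the sharpness bound", {
  M <- 32
  t2 <- array(45, rep(M, 3)); t2[16:M, , ] <- 245
  map <- sigmoid_map(M)
  map$t2_ms <- t2
  fit <- sharpness(map, c(6, 16, 16), c(26, 16, 16))
  expect_true(fit$saturated)
  expect_gt(max(fit$k_per_line), 10)
})

test_that("added blur strictly reduces the measured sharpness", {
  map <- sigmoid_map(M = 32, k = 2)
  blurred <- map
  blurred$t2_ms <- gaussian_blur3(map$t2_ms, 1)
  k0 <- sharpness(map, c(1, 16, 16), c(25, 16, 16))$mean_k
  k1 <- sharpness(blurred, c(1, 16, 16), c(25, 16, 16))$mean_k
  expect_lt(k1, k0)
})

test_that("voxel volume ratio of the 2D and 3D protocols rounds to seven", {
  r <- voxel_volume_ratio(c(1.9, 1.9, 8), 1.6)
  expect_equal(r$ratio, (1.9 * 1.9 * 8) / 1.6^3)
  expect_identical(r$ratio_rounded, 7)
})
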