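test_that("rasterize paints tissues in order and handles shells", {
  M <- 16
  box_spec <- phantom_spec(
    matrix = M, fov_mm = 160,
    tissues = list(list(name = "all", t1_ms = 800, t2_ms = 50, pd = 1,
                        geometry = list(type = "box", center = c(0, 0, 0),
                                        size = c(160, 160, 160)))),
    n_coils = 1)
  maps <- rasterize(box_spec)
  expect_true(all(maps$pd == 1))        # full-FOV box covers every voxel
  expect_true(all(maps$label == 1L))

  # shell voxel count equals outer count minus inner count
  mk <- function(geom) phantom_spec(
    matrix = M, fov_mm = 160,
    tissues = list(list(name = "t", t1_ms = 800, t2_ms = 50, pd = 1,
                        geometry = geom)), n_coils = 1)
  ctr <- c(10, -5, 0); outer_ax <- c(60, 50, 45); inner_ax <- c(40, 30, 25)
  n_outer <- sum(rasterize(mk(list(type = "ellipsoid", center = ctr,
                                   semiaxes = outer_ax)))$pd > 0)
  n_inner <- sum(rasterize(mk(list(type = "ellipsoid", center = ctr,
                                   semiaxes = inner_ax)))$pd > 0)
  n_shell <- sum(rasterize(mk(list(type = "shell", center = ctr,
                                   outer = outer_ax,
                                   inner = inner_ax)))$pd > 0)
  expect_identical(n_shell, n_outer - n_inner)
})

test_that("lesions overwrite T2 only, inside their sphere", {
  spec <- default_phantom_spec(matrix = 24)
  base <- rasterize(default_phantom_spec(matrix = 24, with_lesion = FALSE))
  with_l <- rasterize(spec)
  expect_identical(with_l$label, base$label)
  changed <- with_l$t2 != base$t2
  expect_true(all(changed == with_l$lesion_mask))
  expect_true(all(with_l$t2[with_l$lesion_mask] == 60))
  expect_identical(with_l$t1, base$t1)
  expect_identical(with_l$pd, base$pd)
})

test_that("phantom validation rejects bad geometry and relaxation", {
  expect_error(phantom_spec(tissues = list()), "empty")
  expect_error(phantom_spec(tissues = list(
    list(name = "x", t1_ms = 40, t2_ms = 50, pd = 1,
         geometry = list(type = "box", center = c(0, 0, 0),
                         size = c(10, 10, 10))))), "t1 > t2")
  expect_error(phantom_spec(tissues = list(
    list(name = "x", t1_ms = 800, t2_ms = 50, pd = 1,
         geometry = list(type = "box", center = c(200, 0, 0),
                         size = c(100, 10, 10))))), "FOV")
})

test_that("respiratory displacement is periodic with the right amplitude", {
  spec0 <- default_phantom_spec(
    respiration = list(amplitude_mm = 0, period_s = 4,
                       waveform = "sinusoid", ap_fraction = 0.3))
  t <- seq(0, 20000, by = 37)
  expect_true(all(respiratory_phase(spec0, t)$si_mm == 0))

  for (wf in c("sinusoid", "asymmetric")) {
    spec <- default_phantom_spec(
      respiration = list(amplitude_mm = 8, period_s = 3.5,
                         waveform = wf, ap_fraction = 0.25))
    d1 <- respiratory_phase(spec, t)
    d2 <- respiratory_phase(spec, t + 3500)
    expect_equal(d1$si_mm, d2$si_mm, tolerance = 1e-9)
    dense <- respiratory_phase(spec, seq(0, 3500, length.out = 20001))
    expect_lt(abs(max(dense$si_mm) - 8), 1e-4)
    expect_equal(d1$ap_mm, 0.25 * d1$si_mm)
  }
})

test_that("simulated k-space matches the brute-force DFT oracle", {
  sim <- static_ball_sim(M = 16, n_interleaves = 12)
  ks <- sim$kspace
  img <- attr(ks, "images")[[1]]
  # DC sample of the navigator line equals the image sum
  nav1 <- which(ks$headers$is_navigator & ks$headers$prep_index == 1)[1]
  dc <- ks$data[(ks$samples_per_line + 1) %/% 2, nav1, 1]
  expect_rel_error(Mod(dc), Mod(sum(img)), 1e-3)
  # 20 random lines against the brute-force non-uniform DFT
  set.seed(5)
  rows <- sample(which(ks$headers$prep_index == 1), 20)
  traj_rows <- cardiot2:::match_traj_rows(ks, rows)
  for (i in seq_along(rows)) {
    K <- line_sample_positions(sim$traj, traj_rows[i])
    y_ref <- brute_nudft(img, K)
    y <- ks$data[, rows[i], 1]
    expect_lt(max(Mod(y - y_ref)) / max(Mod(y_ref)), 1e-3)
  }
})

test_that("zero proton density gives identically zero samples", {
  spec <- phantom_spec(
    matrix = 16, fov_mm = 160,
    tissues = list(list(name = "ghost", t1_ms = 800, t2_ms = 50, pd = 0,
                        geometry = list(type = "box", center = c(0, 0, 0),
                                        size = c(100, 100, 100)))),
    respiration = list(amplitude_mm = 5, period_s = 4,
                       waveform = "sinusoid", ap_fraction = 0),
    noise_sd = 0, n_coils = 1, seed = 1)
  params <- sequence_params(n_interleaves = 6, heart_rate_bpm = 67)
  traj <- spiral_phyllotaxis(6, 49, samples_per_line = 17,
                             fov_mm = 160, matrix = 16)
  ks <- simulate_acquisition(spec, params, traj, build_schedule(params))
  expect_true(all(ks$data == 0))
})

test_that("the same seed reproduces the k-space bit-exactly", {
  spec <- default_phantom_spec(matrix = 16, n_coils = 2, seed = 99)
  params <- sequence_params(n_interleaves = 8, heart_rate_bpm = 67)
  traj <- spiral_phyllotaxis(8, 49, samples_per_line = 17,
                             fov_mm = 220, matrix = 16)
  sch <- build_schedule(params)
  k1 <- simulate_acquisition(spec, params, traj, sch)
  k2 <- simulate_acquisition(spec, params, traj, sch)
  expect_identical(k1$data, k2$data)
})

test_that("coil sensitivity maps are smooth with unit root-sum-of-squares", {
  s <- coil_sensitivity_maps(16, 4, fov_mm = 220)
  rss <- sqrt(apply(Mod(s)^2, 1:3, sum))
  expect_equal(max(abs(rss - 1)), 0, tolerance = 1e-12)
  expect_identical(dim(s), c(16L, 16L, 16L, 4L))
  s1 <- coil_sensitivity_maps(8, 1)
  expect_true(all(s1 == 1 + 0i))
})

test_that("noiseless gridded energy is close to image energy", {
  sim <- static_ball_sim(M = 24, n_interleaves = 64)
  rec <- adjoint_recon(sim$kspace, prep = 1)
  img <- attr(sim$kspace, "images")[[1]]
  expect_lt(abs(sum(Mod(rec)^2) / sum(Mod(img)^2) - 1), 0.1)
})
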