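test_that("forward NUFFT matches the brute-force DFT and the adjoint is exact", {
  set.seed(1)
  M <- 16
  plan <- nufft_plan(M)
  k <- matrix(runif(200 * 3, -M / 2, M / 2), ncol = 3)
  x <- array(complex(real = rnorm(M^3), imaginary = rnorm(M^3)),
             dim = rep(M, 3))
  y_ref <- brute_nudft(x, k)
  y <- nufft_forward(plan, x, k)
  expect_lt(max(Mod(y - y_ref)) / max(Mod(y_ref)), 1e-3)
  # adjoint identity <F x, y> = <x, F* y> on random vectors
  y2 <- complex(real = rnorm(200), imaginary = rnorm(200))
  lhs <- sum(Conj(y2) * y)
  rhs <- sum(Conj(as.vector(nufft_adjoint(plan, y2, k))) * as.vector(x))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
})

test_that("analytic density weights follow the radial law", {
  traj <- spiral_phyllotaxis(8, 5, samples_per_line = 17, matrix = 16)
  W <- density_compensation(traj, mode = "radial-analytic")
  expect_true(all(W >= 0))
  expect_true(all(W[, traj$lines$is_navigator] == 0))
  readout <- which(!traj$lines$is_navigator)
  w1 <- W[, readout[1]]
  S <- traj$samples_per_line
  half <- ((S + 1) %/% 2):S
  expect_true(all(diff(w1[half]) > 0))      # increasing with |k|
  expect_equal(w1[half], rev(w1[1:((S + 1) %/% 2)]))  # symmetric spoke
  # same polar angle => identical weights up to solid-angle ties
  w2 <- W[, readout[2]]
  expect_equal(sum(w1 > 0), sum(w2 > 0))
})

test_that("pipe-iterative weights make the adjoint amplitude-correct", {
  sim <- static_ball_sim(M = 24, n_interleaves = 64)
  rec <- adjoint_recon(sim$kspace, prep = 1)
  img <- attr(sim$kspace, "images")[[1]]
  pos <- (seq_len(24) - 1 - 12) * (220 / 24)
  R2 <- outer(outer(pos^2, pos^2, "+"), pos^2, "+")
  interior <- R2 <= 40^2
  err <- mean(abs(Mod(rec[interior]) / Mod(img[interior]) - 1))
  expect_lt(err, 0.05)
})

test_that("adjoint reconstruction basics: zero data, point source, errors", {
  sim <- static_ball_sim(M = 16, n_interleaves = 12)
  ks <- sim$kspace
  ks0 <- ks; ks0$data[] <- 0i
  expect_true(all(adjoint_recon(ks0, prep = 1) == 0))
  # point source at the origin: build data analytically (flat spectrum)
  ksp <- ks
  ksp$data[, , 1] <- 1 + 0i
  rec <- adjoint_recon(ksp, prep = 1)
  expect_equal(which.max(Mod(rec)),
               which.max(Mod(rec) * 0 +
                           as.numeric(seq_len(16^3) ==
                                        (8 + 8 * 16 + 8 * 256 + 1))))
  bad_sens <- array(1 + 0i, dim = c(8, 8, 8, 1))
  expect_error(adjoint_recon(ks, sens = bad_sens, prep = 1), "grid")
})

test_that("sensitivity estimation recovers simulated smooth coil maps", {
  spec <- default_phantom_spec(
    matrix = 24, n_coils = 2, seed = 7, noise_sd = 0,
    respiration = list(amplitude_mm = 0, period_s = 4,
                       waveform = "sinusoid", ap_fraction = 0))
  params <- sequence_params(n_interleaves = 48, heart_rate_bpm = 67)
  traj <- spiral_phyllotaxis(48, 49, samples_per_line = 25,
                             fov_mm = 220, matrix = 24)
  ks <- simulate_acquisition(spec, params, traj, build_schedule(params))
  sens <- estimate_sensitivities(ks)
  truth <- attr(ks, "sens")
  body <- rasterize(spec)$pd > 0
  sup <- attr(sens, "support") & body
  for (c_ in 1:2) {
    expect_gt(abs(cor(Mod(sens[, , , c_][sup]), Mod(truth[, , , c_][sup]))),
              0.95)
  }
  rss <- sqrt(apply(Mod(sens)^2, 1:3, sum))
  expect_lte(max(rss), 1.05)
  # single coil: uniform map of ones
  s1 <- estimate_sensitivities(static_ball_sim(M = 16,
                                               n_interleaves = 12)$kspace)
  expect_true(all(s1 == 1 + 0i))
})

# round-robin bin labels for datasets without real respiratory contrast
fake_bins <- function(kspace, n_bins = 2) {
  nav <- which(kspace$headers$is_navigator)
  np <- kspace$headers$prep_index[nav]
  il <- kspace$headers$interleave[nav]
  structure(list(amplitude = rep(0, length(nav)),
                 time_ms = kspace$headers$timestamp_ms[nav],
                 pc_index = 1L, band_fraction = 1,
                 prep_index = np, interleave = il,
                 bin = ((il - 1L) %% n_bins) + 1L,
                 end_expiration_bin = 1L, n_bins = as.integer(n_bins)),
            class = "resp_signal")
}

# restrict a volume to the sampled k-ball (radial trajectories never cover
# the corners of the k-space cube, so reconstruction claims are only
# meaningful in band)
ball_limit <- function(v) {
  M <- dim(v)[1]
  f1 <- c(0:(M / 2 - 1), -(M / 2):-1)
  KR2 <- outer(outer(f1^2, f1^2, "+"), f1^2, "+")
  fft(fft(v) * (KR2 <= (M / 2)^2), inverse = TRUE) / M^3
}

test_that("CS objective is non-increasing and bins of static data agree", {
  sim <- static_ball_sim(M = 16, n_interleaves = 24)
  sig <- fake_bins(sim$kspace, 2)
  # lambda = 0.25 (the largest of the swept weights) and enough iterations
  # for the inter-bin modes to converge
  cfg <- recon_config(lambda_weight = 0.25, n_iterations = 40,
                      data_weighting = "density", tol_rel_objective = 0)
  bins <- motion_resolved_recon(sim$kspace, signal = sig, config = cfg,
                                preps = 1)
  tr <- bins$objective[[1]]
  expect_true(all(diff(tr$objective) <= 0))
  v <- bins$volumes[[1]]
  d <- ball_limit(v[, , , 1] - v[, , , 2])
  expect_lt(sqrt(mean(Mod(d)^2)) / mean(Mod(v)), 0.01)
})

test_that("empty respiratory bins raise a named error", {
  sim <- static_ball_sim(M = 16, n_interleaves = 24)
  sig <- fake_bins(sim$kspace, 2)
  sig$bin[] <- 1L   # bin 2 empty
  expect_error(motion_resolved_recon(sim$kspace, signal = sig,
                                     config = recon_config(n_iterations = 2)),
               "bin 2")
})

test_that("lambda = 0 with all lines in one bin recovers the image in band", {
  sim <- static_ball_sim(M = 32, n_interleaves = 72)
  sig <- fake_bins(sim$kspace, 1)
  cfg <- recon_config(lambda_weight = 0, n_iterations = 12,
                      data_weighting = "density", tol_rel_objective = 1e-8)
  bins <- motion_resolved_recon(sim$kspace, signal = sig, config = cfg,
                                preps = 1)
  img_bl <- ball_limit(attr(sim$kspace, "images")[[1]])
  rec <- ball_limit(bins$volumes[[1]][, , , 1])
  expect_lt(sqrt(mean(Mod(rec - img_bl)^2)) / sqrt(mean(Mod(img_bl)^2)), 0.05)
})

test_that("scaling k-space scales the lambda = 0 solution linearly", {
  sim <- static_ball_sim(M = 16, n_interleaves = 24)
  sig <- fake_bins(sim$kspace, 1)
  cfg <- recon_config(lambda_weight = 0, n_iterations = 5,
                      tol_rel_objective = 0)
  b1 <- motion_resolved_recon(sim$kspace, signal = sig, config = cfg,
                              preps = 1)
  ks2 <- sim$kspace; ks2$data <- ks2$data * (2.5 + 0i)
  b2 <- motion_resolved_recon(ks2, signal = sig, config = cfg, preps = 1)
  expect_lt(max(Mod(b2$volumes[[1]] - 2.5 * b1$volumes[[1]])) /
              max(Mod(b2$volumes[[1]])), 1e-3)
})

test_that("inter-bin finite-difference l1 is non-increasing in lambda", {
  sim <- small_sim()
  prof <- project_si(sim$kspace)
  sig <- assign_bins(extract_respiratory_signal(prof), 4)
  l1 <- vapply(c(0.01, 0.05, 0.25), function(lam) {
    cfg <- recon_config(lambda_weight = lam, n_iterations = 6,
                        tol_rel_objective = 0)
    bins <- motion_resolved_recon(sim$kspace, signal = sig, config = cfg,
                                  preps = 1)
    v <- bins$volumes[[1]]
    sum(vapply(1:3, function(b) sum(Mod(v[, , , b + 1] - v[, , , b])),
               numeric(1)))
  }, numeric(1))
  expect_true(all(diff(l1) < 0))
})

test_that("self-navigated reconstruction corrects known rigid motion", {
  # moving ball phantom with sinusoidal SI motion
  M <- 24
  spec_m <- phantom_spec(
    matrix = M, fov_mm = 220,
    tissues = static_ball_sim(M = M)$spec$tissues,
    respiration = list(amplitude_mm = 12, period_s = 4,
                       waveform = "sinusoid", ap_fraction = 0),
    noise_sd = 0, n_coils = 1, seed = 3)
  params <- sequence_params(n_interleaves = 64, heart_rate_bpm = 67)
  traj <- spiral_phyllotaxis(64, 49, samples_per_line = M + 1,
                             fov_mm = 220, matrix = M)
  ks_m <- simulate_acquisition(spec_m, params, traj, build_schedule(params))
  img <- attr(ks_m, "images")[[1]]

  # zero displacements: identical to the plain adjoint
  nav <- which(ks_m$headers$is_navigator)
  disp0 <- structure(list(
    displacement_mm = rep(0, length(nav)),
    time_ms = ks_m$headers$timestamp_ms[nav],
    prep_index = ks_m$headers$prep_index[nav],
    interleave = ks_m$headers$interleave[nav],
    reference_index = 1L), class = "si_displacement")
  expect_equal(selfnav_recon(ks_m, disp = disp0, prep = 1),
               adjoint_recon(ks_m, prep = 1))

  # exact displacements (ground truth, relative to the first interleave)
  mo <- ks_m$motion
  d_true <- disp0
  for (p in 1:3) {
    sel <- d_true$prep_index == p
    mop <- mo[mo$prep_index == p, ]
    d <- mop$si_mm[match(d_true$interleave[sel], mop$interleave_index)]
    d_true$displacement_mm[sel] <- d - d[1]
  }
  rec_corr <- selfnav_recon(ks_m, disp = d_true, prep = 1)
  rec_raw <- adjoint_recon(ks_m, prep = 1)
  # reference: static acquisition NRMSE
  rec_static <- adjoint_recon(static_ball_sim(M = 24, n_interleaves = 64)$kspace,
                              prep = 1)
  img_s <- attr(static_ball_sim(M = 24, n_interleaves = 64)$kspace,
                "images")[[1]]
  # the corrected volume is aligned with the first interleave's position;
  # compare against the image translated there
  d1 <- mo$si_mm[mo$prep_index == 1][1]
  plan <- nufft_plan(M)
  nrmse_s <- sqrt(mean(Mod(rec_static - img_s)^2)) / sqrt(mean(Mod(img_s)^2))
  ci <- seq_len(M) - 1 - M %/% 2
  fz <- c(0:(M / 2 - 1), -(M / 2):-1)
  phz <- exp(-2i * pi * fz * (d1 / (220 / M)) / M)
  img_shift <- fft(fft(img) * array(rep(phz, each = M * M), rep(M, 3)),
                   inverse = TRUE) / M^3
  nrmse_corr <- sqrt(mean(Mod(rec_corr - img_shift)^2)) /
    sqrt(mean(Mod(img_shift)^2))
  nrmse_raw <- sqrt(mean(Mod(rec_raw - img)^2)) / sqrt(mean(Mod(img)^2))
  expect_lt(nrmse_corr, nrmse_s * 1.1)   # within 10% of the static NRMSE
  expect_gt(nrmse_raw, nrmse_corr)       # correction actually helped

  # applying the phase with +dz then -dz is the identity
  ks_fwd <- ks_m
  d_neg <- d_true; d_neg$displacement_mm <- -d_neg$displacement_mm
  line_rows <- which(ks_m$headers$prep_index == 1 &
                       !ks_m$headers$is_navigator)
  ph <- function(ks, dsp) {
    tr <- cardiot2:::match_traj_rows(ks, line_rows)
    kz <- outer(ks$traj$radii, ks$traj$lines$dir_z[tr])
    sel <- dsp$prep_index == 1
    idx <- match(ks$headers$interleave[line_rows], dsp$interleave[sel])
    dz <- dsp$displacement_mm[sel][idx] / (220 / M)
    exp(2i * pi * kz * matrix(dz, nrow = ks$samples_per_line,
                              ncol = length(line_rows), byrow = TRUE) / M)
  }
  twice <- ks_m$data[, line_rows, 1] * ph(ks_m, d_true) * ph(ks_m, d_neg)
  expect_equal(twice, ks_m$data[, line_rows, 1], tolerance = 1e-12)
})
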