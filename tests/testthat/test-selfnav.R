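test_that("SI profiles localize a point-like object and obey the shift theorem", {
  M <- 32
  mk <- function(z0) {
    spec <- phantom_spec(
      matrix = M, fov_mm = 220,
      tissues = list(list(name = "dot", t1_ms = 800, t2_ms = 50, pd = 1,
                          geometry = list(type = "ellipsoid",
                                          center = c(0, 0, z0),
                                          semiaxes = c(8, 8, 8)))),
      respiration = list(amplitude_mm = 0, period_s = 4,
                         waveform = "sinusoid", ap_fraction = 0),
      noise_sd = 0, n_coils = 1, seed = 1)
    params <- sequence_params(n_interleaves = 4, heart_rate_bpm = 67)
    traj <- spiral_phyllotaxis(4, 9, samples_per_line = M + 1,
                               fov_mm = 220, matrix = M)
    project_si(simulate_acquisition(spec, params, traj,
                                    build_schedule(params)))
  }
  p0 <- mk(0); p40 <- mk(41.25)   # 41.25 mm = 6 profile samples
  step <- 220 / (M + 1)
  expect_lt(abs(p0$z_mm[which.max(p0$profiles[, 1])] - 0), step)
  expect_lt(abs(p40$z_mm[which.max(p40$profiles[, 1])] - 41.25), step)
  shift_samples <- which.max(p40$profiles[, 1]) - which.max(p0$profiles[, 1])
  expect_equal(shift_samples, round(41.25 / step))
})

test_that("zero data give zero profiles and missing navigators error", {
  sim <- small_sim()
  ks <- sim$kspace
  ks$data[] <- 0i
  expect_true(all(project_si(ks)$profiles == 0))
  ks2 <- sim$kspace
  keep <- !ks2$headers$is_navigator
  ks2$data <- ks2$data[, keep, , drop = FALSE]
  ks2$headers <- ks2$headers[keep, ]
  expect_error(project_si(ks2), "navigator")
})

test_that("PCA respiratory amplitude tracks the true waveform", {
  sim <- small_sim()
  prof <- project_si(sim$kspace)
  sig <- extract_respiratory_signal(prof)
  true_d <- sim$kspace$motion$si_mm
  expect_gt(abs(cor(sig$amplitude, true_d)), 0.99)
  expect_gt(sig$band_fraction, 0.8)
})

test_that("static phantom yields a flagged (low band power) or degenerate signal", {
  sim <- static_ball_sim(M = 24, n_interleaves = 64)
  prof <- project_si(sim$kspace)
  res <- tryCatch(extract_respiratory_signal(prof), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "degenerate")
  } else {
    # noiseless static: any selected component has negligible amplitude
    # relative to the profiles themselves
    expect_lt(sd(res$amplitude) / max(prof$profiles), 1e-6)
  }
})

test_that("amplitudes are invariant to adding a constant to every profile", {
  sim <- small_sim()
  prof <- project_si(sim$kspace)
  s1 <- extract_respiratory_signal(prof)
  prof2 <- prof
  prof2$profiles <- prof2$profiles + 17.3
  s2 <- extract_respiratory_signal(prof2)
  expect_equal(s1$amplitude, s2$amplitude, tolerance = 1e-8)
})

test_that("amplitudes are invariant (up to sign) to positive scaling", {
  sim <- small_sim()
  prof <- project_si(sim$kspace)
  s1 <- extract_respiratory_signal(prof)
  prof2 <- prof
  prof2$profiles <- prof2$profiles * 3.7
  s2 <- extract_respiratory_signal(prof2)
  expect_lt(min(max(abs(s1$amplitude - s2$amplitude)),
                max(abs(s1$amplitude + s2$amplitude))), 1e-6)
})

test_that("equal-count binning orders, balances, and breaks ties by order", {
  mk_sig <- function(amp) {
    structure(list(amplitude = amp, time_ms = seq_along(amp) * 1000,
                   pc_index = 1L, band_fraction = 1,
                   prep_index = NULL, interleave = NULL),
              class = "resp_signal")
  }
  s <- assign_bins(mk_sig(1:8), 4)
  expect_equal(s$bin, rep(1:4, each = 2))
  # two-level square wave, two bins: perfect separation
  sq <- assign_bins(mk_sig(rep(c(-3, 5), 10)), 2)
  expect_true(all(sq$bin[rep(c(TRUE, FALSE), 10)] == 1))
  expect_true(all(sq$bin[rep(c(FALSE, TRUE), 10)] == 2))
  # all-equal amplitudes: warning, equal counts by acquisition order
  expect_warning(tied <- assign_bins(mk_sig(rep(2, 12)), 4), "equal")
  expect_equal(tied$bin, rep(1:4, each = 3))
  expect_error(assign_bins(mk_sig(1:3), 4), "bins")
})

test_that("bin sizes differ by at most one for arbitrary signals", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(9:40, 1)
    nb <- sample(2:4, 1)
    s <- structure(list(amplitude = rnorm(n), time_ms = seq_len(n) * 1000,
                        pc_index = 1L, band_fraction = 1,
                        prep_index = NULL, interleave = NULL),
                   class = "resp_signal")
    b <- assign_bins(s, nb)
    sizes <- table(b$bin)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_true(b$end_expiration_bin %in% seq_len(nb))
  }
})

test_that("SI displacement recovers integer, zero, and sub-sample shifts", {
  # synthetic band-limited profile set
  S <- 64
  z <- seq_len(S)
  base <- exp(-(z - 24)^2 / 18) + 0.6 * exp(-(z - 40)^2 / 30)
  shift_profile <- function(d) {
    f <- fft(base)
    fr <- c(0:(S / 2 - 1), -(S / 2):-1)
    Re(fft(f * exp(-2i * pi * fr * d / S), inverse = TRUE)) / S
  }
  prof <- structure(list(
    profiles = cbind(base, shift_profile(3), shift_profile(0.4)),
    z_mm = z * 2, time_ms = c(0, 1000, 2000),
    prep_index = NULL, interleave = NULL), class = "si_profiles")
  disp <- estimate_si_displacement(prof, reference_index = 1)
  expect_identical(disp$displacement_mm[1], 0)
  expect_lt(abs(disp$displacement_mm[2] - 3 * 2), 1e-6 + 2 * 0.02)
  expect_lt(abs(disp$displacement_mm[3] - 0.4 * 2), 0.1 * 2)
  # flat reference errors
  prof$profiles[, 1] <- 1
  expect_error(estimate_si_displacement(prof, 1), "flat")
})

test_that("binning is at least 90% quartile-correct on the shared phantom", {
  sim <- small_sim()
  prof <- project_si(sim$kspace)
  sig <- assign_bins(extract_respiratory_signal(prof), 4)
  true_d <- sim$kspace$motion$si_mm
  q <- cut(true_d, quantile(true_d, seq(0, 1, 0.25)),
           include.lowest = TRUE, labels = FALSE)
  expect_gte(mean(q == sig$bin), 0.9)
})

test_that("respiratory signal exports as delimited text", {
  sim <- small_sim()
  sig <- assign_bins(extract_respiratory_signal(project_si(sim$kspace)), 4)
  tf <- tempfile(fileext = ".tsv")
  write_resp_signal(sig, tf)
  back <- read.delim(tf)
  expect_equal(nrow(back), length(sig$amplitude))
  expect_equal(back$bin, sig$bin)
})
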