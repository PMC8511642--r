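# Shared fixtures, computed lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Brute-force non-uniform DFT oracle: y_j = sum_m x[m] exp(-2i pi k_j.m / M)
# over the centered voxel grid. Independent of the gridding implementation.
brute_nudft <- function(image, k) {
  M <- dim(image)[1]
  ci <- seq_len(M) - 1 - M %/% 2
  grid <- as.matrix(expand.grid(ci, ci, ci))
  xv <- as.vector(image)
  vapply(seq_len(nrow(k)), function(j) {
    sum(xv * exp(-2i * pi * (grid %*% k[j, ])[, 1] / M))
  }, complex(1))
}

# Independent Bloch oracle: explicit 3x3 rotation / relaxation matrices
# composed step by step (matrix operators, no shared code with the package
# internals beyond the documented sequence structure).
oracle_rot_x <- function(a) {
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), nrow = 3, byrow = TRUE)
}

oracle_relax <- function(m, t, t1, t2) {
  E <- diag(c(exp(-t / t2), exp(-t / t2), exp(-t / t1)))
  as.vector(E %*% m + c(0, 0, 1 - exp(-t / t1)))
}

# Full heartbeat of the sequence with the documented convention:
# ideal prep (crush + scale mz), -alpha/2 catalyzation, TR/2, alternating
# +alpha/-alpha train with readout at TE, recovery to the window end.
oracle_heartbeat <- function(m, tau, params, t1, t2, window_ms) {
  alpha <- params$flip_deg * pi / 180
  m <- c(0, 0, m[3] * exp(-tau / t2))
  m <- as.vector(oracle_rot_x(-alpha / 2) %*% m)
  m <- oracle_relax(m, params$tr_ms / 2, t1, t2)
  sig <- numeric(params$lines_per_interleave)
  for (i in seq_len(params$lines_per_interleave)) {
    a <- if (i %% 2 == 1) alpha else -alpha
    m <- as.vector(oracle_rot_x(a) %*% m)
    m <- oracle_relax(m, params$te_ms, t1, t2)
    sig[i] <- sqrt(m[1]^2 + m[2]^2)
    m <- oracle_relax(m, params$tr_ms - params$te_ms, t1, t2)
  }
  used <- tau + params$tr_ms / 2 + params$lines_per_interleave * params$tr_ms
  m <- oracle_relax(m, window_ms - used, t1, t2)
  list(m = m, signal = sig)
}

# Small dynamic phantom acquisition shared across test files (24^3 grid,
# 48 interleaves, 2 coils, sinusoidal breathing).
small_sim <- function() {
  with_cache("small_sim", {
    spec <- default_phantom_spec(
      matrix = 24, n_coils = 2, seed = 7,
      respiration = list(amplitude_mm = 10, period_s = 4,
                         waveform = "sinusoid", ap_fraction = 0.3))
    params <- sequence_params(n_interleaves = 48, heart_rate_bpm = 67)
    traj <- spiral_phyllotaxis(48, 49, samples_per_line = 25,
                               fov_mm = 220, matrix = 24)
    schedule <- build_schedule(params)
    kspace <- simulate_acquisition(spec, params, traj, schedule)
    list(spec = spec, params = params, traj = traj, schedule = schedule,
         kspace = kspace)
  })
}

# Static noiseless single-coil ball acquisition on a small grid.
static_ball_sim <- function(M = 24, n_interleaves = 64) {
  with_cache(paste0("ball_", M, "_", n_interleaves), {
    spec <- phantom_spec(
      matrix = M, fov_mm = 220,
      tissues = list(list(
        name = "ball", t1_ms = 800, t2_ms = 50, pd = 1,
        geometry = list(type = "ellipsoid", center = c(0, 0, 0),
                        semiaxes = c(60, 60, 60)))),
      respiration = list(amplitude_mm = 0, period_s = 4,
                         waveform = "sinusoid", ap_fraction = 0),
      noise_sd = 0, n_coils = 1, seed = 3)
    params <- sequence_params(n_interleaves = n_interleaves,
                              heart_rate_bpm = 67)
    traj <- spiral_phyllotaxis(n_interleaves, 49, samples_per_line = M + 1,
                               fov_mm = 220, matrix = M)
    kspace <- simulate_acquisition(spec, params, traj, build_schedule(params))
    list(spec = spec, params = params, traj = traj, kspace = kspace)
  })
}

# The default end-to-end pipeline run (48^3) shared by the acceptance tests.
full_pipeline_result <- function() {
  with_cache("full_pipeline", {
    run_pipeline(default_run_config(matrix = 48, seed = 42))
  })
}

expect_rel_error <- function(value, reference, tol) {
  expect_lt(abs(value - reference) / abs(reference), tol)
}
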