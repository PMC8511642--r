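#' Specification of the dynamic numerical thorax phantom
#'
#' Defines an axis-aligned geometric tissue model (boxes, ellipsoids,
#' ellipsoidal shells) with per-tissue relaxation times and proton density,
#' optional focal T2 lesions, a quasi-periodic respiratory translation
#' (superior-inferior dominant with an optional anterior-posterior coupling),
#' complex Gaussian noise, and simulated receive coils. The phantom is the
#' package's stand-in for in-vivo thorax data; all synthetic raw data are
#' derived from it.
#'
#' @param matrix Image matrix size (isotropic grid).
#' @param fov_mm Field of view (mm).
#' @param tissues List of tissues, each
#'   `list(name, geometry, t1_ms, t2_ms, pd)` with `geometry` one of
#'   `list(type = "box", center, size)`,
#'   `list(type = "ellipsoid", center, semiaxes)`, or
#'   `list(type = "shell", center, outer, inner)` (all mm, axis-aligned).
#'   Later tissues overwrite earlier ones (painter's order).
#' @param lesions List of `list(center, radius, t2_ms)`; lesions overwrite
#'   T2 only.
#' @param respiration `list(amplitude_mm, period_s, waveform, ap_fraction)`;
#'   `waveform` is `"sinusoid"` or `"asymmetric"` (sin^4, which dwells near
#'   end-expiration as real breathing does).
#' @param noise_sd Complex Gaussian noise standard deviation relative to the
#'   magnitude of the DC sample of the first prepared volume.
#' @param n_coils Number of simulated receive coils.
#' @param seed Integer seed controlling all randomness of the simulation.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(matrix = 48, fov_mm = 220, tissues, lesions = list(),
                         respiration = list(amplitude_mm = 10, period_s = 4,
                                            waveform = "asymmetric",
                                            ap_fraction = 0.3),
                         noise_sd = 3e-5, n_coils = 4, seed = 42L) {
  if (length(tissues) == 0) stop_invalid("tissue list must not be empty")
  if (respiration$period_s <= 0) stop_invalid("respiration period must be positive")
  if (respiration$amplitude_mm < 0) stop_invalid("respiration amplitude must be >= 0")
  half <- fov_mm / 2
  for (ts in tissues) {
    if (!(ts$t1_ms > ts$t2_ms && ts$t2_ms > 0))
      stop_invalid("tissue '%s': need t1 > t2 > 0", ts$name)
    ext <- switch(ts$geometry$type,
                  box = abs(ts$geometry$center) + ts$geometry$size / 2,
                  ellipsoid = abs(ts$geometry$center) + ts$geometry$semiaxes,
                  shell = abs(ts$geometry$center) + ts$geometry$outer,
                  stop_invalid("unknown geometry type '%s'", ts$geometry$type))
    if (any(ext > half))
      stop_invalid("tissue '%s' extends outside the FOV", ts$name)
  }
  structure(list(matrix = as.integer(matrix), fov_mm = fov_mm,
                 voxel_mm = fov_mm / matrix,
                 tissues = tissues, lesions = lesions,
                 respiration = respiration, noise_sd = noise_sd,
                 n_coils = as.integer(n_coils), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default cardiac phantom
#'
#' A liver-like background box (T2 50 ms), a left-ventricular blood-pool
#' ellipsoid (T2 250 ms), a myocardial ellipsoidal shell (T2 46 ms, matching
#' healthy myocardium at 1.5 T), and optionally a focal lesion sphere
#' (T2 60 ms, emulating edema) embedded in the septal wall.
#'
#' @param matrix Matrix size (default 48 for desk-scale studies).
#' @param fov_mm Field of view (mm).
#' @param with_lesion Include the septal lesion sphere.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(matrix = 48, fov_mm = 220,
                                 with_lesion = TRUE, ...) {
  tissues <- list(
    list(name = "body", t1_ms = 800, t2_ms = 50, pd = 0.8,
         geometry = list(type = "box", center = c(0, 0, 0),
                         size = c(180, 140, 180))),
    list(name = "myocardium", t1_ms = 1050, t2_ms = 46, pd = 0.9,
         geometry = list(type = "shell", center = c(20, 0, 10),
                         outer = c(42, 42, 50), inner = c(30, 30, 38))),
    list(name = "blood", t1_ms = 1650, t2_ms = 250, pd = 1,
         geometry = list(type = "ellipsoid", center = c(20, 0, 10),
                         semiaxes = c(30, 30, 38))))
  lesions <- if (with_lesion)
    list(list(center = c(-16, 0, 10), radius = 7, t2_ms = 60)) else list()
  phantom_spec(matrix = matrix, fov_mm = fov_mm, tissues = tissues,
               lesions = lesions, ...)
}

# mm coordinates of voxel centers (centered grid, z = superior-inferior)
voxel_coords_mm <- function(matrix, fov_mm) {
  centered_index(matrix) * (fov_mm / matrix)
}

geom_mask <- function(geom, X, Y, Z) {
  ctr <- geom$center
  switch(geom$type,
    box = (abs(X - ctr[1]) <= geom$size[1] / 2) &
          (abs(Y - ctr[2]) <= geom$size[2] / 2) &
          (abs(Z - ctr[3]) <= geom$size[3] / 2),
    ellipsoid = ((X - ctr[1]) / geom$semiaxes[1])^2 +
                ((Y - ctr[2]) / geom$semiaxes[2])^2 +
                ((Z - ctr[3]) / geom$semiaxes[3])^2 <= 1,
    shell = {
      outer_in <- ((X - ctr[1]) / geom$outer[1])^2 +
                  ((Y - ctr[2]) / geom$outer[2])^2 +
                  ((Z - ctr[3]) / geom$outer[3])^2 <= 1
      inner_in <- ((X - ctr[1]) / geom$inner[1])^2 +
                  ((Y - ctr[2]) / geom$inner[2])^2 +
                  ((Z - ctr[3]) / geom$inner[3])^2 <= 1
      outer_in & !inner_in
    },
    stop_invalid("unknown geometry type '%s'", geom$type))
}

#' Rasterize a phantom specification to tissue parameter maps
#'
#' Paints the tissues onto the voxel grid in list order (later tissues
#' overwrite earlier ones); lesions overwrite the T2 map only, leaving the
#' label volume untouched.
#'
#' @param spec A [phantom_spec()].
#' @return A `tissue_maps` object: `t1`, `t2`, `pd` volumes (ms / unitless),
#'   an integer `label` volume (0 = air, i = i-th tissue), `lesion_mask`,
#'   `tissue_names`, and grid metadata.
#' @export
rasterize <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  M <- spec$matrix
  pos <- voxel_coords_mm(M, spec$fov_mm)
  X <- array(rep(pos, times = M * M), dim = c(M, M, M))
  Y <- array(rep(rep(pos, each = M), times = M), dim = c(M, M, M))
  Z <- array(rep(pos, each = M * M), dim = c(M, M, M))
  t1 <- array(0, dim = c(M, M, M)); t2 <- t1; pd <- t1
  label <- array(0L, dim = c(M, M, M))
  for (i in seq_along(spec$tissues)) {
    ts <- spec$tissues[[i]]
    msk <- geom_mask(ts$geometry, X, Y, Z)
    t1[msk] <- ts$t1_ms; t2[msk] <- ts$t2_ms; pd[msk] <- ts$pd
    label[msk] <- i
  }
  lesion_mask <- array(FALSE, dim = c(M, M, M))
  for (le in spec$lesions) {
    msk <- ((X - le$center[1])^2 + (Y - le$center[2])^2 +
            (Z - le$center[3])^2) <= le$radius^2
    t2[msk] <- le$t2_ms
    lesion_mask <- lesion_mask | msk
  }
  structure(list(t1 = t1, t2 = t2, pd = pd, label = label,
                 lesion_mask = lesion_mask,
                 tissue_names = vapply(spec$tissues, `[[`, "", "name"),
                 matrix = M, fov_mm = spec$fov_mm, voxel_mm = spec$voxel_mm),
            class = "tissue_maps")
}

#' Respiratory displacement at a given time
#'
#' Periodic superior-inferior translation with a derived anterior-posterior
#' component (`ap_fraction` of the SI displacement). The sinusoid waveform is
#' `A sin(2 pi t / T)`; the asymmetric waveform `A sin^4(pi t / T)` spends
#' more time near end-expiration (zero displacement), as real breathing does.
#'
#' @param spec A [phantom_spec()].
#' @param t_ms Time(s) in ms, `>= 0`.
#' @return Data frame with `t_ms`, `si_mm`, `ap_mm`.
#' @export
respiratory_phase <- function(spec, t_ms) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(t_ms < 0)) stop_invalid("t_ms must be >= 0")
  r <- spec$respiration
  T_ms <- r$period_s * 1000
  si <- switch(r$waveform,
               sinusoid = r$amplitude_mm * sin(2 * pi * t_ms / T_ms),
               asymmetric = r$amplitude_mm * sin(pi * t_ms / T_ms)^4,
               stop_invalid("unknown waveform '%s'", r$waveform))
  ap <- if (is.null(r$ap_fraction)) 0 * si else r$ap_fraction * si
  data.frame(t_ms = t_ms, si_mm = si, ap_mm = ap)
}

#' Simulated smooth receive-coil sensitivity maps
#'
#' Complex Gaussian-shaped sensitivities centered on the faces of the FOV
#' with smooth per-coil phase ramps, normalized so the root-sum-of-squares is
#' exactly 1 everywhere.
#'
#' @param matrix Grid size.
#' @param n_coils Number of coils (1 returns a uniform all-ones map).
#' @param fov_mm Field of view (mm).
#' @return Complex array `c(matrix, matrix, matrix, n_coils)`.
#' @export
coil_sensitivity_maps <- function(matrix, n_coils, fov_mm = 220) {
  M <- as.integer(matrix)
  if (n_coils == 1) return(array(1 + 0i, dim = c(M, M, M, 1)))
  pos <- voxel_coords_mm(M, fov_mm)
  X <- array(rep(pos, times = M * M), dim = c(M, M, M))
  Y <- array(rep(rep(pos, each = M), times = M), dim = c(M, M, M))
  Z <- array(rep(pos, each = M * M), dim = c(M, M, M))
  half <- fov_mm / 2
  centers <- rbind(c(half, 0, 0), c(-half, 0, 0), c(0, half, 0),
                   c(0, -half, 0), c(0, 0, half), c(0, 0, -half))
  centers <- centers[((seq_len(n_coils) - 1L) %% 6L) + 1L, , drop = FALSE]
  width <- 0.8 * fov_mm
  sens <- array(0i, dim = c(M, M, M, n_coils))
  for (c_ in seq_len(n_coils)) {
    r2 <- (X - centers[c_, 1])^2 + (Y - centers[c_, 2])^2 +
          (Z - centers[c_, 3])^2
    mag <- exp(-r2 / (2 * width^2))
    ph <- 2 * pi * (0.1 * c_ * X + 0.07 * c_ * Y + 0.05 * c_ * Z) / fov_mm
    sens[, , , c_] <- mag * exp(1i * ph)
  }
  rss <- sqrt(apply(Mod(sens)^2, 1:3, sum))
  for (c_ in seq_len(n_coils)) sens[, , , c_] <- sens[, , , c_] / rss
  sens
}

#' Simulate the T2-prepared 3D radial acquisition of a phantom
#'
#' Forward model of the free-breathing acquisition: for every interleave the
#' respiratory displacement is evaluated at the interleave start time and
#' applied as an exact k-space linear phase (rigid translation); the per-prep
#' complex image is the proton density weighted by the Bloch-simulated
#' steady-state signal of each tissue; its non-uniform Fourier transform is
#' evaluated at all of the interleave's sample positions (navigator line
#' included), modulated by the coil sensitivities, and corrupted with seeded
#' complex Gaussian noise.
#'
#' @param spec A [phantom_spec()].
#' @param params A [sequence_params()].
#' @param traj A [spiral_phyllotaxis()] trajectory with the same matrix/FOV.
#' @param schedule A [build_schedule()] result consistent with `params`.
#' @return A `kspace_data` object: complex `data`
#'   (samples x lines x coils), per-line `headers`
#'   (`prep_index`, `interleave`, `line_in_interleave`, `is_navigator`,
#'   `timestamp_ms`, direction), the trajectory, and simulation ground truth
#'   (`motion`, `sens`, `tissue_maps`, per-tissue signals) as attributes for
#'   validation.
#' @export
simulate_acquisition <- function(spec, params, traj, schedule) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(params, "sequence_params"),
            inherits(traj, "trajectory"), inherits(schedule, "acq_schedule"))
  if (traj$matrix != spec$matrix || traj$fov_mm != spec$fov_mm)
    stop_invalid("trajectory grid/FOV does not match the phantom grid/FOV")
  if (traj$n_interleaves != params$n_interleaves)
    stop_invalid("trajectory and schedule disagree on the interleave count")
  ev <- schedule$events
  preps <- params$prep_durations_ms
  if (max(ev$prep_index) != length(preps))
    stop_invalid("schedule and sequence parameters disagree on prep count")
  M <- spec$matrix
  maps <- rasterize(spec)
  support <- maps$pd > 0
  combos <- unique(data.frame(t1 = maps$t1[support], t2 = maps$t2[support]))
  sig_tab <- matrix(0, nrow = nrow(combos), ncol = length(preps))
  for (i in seq_len(nrow(combos))) {
    s <- simulate_interleave_signal(params, combos$t1[i], combos$t2[i])
    sig_tab[i, ] <- s$signal
  }
  # per-prep complex images
  key_vol <- paste(maps$t1, maps$t2)
  key_tab <- paste(combos$t1, combos$t2)
  idx <- match(key_vol, key_tab)
  images <- vector("list", length(preps))
  for (p in seq_along(preps)) {
    sigvol <- array(0, dim = dim(maps$pd))
    hit <- !is.na(idx) & as.vector(support)
    sigvol[hit] <- sig_tab[idx[hit], p]
    images[[p]] <- as.complex(maps$pd * sigvol)
    dim(images[[p]]) <- dim(maps$pd)
  }
  sens <- coil_sensitivity_maps(M, spec$n_coils, spec$fov_mm)
  plan <- nufft_plan(M)
  nlines_prep <- nrow(traj$lines)
  S <- traj$samples_per_line
  K <- all_sample_positions(traj)
  n_coils <- spec$n_coils
  # per-interleave respiratory displacement at the interleave start time
  disp <- respiratory_phase(spec, ev$start_time_ms)
  voxel <- spec$voxel_mm
  headers <- do.call(rbind, lapply(seq_along(preps), function(p) {
    h <- traj$lines
    h$prep_index <- p
    evp <- ev[ev$prep_index == p, ]
    h$timestamp_ms <- evp$start_time_ms[match(h$interleave, evp$interleave_index)]
    h
  }))
  data <- array(0i, dim = c(S, nlines_prep * length(preps), n_coils))
  set.seed(spec$seed)
  dc_mag <- Mod(sum(images[[1]]))
  sigma <- spec$noise_sd * dc_mag
  il_of_row <- traj$lines$interleave
  for (p in seq_along(preps)) {
    evp <- ev[ev$prep_index == p, ]
    d <- disp[ev$prep_index == p, ]
    dz_vox <- d$si_mm[match(il_of_row, evp$interleave_index)] / voxel
    dy_vox <- d$ap_mm[match(il_of_row, evp$interleave_index)] / voxel
    # per-sample phase for the rigid translation of each interleave
    phase <- exp(-2i * pi * (K[, 2] * rep(dy_vox, each = S) +
                             K[, 3] * rep(dz_vox, each = S)) / M)
    cols <- (p - 1L) * nlines_prep + seq_len(nlines_prep)
    for (c_ in seq_len(n_coils)) {
      y <- nufft_forward(plan, images[[p]] * sens[, , , c_], K)
      y <- y * phase
      if (sigma > 0)
        y <- y + complex(real = rnorm(length(y), sd = sigma),
                         imaginary = rnorm(length(y), sd = sigma))
      data[, cols, c_] <- y
    }
  }
  structure(list(data = data, headers = headers, traj = traj,
                 matrix = M, fov_mm = spec$fov_mm,
                 samples_per_line = S, n_coils = n_coils,
                 prep_durations_ms = preps, seed = spec$seed,
                 motion = cbind(ev, disp[, c("si_mm", "ap_mm")]),
                 schema_version = 1L),
            class = "kspace_data",
            sens = sens, tissue_maps = maps, tissue_signals = sig_tab,
            images = images)
}
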