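#' Superior-inferior projection profiles from navigator lines
#'
#' Inverse-Fourier-transforms every superior-inferior navigator readout to a
#' 1D projection of the object along z and combines coils by
#' root-sum-of-squares. One profile per navigator (one per interleave per
#' prep), ordered by acquisition time.
#'
#' @param kspace A `kspace_data` object containing navigator lines.
#' @return An `si_profiles` object: `profiles`
#'   (samples x navigators magnitude matrix), `z_mm` positions, and
#'   per-navigator `time_ms`, `prep_index`, `interleave`.
#' @export
project_si <- function(kspace) {
  stopifnot(inherits(kspace, "kspace_data"))
  nav <- which(kspace$headers$is_navigator)
  if (length(nav) == 0) stop_invalid("dataset contains no navigator lines")
  S <- kspace$samples_per_line
  kz <- kspace$traj$radii                    # cycles/FOV (grid units)
  M <- kspace$matrix
  zc <- centered_index(S) * (kspace$fov_mm / S)
  # inverse DFT from the radial kz samples (grid units, i.e. cycles/FOV)
  # onto S z-positions: z in mm enters as a fractional voxel index z*M/fov.
  E <- exp(2i * pi * outer(zc, kz) / kspace$fov_mm)
  prof <- matrix(0, nrow = S, ncol = length(nav))
  for (c_ in seq_len(kspace$n_coils)) {
    pc <- E %*% kspace$data[, nav, c_]
    prof <- prof + Mod(pc)^2
  }
  ord <- order(kspace$headers$timestamp_ms[nav], nav)
  structure(list(profiles = sqrt(prof)[, ord],
                 z_mm = zc,
                 time_ms = kspace$headers$timestamp_ms[nav][ord],
                 prep_index = kspace$headers$prep_index[nav][ord],
                 interleave = kspace$headers$interleave[nav][ord]),
            class = "si_profiles")
}

#' Extract the respiratory amplitude by PCA of the SI profiles
#'
#' Mean-centers the profiles over navigators, runs a principal component
#' analysis across navigators, and selects the component whose score series
#' carries the largest spectral-power fraction in the respiratory band
#' (0.1-0.5 Hz by default). The selected scores are the per-interleave
#' respiratory amplitude; the sign is fixed so the densest amplitude cluster
#' (the end-expiratory plateau) is positive.
#'
#' @param profiles An [project_si()] result (or a samples x navigators
#'   matrix).
#' @param times Acquisition times (ms), one per navigator; taken from
#'   `profiles` when it is an `si_profiles` object.
#' @param band_hz Respiratory frequency band for component selection.
#' @param n_candidates How many leading components to score.
#' @return A `resp_signal` object: `amplitude`, `time_ms`, `pc_index`,
#'   `band_fraction`, plus `prep_index`/`interleave` when available. Bin
#'   labels are added by [assign_bins()].
#' @export
extract_respiratory_signal <- function(profiles, times = NULL,
                                       band_hz = c(0.1, 0.5),
                                       n_candidates = 5) {
  meta <- NULL
  if (inherits(profiles, "si_profiles")) {
    meta <- profiles
    if (is.null(times)) times <- profiles$time_ms
    profiles <- profiles$profiles
  }
  n <- ncol(profiles)
  if (n < 8) stop_invalid("need at least 8 navigators for PCA")
  if (is.null(times)) stop_invalid("acquisition times are required")
  X <- t(profiles)                       # navigators x positions
  if (all(apply(X, 2, stats::sd) < 1e-12 * max(abs(X))))
    stop_invalid("degenerate (zero-variance) SI profiles")
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ncand <- min(n_candidates, ncol(pca$x))
  dt_s <- stats::median(diff(sort(times))) / 1000
  band_frac <- vapply(seq_len(ncand), function(j) {
    s <- pca$x[, j] - mean(pca$x[, j])
    pw <- Mod(stats::fft(s))^2
    freq <- (seq_along(s) - 1) / (length(s) * dt_s)
    half <- freq <= 1 / (2 * dt_s)
    inband <- half & freq >= band_hz[1] & freq <= band_hz[2]
    sum(pw[inband]) / sum(pw[half & freq > 0])
  }, numeric(1))
  pc <- which.max(band_frac)
  amp <- pca$x[, pc]
  # The apparent signal level differs across the three prepared volumes, so
  # the PC scores of a shared respiratory motion are gain-modulated per prep
  # block. Breathing statistics are stationary over the blocks, so the
  # scores are standardized within each block to a common scale.
  if (!is.null(meta$prep_index)) {
    for (p in unique(meta$prep_index)) {
      s <- meta$prep_index == p
      if (sum(s) > 2 && stats::sd(amp[s]) > 0)
        amp[s] <- (amp[s] - mean(amp[s])) / stats::sd(amp[s])
    }
  }
  dens <- stats::density(amp)
  if (dens$x[which.max(dens$y)] < 0) amp <- -amp
  structure(list(amplitude = amp, time_ms = times,
                 pc_index = pc, band_fraction = band_frac[pc],
                 prep_index = meta$prep_index, interleave = meta$interleave,
                 bin = NULL, end_expiration_bin = NULL, n_bins = NULL),
            class = "resp_signal")
}

#' Partition interleaves into respiratory bins
#'
#' Equal-count amplitude binning: the amplitudes are sorted and split into
#' `n_bins` contiguous quantile groups (sizes differing by at most one), with
#' ties broken by acquisition order. The end-expiration bin is the one
#' containing the modal (highest-density) amplitude.
#'
#' @param signal A [extract_respiratory_signal()] result.
#' @param n_bins Number of respiratory states (default 4).
#' @return The `resp_signal` with `bin` labels (1 = lowest amplitude),
#'   `end_expiration_bin`, and `n_bins` filled in.
#' @export
assign_bins <- function(signal, n_bins = 4) {
  stopifnot(inherits(signal, "resp_signal"))
  amp <- signal$amplitude
  if (any(!is.finite(amp))) stop_invalid("amplitudes must be finite")
  n <- length(amp)
  if (n_bins > n) stop_invalid("more bins (%d) than interleaves (%d)", n_bins, n)
  if (diff(range(amp)) == 0)
    warning("all amplitudes equal; binning by acquisition order", call. = FALSE)
  ord <- order(amp, seq_along(amp))       # ties by acquisition order
  sizes <- diff(round(seq(0, n, length.out = n_bins + 1)))
  lab_sorted <- rep(seq_len(n_bins), times = sizes)
  bin <- integer(n)
  bin[ord] <- lab_sorted
  dens <- stats::density(amp)
  mode_amp <- dens$x[which.max(dens$y)]
  # bin whose amplitude range contains (or is nearest to) the modal amplitude
  bin_lo <- tapply(amp, bin, min)
  bin_hi <- tapply(amp, bin, max)
  dist <- pmax(bin_lo - mode_amp, 0) + pmax(mode_amp - bin_hi, 0)
  signal$bin <- bin
  signal$end_expiration_bin <- as.integer(names(which.min(dist)))
  signal$n_bins <- as.integer(n_bins)
  signal
}

#' 1D superior-inferior displacement of each interleave
#'
#' Cross-correlates every SI profile against a reference profile; the
#' argmax lag is refined to sub-sample precision by parabolic interpolation
#' and converted to mm. This is the displacement estimate used by the
#' baseline self-navigated reconstruction.
#'
#' @param profiles An [project_si()] result.
#' @param reference_index Index of the reference navigator (displacement 0).
#' @param max_shift_mm Maximum displacement searched (default a quarter FOV).
#' @return An `si_displacement` object with `displacement_mm` per navigator
#'   (and the profile metadata).
#' @export
estimate_si_displacement <- function(profiles, reference_index = 1,
                                     max_shift_mm = NULL) {
  stopifnot(inherits(profiles, "si_profiles"))
  P <- profiles$profiles
  S <- nrow(P)
  step_mm <- diff(profiles$z_mm[1:2])
  if (is.null(max_shift_mm)) max_shift_mm <- S * step_mm / 4
  ref <- P[, reference_index]
  if (stats::sd(ref) < 1e-12 * max(abs(ref), 1e-300))
    stop_invalid("flat reference profile")
  maxlag <- max(1L, min(S %/% 2 - 1L, round(max_shift_mm / step_mm)))
  refc <- ref - mean(ref)
  Fr <- stats::fft(refc)
  disp <- vapply(seq_len(ncol(P)), function(j) {
    p <- P[, j] - mean(P[, j])
    # circular cross-correlation: the peak index gives the displacement of
    # the profile relative to the reference, exact for whole-sample shifts
    cc <- Re(stats::fft(Fr * Conj(stats::fft(p)), inverse = TRUE)) / S
    lag_of <- function(i) { l <- i - 1L; if (l > S / 2) l - S else l }
    idx_of <- function(l) ((l %% S) + S) %% S + 1L
    cand <- idx_of(-maxlag:maxlag)
    i <- cand[which.max(cc[cand])]
    lag <- lag_of(i)
    cm <- cc[idx_of(lag - 1)]; c0 <- cc[i]; cp <- cc[idx_of(lag + 1)]
    denom <- cm - 2 * c0 + cp
    if (denom < 0) lag <- lag + 0.5 * (cm - cp) / denom
    -lag * step_mm
  }, numeric(1))
  disp <- disp - disp[reference_index]
  structure(list(displacement_mm = disp, time_ms = profiles$time_ms,
                 prep_index = profiles$prep_index,
                 interleave = profiles$interleave,
                 reference_index = reference_index),
            class = "si_displacement")
}

#' Export a respiratory signal as delimited text
#'
#' @param signal A binned [assign_bins()] signal.
#' @param path Output TSV path.
#' @export
write_resp_signal <- function(signal, path) {
  df <- data.frame(time_ms = signal$time_ms,
                   amplitude = signal$amplitude,
                   bin = if (is.null(signal$bin)) NA_integer_ else signal$bin)
  if (!is.null(signal$prep_index)) df$prep_index <- signal$prep_index
  if (!is.null(signal$interleave)) df$interleave <- signal$interleave
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
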