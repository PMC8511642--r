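#' Septum-to-blood-pool line for sharpness measurement
#'
#' Derives, from the ground-truth tissue labels of a phantom, the standard
#' sharpness line: from the middle of the septal myocardium into the
#' left-ventricular blood pool, in the slice through the blood-pool
#' centroid.
#'
#' @param maps A [rasterize()] `tissue_maps` object.
#' @return List `start`, `end` (1-based voxel coordinates).
#' @export
default_sharpness_line <- function(maps) {
  stopifnot(inherits(maps, "tissue_maps"))
  myo <- match("myocardium", maps$tissue_names)
  blo <- match("blood", maps$tissue_names)
  if (is.na(myo) || is.na(blo))
    stop_invalid("phantom lacks myocardium/blood labels")
  idx <- which(maps$label == blo, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  # pick a slice a few voxels above the centroid so the line stays clear of
  # any lesion embedded mid-septum, then walk from the blood centroid toward
  # -x; the septal wall is the first myocardial run encountered
  z0 <- ctr[3] + max(2L, round(nrow(idx)^(1 / 3) / 4))
  if (!any(maps$label[, ctr[2], z0] == myo)) z0 <- ctr[3]
  xs <- rev(seq_len(ctr[1]))
  lab_line <- maps$label[xs, ctr[2], z0]
  in_myo <- which(lab_line == myo)
  if (length(in_myo) == 0) stop_invalid("no septal myocardium along -x")
  sept_mid_x <- xs[round(mean(range(in_myo)))]
  start <- c(sept_mid_x, ctr[2], z0)
  end <- c(round(sept_mid_x + 0.75 * (ctr[1] - sept_mid_x)), ctr[2], z0)
  list(start = start, end = end)
}

#' Alternative reconstruction: map each respiratory bin, then average
#'
#' The main route averages the registered respiratory bins and fits one
#' voxel-wise map on the high-SNR volumes; this alternative swaps the
#' order: it fits a map inside every (already aligned) respiratory bin and
#' averages the four maps. The same registrations are reused — the aligned
#' bins come from [register_and_average_bins()] and the prep-stage
#' transforms from [register_preps()] — so the comparison isolates exactly
#' the fit-then-average versus average-then-fit question.
#'
#' @param averaged The result of [register_and_average_bins()] (carries the
#'   aligned per-bin volumes as an attribute).
#' @param registered The [register_preps()] result of the main route (its
#'   prep-stage transforms are applied to each bin's volumes).
#' @param model Fit model passed to [map_volume()].
#' @return A `t2_map` whose T2 volume is the voxel-wise mean of the per-bin
#'   maps (mask = voxels valid in at least half the bins).
#' @export
map_bins_then_average <- function(averaged, registered,
                                  model = "three_param") {
  aligned <- attr(averaged, "aligned_bins")
  if (is.null(aligned))
    stop_invalid("'averaged' must come from register_and_average_bins()")
  stopifnot(inherits(registered, "registered_preps"))
  times <- registered$times_ms
  B <- dim(aligned[[1]])[4]
  acc <- NULL; cnt <- NULL
  for (b in seq_len(B)) {
    vols <- lapply(seq_along(aligned), function(p) {
      v <- aligned[[p]][, , , b]
      f <- registered$fields[[paste0("prep", p)]]
      if (!is.null(f)) {
        v <- apply_deformation(v, f$translation)
        v <- apply_deformation(v, f$nonrigid)
      }
      v
    })
    mp <- map_volume(vols, model = model, times_ms = times,
                     voxel_mm = registered$voxel_mm)
    t2b <- mp$t2_ms
    t2b[!mp$mask] <- NA
    if (is.null(acc)) {
      acc <- array(0, dim = dim(t2b)); cnt <- array(0L, dim = dim(t2b))
    }
    hit <- !is.na(t2b)
    acc[hit] <- acc[hit] + t2b[hit]
    cnt[hit] <- cnt[hit] + 1L
  }
  mask <- cnt >= ceiling(B / 2)
  t2 <- array(NA_real_, dim = dim(acc))
  t2[mask] <- acc[mask] / cnt[mask]
  structure(list(t2_ms = t2, a = NULL, b = NULL, mask = mask,
                 residual = NULL, model = model, times_ms = times,
                 voxel_mm = registered$voxel_mm),
            class = "t2_map")
}

log_stage <- function(level, fmt, ...) {
  if (identical(level, "silent")) return(invisible())
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Run the full phantom-to-T2-map pipeline
#'
#' Executes the complete chain on the synthetic phantom: simulate the
#' T2-prepared 3D radial acquisition, project the navigators, extract and
#' bin the respiratory signal, run the motion-resolved compressed-sensing
#' reconstruction per prep, register the respiratory bins to end-expiration
#' and average, register the three prepared volumes, fit the voxel-wise T2
#' map, and compute the QC metrics (myocardial CoV and sigmoid sharpness).
#' Deterministic given `config$seed`; every artifact is written with
#' provenance (config, seed, package version).
#'
#' @param config A [default_run_config()] list (or [read_config()] result).
#' @param out_dir Output directory for artifacts (created); `NULL` skips
#'   writing.
#' @return Invisible list with all intermediate objects (`kspace`, `signal`,
#'   `bins`, `averaged`, `registered`, `map`, `qc`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  lvl <- config$log_level %||% "info"
  t0 <- Sys.time()
  set.seed(config$seed)
  spec <- default_phantom_spec(matrix = config$matrix, fov_mm = config$fov_mm,
                               with_lesion = isTRUE(config$with_lesion),
                               respiration = config$respiration,
                               noise_sd = config$noise_sd,
                               n_coils = config$n_coils, seed = config$seed)
  params <- sequence_params(heart_rate_bpm = config$heart_rate_bpm,
                            n_interleaves = config$n_interleaves %||% 112L)
  traj <- spiral_phyllotaxis(params$n_interleaves, params$lines_per_interleave,
                             samples_per_line = config$samples_per_line,
                             fov_mm = config$fov_mm, matrix = config$matrix)
  schedule <- build_schedule(params)
  log_stage(lvl, "simulating acquisition (matrix %d, %d coils)",
            config$matrix, config$n_coils)
  kspace <- simulate_acquisition(spec, params, traj, schedule)
  maps <- attr(kspace, "tissue_maps")
  log_stage(lvl, "self-navigation: SI projection + PCA binning")
  profiles <- project_si(kspace)
  signal <- extract_respiratory_signal(profiles)
  signal <- assign_bins(signal, n_bins = config$n_bins)
  rc <- recon_config(lambda_weight = config$lambda_weight,
                     n_iterations = config$n_iterations)
  log_stage(lvl, "motion-resolved CS reconstruction (lambda = %g, %d it)",
            config$lambda_weight, config$n_iterations)
  sens <- estimate_sensitivities(kspace, traj)
  bins <- motion_resolved_recon(kspace, traj, signal, sens = sens, config = rc)
  for (tr in bins$objective)
    log_stage(lvl, "  CG objective: %.4g -> %.4g (%d iterations)",
              tr$objective[1], tr$objective[nrow(tr)], max(tr$iteration))
  log_stage(lvl, "registering respiratory bins to end-expiration")
  averaged <- register_and_average_bins(bins,
                                        control_spacing_mm = config$control_spacing_mm)
  log_stage(lvl, "registering prepared volumes")
  registered <- register_preps(averaged,
                               control_spacing_mm = config$control_spacing_mm)
  log_stage(lvl, "voxel-wise T2 fitting (%s)", config$model)
  map <- map_volume(registered, model = config$model)
  myo <- match("myocardium", maps$tissue_names)
  roi <- maps$label == myo & !maps$lesion_mask
  stats_myo <- region_stats(map, roi)
  line <- default_sharpness_line(maps)
  sharp <- tryCatch(sharpness(map, line$start, line$end),
                    error = function(e) NULL)
  qc <- list(myocardium = stats_myo,
             sharpness_k_mm = if (!is.null(sharp)) sharp$mean_k else NA_real_,
             bin_counts = as.vector(bins$bin_counts),
             provenance = list(seed = config$seed,
                               package_version =
                                 as.character(utils::packageVersion("cardiot2")),
                               config = unclass(config),
                               elapsed_s =
                                 as.numeric(difftime(Sys.time(), t0, "secs"))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_raw(kspace, file.path(out_dir, "raw_kspace.bin"))
    write_resp_signal(signal, file.path(out_dir, "respiratory_signal.tsv"))
    vx <- config$fov_mm / config$matrix
    for (p in seq_along(bins$volumes))
      write_volume_nifti(bins$volumes[[p]],
                         file.path(out_dir, sprintf("bins_prep%d.nii.gz", p)), vx)
    for (p in seq_along(registered$volumes))
      write_volume_nifti(registered$volumes[[p]],
                         file.path(out_dir, sprintf("registered_prep%d.nii.gz", p)),
                         vx)
    t2v <- map$t2_ms; t2v[!map$mask] <- 0
    write_volume_nifti(t2v, file.path(out_dir, "t2_map.nii.gz"), vx)
    write_volume_nifti(maps$t2, file.path(out_dir, "ground_truth_t2.nii.gz"), vx)
    qc_out <- qc
    yaml::write_yaml(qc_out, file.path(out_dir, "qc_report.yaml"))
  }
  log_stage(lvl, "done: myocardial T2 %.1f ms (CoV %.1f%%)",
            stats_myo$mean_t2_ms, stats_myo$cov_percent)
  invisible(list(kspace = kspace, tissue_maps = maps, signal = signal,
                 bins = bins, averaged = averaged, registered = registered,
                 map = map, qc = qc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
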