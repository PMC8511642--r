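#' Deformation field
#'
#' Internal constructor for the registration result: either a spatially
#' constant translation (`shift_vox`, voxels) or a dense non-rigid
#' displacement field (`disp`, voxels, dim `c(M, M, M, 3)`), with the mean
#' Jacobian determinant of the warp as a regularity metric.
#'
#' @name deformation_field
#' @keywords internal
NULL

new_deformation <- function(type, shift_vox = NULL, disp = NULL,
                            voxel_mm = 1, mean_jacobian = 1,
                            mse_before = NA_real_, mse_after = NA_real_) {
  structure(list(type = type, shift_vox = shift_vox, disp = disp,
                 voxel_mm = voxel_mm, mean_jacobian = mean_jacobian,
                 mse_before = mse_before, mse_after = mse_after),
            class = "deformation_field")
}

mse <- function(a, b) mean((a - b)^2)

#' Apply a deformation field to a volume
#'
#' Resamples `vol` (trilinear interpolation) so that the returned volume is
#' aligned with the fixed image of the registration that produced the field.
#'
#' @param vol Real 3D array (the moving image).
#' @param field A `deformation_field`.
#' @return Warped array of the same dimensions.
#' @export
apply_deformation <- function(vol, field) {
  stopifnot(inherits(field, "deformation_field"))
  d <- dim(vol)
  if (field$type == "identity") return(vol)
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  if (field$type == "translation") {
    pts <- sweep(g, 2, field$shift_vox, "-")
  } else {
    pts <- g - cbind(as.vector(field$disp[, , , 1]),
                     as.vector(field$disp[, , , 2]),
                     as.vector(field$disp[, , , 3]))
  }
  array(sample_trilinear(vol, pts), dim = d)
}

# sub-voxel peak location of a phase-correlation surface (wrapped)
phasecorr_shift <- function(moving, fixed, normalize = TRUE) {
  F1 <- stats::fft(fixed)
  F2 <- stats::fft(moving)
  X <- F1 * Conj(F2)
  if (normalize) {
    m <- Mod(X)
    X <- X / pmax(m, 1e-12 * max(m))
  }
  cc <- Re(stats::fft(X, inverse = TRUE))
  d <- dim(cc)
  i <- which.max(cc)
  sub <- arrayInd(i, d)[1, ]
  shift <- numeric(3)
  for (ax in 1:3) {
    n <- d[ax]
    s0 <- sub[ax] - 1L
    idx <- function(off) {
      j <- sub
      j[ax] <- ((s0 + off) %% n) + 1L
      cc[j[1], j[2], j[3]]
    }
    cm <- idx(-1); c0 <- idx(0); cp <- idx(1)
    denom <- cm - 2 * c0 + cp
    frac <- if (denom < 0) 0.5 * (cm - cp) / denom else 0
    s <- s0 + frac
    if (s > n / 2) s <- s - n
    shift[ax] <- s
  }
  shift
}

#' Translational registration by phase correlation
#'
#' Finds the sub-voxel 3D shift aligning `moving` to `fixed` (phase
#' correlation with parabolic peak refinement). The returned field never
#' increases the mean squared difference: if the estimated shift does not
#' improve on the identity, the identity is returned with a warning.
#'
#' @param moving,fixed Real 3D arrays on the same grid.
#' @param voxel_mm Voxel size (mm), recorded on the field.
#' @return A `deformation_field` of type `"translation"` (or `"identity"`).
#' @export
register_translation <- function(moving, fixed, voxel_mm = 1) {
  if (!all(dim(moving) == dim(fixed))) stop_invalid("grids differ")
  if (all(moving == 0) || all(fixed == 0))
    stop_invalid("degenerate all-zero volume")
  shift <- phasecorr_shift(moving, fixed)
  f <- new_deformation("translation", shift_vox = shift, voxel_mm = voxel_mm)
  m0 <- mse(moving, fixed)
  m1 <- mse(apply_deformation(moving, f), fixed)
  if (m1 > m0) {
    # a sub-half-voxel estimate that fails to improve just means the inputs
    # are already aligned; larger failed shifts indicate a mismatch
    if (sqrt(sum(shift^2)) >= 0.5)
      warning("translation did not reduce the dissimilarity; returning identity",
              call. = FALSE)
    return(new_deformation("identity", voxel_mm = voxel_mm,
                           mse_before = m0, mse_after = m0))
  }
  f$mse_before <- m0; f$mse_after <- m1
  f
}

# mean Jacobian determinant of the warp x -> x + disp (disp in voxels),
# central finite differences (one-sided at the edges)
mean_jacobian_det <- function(disp) {
  d <- dim(disp)[1:3]
  J <- array(0, dim = c(d, 3, 3))
  for (comp in 1:3) {
    a <- disp[, , , comp]
    for (ax in 1:3) {
      n <- d[ax]
      ip <- pmin(seq_len(n) + 1L, n); im <- pmax(seq_len(n) - 1L, 1L)
      hi <- switch(ax, a[ip, , ], a[, ip, ], a[, , ip])
      lo <- switch(ax, a[im, , ], a[, im, ], a[, , im])
      den <- ip - im
      deriv <- (hi - lo) / switch(ax,
        array(den, dim = d),
        aperm(array(den, dim = d[c(2, 1, 3)]), c(2, 1, 3)),
        aperm(array(den, dim = d[c(3, 1, 2)]), c(2, 3, 1)))
      J[, , , comp, ax] <- deriv
    }
  }
  det_vox <- (1 + J[, , , 1, 1]) * ((1 + J[, , , 2, 2]) * (1 + J[, , , 3, 3]) -
                                      J[, , , 2, 3] * J[, , , 3, 2]) -
    J[, , , 1, 2] * (J[, , , 2, 1] * (1 + J[, , , 3, 3]) -
                       J[, , , 2, 3] * J[, , , 3, 1]) +
    J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] -
                       (1 + J[, , , 2, 2]) * J[, , , 3, 1])
  mean(det_vox)
}

#' Non-rigid registration (multi-resolution block matching)
#'
#' Estimates a dense displacement field by phase-correlation block matching
#' on a coarse-to-fine schedule, trilinearly interpolated to the voxel grid
#' and Gaussian-smoothed at the control-point spacing. Contract: the
#' returned warp never increases the mean squared difference against the
#' fixed image (the identity is returned, with a warning if the optimizer
#' failed, when the improvement is below 0.1%), and the mean Jacobian
#' determinant is kept within \[0.5, 2\] by scaling back the field if needed.
#'
#' @param moving,fixed Real nonnegative 3D arrays on the same grid.
#' @param control_spacing_mm Control-point spacing (mm), default 12.
#' @param voxel_mm Voxel size (mm).
#' @param n_passes Block-matching passes per pyramid level (field composed
#'   additively).
#' @param demons_iterations Optical-flow (demons) refinement iterations run
#'   after block matching (0 disables).
#' @return A `deformation_field` of type `"nonrigid"` (or `"identity"`).
#' @export
register_nonrigid <- function(moving, fixed, control_spacing_mm = 12,
                              voxel_mm = 1, n_passes = 3,
                              demons_iterations = 20) {
  if (!all(dim(moving) == dim(fixed))) stop_invalid("grids differ")
  d <- dim(moving)
  m0 <- mse(moving, fixed)
  if (m0 <= 1e-12 * mean(fixed^2))   # already aligned to numerical precision
    return(new_deformation("identity", voxel_mm = voxel_mm,
                           mse_before = m0, mse_after = m0))
  spacing0 <- max(2, round(control_spacing_mm / voxel_mm))
  # coarse-to-fine: large blocks capture the bulk deformation, the final
  # level resolves it at the requested control spacing
  spacings <- unique(rev(sort(pmin(round(min(d) / 3),
                                   spacing0 * c(4, 2, 1)))))
  spacings <- spacings[spacings >= 2]
  schedule <- rep(spacings, each = n_passes)
  disp <- array(0, dim = c(d, 3))
  warped <- moving
  best_mse <- m0
  for (spacing in schedule) {
    block <- min(2L * spacing, min(d))
    hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(block) - 1) / (block - 1))
    win <- outer(outer(hann, hann), hann)
    centers <- lapply(d, function(n) {
      s <- seq(1 + block %/% 2, n - block %/% 2, by = spacing)
      if (length(s) == 0) s <- (n + 1) / 2
      unique(round(s))
    })
    nc <- vapply(centers, length, integer(1))
    cf <- array(0, dim = c(nc, 3))
    grad_thr <- 0.02 * stats::sd(fixed)
    for (i in seq_along(centers[[1]])) for (j in seq_along(centers[[2]]))
      for (k in seq_along(centers[[3]])) {
        cx <- centers[[1]][i]; cy <- centers[[2]][j]; cz <- centers[[3]][k]
        rx <- max(1, cx - block %/% 2):min(d[1], cx + block %/% 2 - 1)
        ry <- max(1, cy - block %/% 2):min(d[2], cy + block %/% 2 - 1)
        rz <- max(1, cz - block %/% 2):min(d[3], cz + block %/% 2 - 1)
        if (length(rx) < block || length(ry) < block || length(rz) < block)
          next
        fb <- fixed[rx, ry, rz]
        if (stats::sd(fb) < grad_thr) next   # no structure to match
        mb <- warped[rx, ry, rz]
        if (all(mb == 0)) next
        # mean removal kills the DC term that otherwise pins the circular
        # correlation peak at zero; the Hann window tames wrap-around
        sh <- phasecorr_shift((mb - mean(mb)) * win, (fb - mean(fb)) * win,
                              normalize = FALSE)
        sh <- pmin(pmax(sh, -spacing / 2), spacing / 2)
        cf[i, j, k, ] <- sh
      }
    # interpolate the coarse field to the voxel grid
    g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
    upd <- array(0, dim = c(d, 3))
    for (comp in 1:3) {
      coarse <- cf[, , , comp, drop = TRUE]
      dim(coarse) <- nc
      pts <- cbind(approx_index(g[, 1], centers[[1]]),
                   approx_index(g[, 2], centers[[2]]),
                   approx_index(g[, 3], centers[[3]]))
      upd[, , , comp] <- array(sample_trilinear(coarse, pts), dim = d)
      upd[, , , comp] <- gaussian_blur3(upd[, , , comp], spacing / 3)
    }
    improved <- FALSE
    for (scale in c(1, 0.5, 0.25)) {
      cand <- disp + scale * upd
      f <- new_deformation("nonrigid", disp = cand, voxel_mm = voxel_mm)
      m1 <- mse(apply_deformation(moving, f), fixed)
      if (m1 < best_mse) {
        disp <- cand; best_mse <- m1; improved <- TRUE
        break
      }
    }
    if (!improved) next
    f_cur <- new_deformation("nonrigid", disp = disp, voxel_mm = voxel_mm)
    warped <- apply_deformation(moving, f_cur)
  }
  # demons-style refinement: optical-flow force (normalized), smoothed and
  # accumulated, drives the edge alignment to sub-voxel precision
  disp <- demons_refine(moving, fixed, disp, n_iterations = demons_iterations)
  best_mse <- mse(apply_deformation(
    moving, new_deformation("nonrigid", disp = disp, voxel_mm = voxel_mm)),
    fixed)
  if ((m0 - best_mse) / m0 < 0.001) {
    if (best_mse >= m0)
      warning("non-rigid registration did not converge; returning identity",
              call. = FALSE)
    return(new_deformation("identity", voxel_mm = voxel_mm,
                           mse_before = m0, mse_after = m0))
  }
  jac <- mean_jacobian_det(disp)
  while ((jac < 0.5 || jac > 2) && max(abs(disp)) > 1e-6) {
    disp <- disp * 0.5
    jac <- mean_jacobian_det(disp)
  }
  f <- new_deformation("nonrigid", disp = disp, voxel_mm = voxel_mm,
                       mean_jacobian = jac, mse_before = m0)
  f$mse_after <- mse(apply_deformation(moving, f), fixed)
  if (f$mse_after > m0)
    return(new_deformation("identity", voxel_mm = voxel_mm,
                           mse_before = m0, mse_after = m0))
  f
}

# central-difference gradient of a volume (one-sided at the edges)
gradient3 <- function(a) {
  d <- dim(a)
  g <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n); im <- pmax(seq_len(n) - 1L, 1L)
    hi <- switch(ax, a[ip, , , drop = FALSE], a[, ip, , drop = FALSE],
                 a[, , ip, drop = FALSE])
    lo <- switch(ax, a[im, , , drop = FALSE], a[, im, , drop = FALSE],
                 a[, , im, drop = FALSE])
    den <- ip - im
    den_arr <- switch(ax,
      array(den, dim = d),
      aperm(array(den, dim = d[c(2, 1, 3)]), c(2, 1, 3)),
      aperm(array(den, dim = d[c(3, 1, 2)]), c(2, 3, 1)))
    g[[ax]] <- (hi - lo) / den_arr
  }
  g
}

# Thirion-style demons iterations refining a displacement field (voxels)
demons_refine <- function(moving, fixed, disp, n_iterations = 20,
                          smooth_sigma = 1) {
  if (n_iterations < 1) return(disp)
  f_of <- function(u) new_deformation("nonrigid", disp = u, voxel_mm = 1)
  best <- disp
  best_mse <- mse(apply_deformation(moving, f_of(disp)), fixed)
  u <- disp
  for (it in seq_len(n_iterations)) {
    w <- apply_deformation(moving, f_of(u))
    diffv <- fixed - w
    gr <- gradient3(w)
    gn <- gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2
    denom <- gn + diffv^2 + 1e-8 * max(gn, 1e-300)
    for (c_ in 1:3)
      u[, , , c_] <- u[, , , c_] -
        gaussian_blur3(diffv * gr[[c_]] / denom, smooth_sigma)
    m <- mse(apply_deformation(moving, f_of(u)), fixed)
    if (m < best_mse) {
      rel <- (best_mse - m) / best_mse
      best <- u; best_mse <- m
      if (rel < 1e-3) break
    } else break
  }
  best
}

# fractional index of x within the (sorted) coarse coordinate vector ctr
approx_index <- function(x, ctr) {
  if (length(ctr) == 1) return(rep(1, length(x)))
  stats::approx(ctr, seq_along(ctr), xout = x, rule = 2)$y
}

#' Register all respiratory bins to end-expiration and average
#'
#' Each non-reference bin is translationally and then non-rigidly registered
#' to the end-expiration bin; the aligned magnitude volumes are averaged to
#' recover the SNR of the full dataset in a single motion-consistent volume
#' per prep.
#'
#' @param bins A [motion_resolved_recon()] `binned_images` object (or a list
#'   of 4D magnitude arrays).
#' @param end_expiration_bin Reference bin (defaults to the one identified
#'   by [assign_bins()]).
#' @param control_spacing_mm Non-rigid control spacing (mm).
#' @return List of per-prep averaged magnitude volumes, with the per-bin
#'   deformation fields attached as an attribute.
#' @export
register_and_average_bins <- function(bins, end_expiration_bin = NULL,
                                      control_spacing_mm = 12) {
  stopifnot(inherits(bins, "binned_images"))
  if (is.null(end_expiration_bin)) end_expiration_bin <- bins$end_expiration_bin
  if (is.null(end_expiration_bin)) end_expiration_bin <- 1L
  out <- vector("list", length(bins$volumes))
  fields <- list()
  aligned <- vector("list", length(bins$volumes))
  for (p in seq_along(bins$volumes)) {
    vol4 <- Mod(bins$volumes[[p]])
    B <- dim(vol4)[4]
    ref <- vol4[, , , end_expiration_bin]
    acc <- ref
    aligned[[p]] <- vol4
    for (b in seq_len(B)) {
      if (b == end_expiration_bin) next
      mov <- vol4[, , , b]
      ft <- tryCatch(register_translation(mov, ref, bins$voxel_mm),
                     error = function(e)
                       stop_invalid("bin %d of prep %d: %s", b, p,
                                    conditionMessage(e)))
      mov_t <- apply_deformation(mov, ft)
      fn <- register_nonrigid(mov_t, ref, control_spacing_mm, bins$voxel_mm)
      aligned[[p]][, , , b] <- apply_deformation(mov_t, fn)
      acc <- acc + aligned[[p]][, , , b]
      fields[[paste0("prep", p, "_bin", b)]] <- list(translation = ft,
                                                     nonrigid = fn)
    }
    out[[p]] <- acc / B
  }
  attr(out, "fields") <- fields
  attr(out, "aligned_bins") <- aligned
  attr(out, "prep_durations_ms") <- bins$prep_durations_ms
  attr(out, "voxel_mm") <- bins$voxel_mm
  out
}

#' Register the averaged T2-prepared volumes to each other
#'
#' Second registration stage: the prep-0 volume (highest signal) is the
#' fixed image; the other prepared volumes are translationally and then
#' non-rigidly registered to it. Order and prep durations are preserved.
#'
#' @param volumes List of per-prep real magnitude volumes (same grid).
#' @param prep_durations_ms Strictly increasing prep durations (ms); taken
#'   from the attribute left by [register_and_average_bins()] if absent.
#' @param voxel_mm Voxel size (mm).
#' @param control_spacing_mm Non-rigid control spacing (mm).
#' @return A `registered_preps` object: `volumes` (aligned), `times_ms`,
#'   `voxel_mm`, per-prep fields.
#' @export
register_preps <- function(volumes, prep_durations_ms = NULL, voxel_mm = NULL,
                           control_spacing_mm = 12) {
  if (is.null(prep_durations_ms))
    prep_durations_ms <- attr(volumes, "prep_durations_ms")
  if (is.null(voxel_mm)) voxel_mm <- attr(volumes, "voxel_mm")
  if (is.null(voxel_mm)) voxel_mm <- 1
  if (is.null(prep_durations_ms) || length(volumes) != length(prep_durations_ms))
    stop_invalid("need one prep duration per volume")
  if (is.unsorted(prep_durations_ms, strictly = TRUE))
    stop_invalid("prep durations must be strictly increasing")
  fixed <- volumes[[1]]
  out <- list(fixed)
  fields <- list()
  for (p in seq_along(volumes)[-1]) {
    mov <- volumes[[p]]
    # the prepared volumes share anatomy but not contrast (the T2
    # preparation scales tissues differently), so the registration is driven
    # on an intensity-matched copy and the resulting geometric transform is
    # applied to the original volume; the demons stage is disabled here
    # because an intensity force across contrasts would trade geometry for
    # brightness and corrupt the decay used for fitting
    sc <- sum(fixed * mov) / max(sum(mov^2), .Machine$double.xmin)
    mov_s <- mov * sc
    ft <- register_translation(mov_s, fixed, voxel_mm)
    fn <- register_nonrigid(apply_deformation(mov_s, ft), fixed,
                            control_spacing_mm, voxel_mm,
                            demons_iterations = 0)
    out[[p]] <- apply_deformation(apply_deformation(mov, ft), fn)
    fields[[paste0("prep", p)]] <- list(translation = ft, nonrigid = fn)
  }
  structure(list(volumes = out, times_ms = prep_durations_ms,
                 voxel_mm = voxel_mm, fields = fields),
            class = "registered_preps")
}
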