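#' Reconstruction configuration
#'
#' @param lambda_weight Regularization weight of the finite-difference
#'   sparsifying transform along the respiratory dimension (default 0.05, the
#'   commonly used value at this spatial resolution). Scaled internally by
#'   the peak magnitude of the initializer so the printed value is
#'   data-scale-invariant.
#' @param n_iterations Nonlinear conjugate-gradient iterations (default 15).
#' @param l1_smoothing_eps Smoothing constant of the l1 surrogate, relative
#'   to the initializer peak magnitude (default 1e-6).
#' @param grid_oversampling Gridding oversampling factor (default 2).
#' @param kernel_width Gridding kernel width (default 5).
#' @param dcf_mode Density-compensation mode (`"pipe-iterative"` default or
#'   `"radial-analytic"`), see [density_compensation()].
#' @param data_weighting `"none"` (default) for the plain least-squares
#'   data term, or `"density"` for density-weighted least squares
#'   (preconditions the radial normal equations; useful for noiseless
#'   convergence studies, but amplifies high-frequency noise).
#' @param tol_rel_objective Early stop when the relative objective change
#'   falls below this (default 1e-4).
#' @return A `recon_config` object.
#' @export
recon_config <- function(lambda_weight = 0.05, n_iterations = 15,
                         l1_smoothing_eps = 1e-6, grid_oversampling = 2,
                         kernel_width = 5, dcf_mode = "pipe-iterative",
                         data_weighting = c("none", "density"),
                         tol_rel_objective = 1e-4) {
  data_weighting <- match.arg(data_weighting)
  if (lambda_weight < 0) stop_invalid("lambda_weight must be >= 0")
  if (n_iterations < 1) stop_invalid("n_iterations must be >= 1")
  if (l1_smoothing_eps <= 0) stop_invalid("l1_smoothing_eps must be > 0")
  structure(list(lambda_weight = lambda_weight,
                 n_iterations = as.integer(n_iterations),
                 l1_smoothing_eps = l1_smoothing_eps,
                 grid_oversampling = grid_oversampling,
                 kernel_width = as.integer(kernel_width),
                 dcf_mode = dcf_mode,
                 data_weighting = data_weighting,
                 tol_rel_objective = tol_rel_objective),
            class = "recon_config")
}

# Pipe-style iterative density estimate: w <- w / (C C^H w) with the
# gridding kernel as the convolution; at the fixed point the kernel-smoothed
# sample density is flat, so the weights are Riemann volume elements. The
# analytic scale factor (kernel autocorrelation mass, oversampled-cell
# volume) makes the density-compensated adjoint amplitude-correct.
dcf_pipe <- function(plan, K, n_iterations = 25) {
  Kos <- K * plan$scale
  w <- rep(1, nrow(K))
  for (it in seq_len(n_iterations)) {
    g <- cpp_kb_spread(as.complex(w), Kos, plan$Mo, plan$width, plan$table)
    d <- Re(cpp_kb_interp(g, Kos, plan$Mo, plan$width, plan$table))
    w <- w / pmax(d, max(d) * 1e-12)
  }
  psi0 <- plan$width * sinh(plan$beta) / plan$beta
  w * psi0^6 * (plan$M / plan$Mo)^3
}

# Analytic radial weights: spherical-shell volume elements shared among the
# spokes (each full spoke samples a shell twice), with a per-spoke solid
# angle from spherical-cap differences over the sorted polar angles (the
# phyllotaxis polar profile is not exactly area-uniform). The DC sample gets
# its Voronoi-equivalent sphere of radius dr/2 shared among spokes.
dcf_radial_analytic <- function(traj, n_spokes) {
  nav <- traj$lines$is_navigator
  r <- abs(traj$radii)
  dr <- traj$matrix / (traj$samples_per_line - 1)
  radial <- 2 * pi * r^2 * dr
  idx <- which(!nav)
  cz <- pmin(pmax(traj$lines$dir_z[idx], -1), 1)
  theta <- acos(cz)
  ord <- order(theta)
  ts <- theta[ord]
  bounds <- c(0, (ts[-1] + ts[-length(ts)]) / 2, pi / 2)
  dom <- 2 * pi * (cos(bounds[-length(bounds)]) - cos(bounds[-1]))
  dom <- dom * (2 * pi / sum(dom))
  omega <- numeric(length(idx))
  omega[ord] <- dom
  omega <- omega * (length(idx) / n_spokes)
  W <- matrix(0, nrow = traj$samples_per_line, ncol = nrow(traj$lines))
  for (j in seq_along(idx)) {
    w <- radial * (omega[j] / (2 * pi))
    w[r == 0] <- (4 / 3) * pi * (dr / 2)^3 / n_spokes
    W[, idx[j]] <- w
  }
  W
}

#' Density compensation for the 3D radial trajectory
#'
#' Per-sample weights that turn the adjoint non-uniform Fourier transform
#' into an amplitude-correct (Riemann-sum) inverse. Two modes:
#' `"pipe-iterative"` (default) estimates the sampling density by iterating
#' `w <- w / (C C^H w)` with the gridding kernel, which captures both the
#' radial |k|^2 law and the slight angular nonuniformity of the
#' spiral-phyllotaxis polar profile; `"radial-analytic"` uses closed-form
#' spherical-shell volume elements (|k|^2 law, DC sample = its
#' Voronoi-equivalent sphere) modulated by per-spoke solid angles.
#' Navigator lines (coincident spokes) receive weight 0 and are excluded
#' from image reconstruction.
#'
#' @param traj A [spiral_phyllotaxis()] trajectory.
#' @param n_spokes Number of (non-navigator) spokes sharing the k-space
#'   ball; defaults to the full trajectory count. Pass the per-bin count
#'   when reconstructing a subset, to keep amplitudes comparable
#'   (radial-analytic mode; pipe mode recomputes on the subset instead).
#' @param mode `"pipe-iterative"` or `"radial-analytic"`.
#' @param line_rows Optional subset of trajectory line rows (pipe mode
#'   computes the density of exactly this subset).
#' @param plan Optional [nufft_plan()] reused for the pipe iteration.
#' @return Samples x lines matrix of nonnegative weights (columns outside
#'   `line_rows` are zero).
#' @export
density_compensation <- function(traj, n_spokes = NULL,
                                 mode = c("pipe-iterative", "radial-analytic"),
                                 line_rows = NULL, plan = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  mode <- match.arg(mode)
  nav <- traj$lines$is_navigator
  if (is.null(line_rows)) line_rows <- which(!nav)
  line_rows <- line_rows[!nav[line_rows]]
  if (is.null(n_spokes)) n_spokes <- length(line_rows)
  if (mode == "radial-analytic") {
    W <- dcf_radial_analytic(traj, n_spokes)
    keep <- logical(nrow(traj$lines)); keep[line_rows] <- TRUE
    W[, !keep] <- 0
    return(W)
  }
  if (is.null(plan)) plan <- nufft_plan(traj$matrix)
  K <- all_sample_positions(traj, line_rows)
  w <- dcf_pipe(plan, K)
  W <- matrix(0, nrow = traj$samples_per_line, ncol = nrow(traj$lines))
  W[, line_rows] <- matrix(w, nrow = traj$samples_per_line)
  W
}

# Map header rows (which repeat the trajectory once per prep) back to
# trajectory line rows.
match_traj_rows <- function(kspace, line_rows) {
  nlines_prep <- nrow(kspace$traj$lines)
  ((line_rows - 1L) %% nlines_prep) + 1L
}

#' Density-compensated adjoint (gridding) reconstruction
#'
#' Adjoint non-uniform Fourier transform of the density-compensated data,
#' coil-combined with conjugate sensitivities (or root-sum-of-squares when
#' no sensitivities are given). Navigator lines are excluded.
#'
#' @param kspace A `kspace_data` object.
#' @param traj Its trajectory (defaults to `kspace$traj`).
#' @param weights Optional samples x lines weight matrix as produced by
#'   [density_compensation()] (computed if `NULL`).
#' @param sens Optional complex coil sensitivities
#'   (matrix^3 x coils array).
#' @param prep Which prepared volume to reconstruct (default 1).
#' @param line_rows Optional explicit header-row subset (navigators are
#'   always dropped).
#' @param plan Optional precomputed [nufft_plan()].
#' @return Complex image volume.
#' @export
adjoint_recon <- function(kspace, traj = kspace$traj, weights = NULL,
                          sens = NULL, prep = 1, line_rows = NULL,
                          plan = NULL, dcf_mode = "pipe-iterative") {
  stopifnot(inherits(kspace, "kspace_data"))
  h <- kspace$headers
  if (is.null(line_rows))
    line_rows <- which(h$prep_index == prep & !h$is_navigator)
  else
    line_rows <- line_rows[!h$is_navigator[line_rows]]
  if (length(line_rows) == 0) stop_invalid("no readout lines selected")
  if (!is.null(sens) && !all(dim(sens)[1:3] == kspace$matrix))
    stop_invalid("sensitivity map grid does not match the data grid")
  if (is.null(plan)) plan <- nufft_plan(kspace$matrix)
  traj_rows <- match_traj_rows(kspace, line_rows)
  if (is.null(weights))
    weights <- density_compensation(traj, mode = dcf_mode,
                                    line_rows = traj_rows, plan = plan)
  K <- all_sample_positions(traj, traj_rows)
  w <- as.vector(weights[, traj_rows])
  M <- kspace$matrix
  out <- array(0i, dim = rep(M, 3))
  rss <- NULL
  for (c_ in seq_len(kspace$n_coils)) {
    y <- as.vector(kspace$data[, line_rows, c_]) * w
    xc <- nufft_adjoint(plan, y, K) / M^3
    if (is.null(sens)) {
      if (is.null(rss)) rss <- array(0, dim = rep(M, 3))
      rss <- rss + Mod(xc)^2
    } else {
      out <- out + Conj(sens[, , , c_]) * xc
    }
  }
  if (is.null(sens)) out <- sqrt(rss) + 0i
  out
}

#' Estimate coil sensitivity maps from the data
#'
#' Low-resolution (Gaussian-apodized) adjoint images per coil, divided by
#' their root-sum-of-squares and masked to the object support (RSS above 5%
#' of its maximum). A single-coil dataset returns a uniform all-ones map.
#'
#' @param kspace A `kspace_data` object.
#' @param traj Its trajectory.
#' @param prep Prepared volume used for the estimate (default 1, the
#'   highest-signal one).
#' @param lowres_frac Gaussian apodization width as a fraction of kmax.
#' @return Complex array matrix^3 x coils with a `support` attribute.
#' @export
estimate_sensitivities <- function(kspace, traj = kspace$traj, prep = 1,
                                   lowres_frac = 0.3) {
  stopifnot(inherits(kspace, "kspace_data"))
  M <- kspace$matrix
  if (kspace$n_coils == 1) {
    s <- array(1 + 0i, dim = c(M, M, M, 1))
    attr(s, "support") <- array(TRUE, dim = rep(M, 3))
    return(s)
  }
  h <- kspace$headers
  line_rows <- which(h$prep_index == prep & !h$is_navigator)
  traj_rows <- match_traj_rows(kspace, line_rows)
  K <- all_sample_positions(traj, traj_rows)
  plan <- nufft_plan(M)
  w <- as.vector(density_compensation(traj, line_rows = traj_rows,
                                      plan = plan)[, traj_rows])
  apod <- exp(-(rowSums(K^2)) / (2 * (lowres_frac * M / 2)^2))
  imgs <- array(0i, dim = c(M, M, M, kspace$n_coils))
  for (c_ in seq_len(kspace$n_coils)) {
    y <- as.vector(kspace$data[, line_rows, c_]) * w * apod
    imgs[, , , c_] <- nufft_adjoint(plan, y, K) / M^3
  }
  rss <- sqrt(apply(Mod(imgs)^2, 1:3, sum))
  support <- rss >= 0.05 * max(rss)
  sens <- array(0i, dim = dim(imgs))
  for (c_ in seq_len(kspace$n_coils)) {
    sc <- imgs[, , , c_]
    sc[!support] <- 0
    sc[support] <- sc[support] / rss[support]
    sens[, , , c_] <- sc
  }
  attr(sens, "support") <- support
  sens
}

# Forward coil-wise NUFFT of one bin: E x = {NUFFT(s_c * x)}_c
op_forward <- function(plan, x, K, sens) {
  nc <- dim(sens)[4]
  y <- matrix(0i, nrow = nrow(K), ncol = nc)
  for (c_ in seq_len(nc))
    y[, c_] <- nufft_forward(plan, x * sens[, , , c_], K)
  y
}

# Adjoint: E^H y = sum_c conj(s_c) * NUFFT^H(y_c)
op_adjoint <- function(plan, y, K, sens, M) {
  nc <- dim(sens)[4]
  out <- array(0i, dim = rep(M, 3))
  for (c_ in seq_len(nc))
    out <- out + Conj(sens[, , , c_]) * nufft_adjoint(plan, y[, c_], K)
  out
}

# Smoothed l1 of the finite differences along the bin dimension and its
# gradient (list of per-bin volumes). x is a list of B complex volumes.
reg_value <- function(x, eps) {
  B <- length(x)
  if (B < 2) return(0)
  v <- 0
  for (b in seq_len(B - 1)) {
    d <- x[[b + 1]] - x[[b]]
    v <- v + sum(sqrt(Mod(d)^2 + eps^2))
  }
  v
}

reg_grad <- function(x, eps) {
  B <- length(x)
  g <- lapply(x, function(z) array(0i, dim = dim(z)))
  if (B < 2) return(g)
  for (b in seq_len(B - 1)) {
    d <- x[[b + 1]] - x[[b]]
    u <- d / sqrt(Mod(d)^2 + eps^2)
    g[[b]] <- g[[b]] - u
    g[[b + 1]] <- g[[b + 1]] + u
  }
  g
}

cinner <- function(a, b) sum(Re(Conj(unlist(a)) * unlist(b)))

#' Respiratory motion-resolved compressed-sensing reconstruction
#'
#' Reconstructs, independently for every T2 preparation, one image per
#' respiratory bin by minimizing
#' \deqn{\frac12 \sum_b \|E_b x_b - y_b\|_2^2 +
#'       \lambda' \sum_{b=1}^{B-1} \|x_{b+1} - x_b\|_{1,\epsilon}}
#' where \eqn{E_b} is the coil-weighted non-uniform Fourier transform of bin
#' b's lines and the second term is the (epsilon-smoothed) l1 norm of the
#' finite differences along the respiratory dimension with weight
#' \eqn{\lambda' = \lambda \max|x_0|}. Solved by Fletcher-Reeves nonlinear
#' conjugate gradient with an Armijo backtracking line search, initialized
#' from the per-bin density-compensated adjoint.
#'
#' @param kspace A `kspace_data` object.
#' @param traj Its trajectory.
#' @param signal A binned [assign_bins()] respiratory signal (one entry per
#'   navigator, i.e. per prep x interleave).
#' @param sens Coil sensitivities (estimated from the data when `NULL`).
#' @param config A [recon_config()].
#' @param preps Which prepared volumes to reconstruct (default all).
#' @return A `binned_images` object: `volumes` (list per prep of complex
#'   x,y,z,bin arrays), `bin_counts`, `objective` traces (data term,
#'   regularizer per iteration), `end_expiration_bin`, grid metadata.
#' @export
motion_resolved_recon <- function(kspace, traj = kspace$traj, signal,
                                  sens = NULL, config = recon_config(),
                                  preps = NULL) {
  stopifnot(inherits(kspace, "kspace_data"), inherits(signal, "resp_signal"))
  if (is.null(signal$bin)) stop_invalid("signal has no bins; call assign_bins()")
  if (is.null(preps)) preps <- seq_along(kspace$prep_durations_ms)
  if (is.null(sens)) sens <- estimate_sensitivities(kspace, traj)
  M <- kspace$matrix
  B <- signal$n_bins
  plan <- nufft_plan(M, oversampling = config$grid_oversampling,
                     width = config$kernel_width)
  h <- kspace$headers
  volumes <- list(); traces <- list()
  bin_counts <- matrix(0L, nrow = B, ncol = length(preps),
                       dimnames = list(NULL, paste0("prep", preps)))
  for (pi_ in seq_along(preps)) {
    p <- preps[pi_]
    # navigator-derived bin of each interleave of this prep
    sel <- if (is.null(signal$prep_index)) rep(TRUE, length(signal$bin))
           else signal$prep_index == p
    il_bin <- signal$bin[sel]
    il_ids <- if (is.null(signal$interleave)) seq_along(il_bin)
              else signal$interleave[sel]
    Ks <- list(); ys <- list(); x <- list(); bin_traj_rows <- list()
    for (b in seq_len(B)) {
      ils <- il_ids[il_bin == b]
      line_rows <- which(h$prep_index == p & !h$is_navigator &
                           h$interleave %in% ils)
      if (length(line_rows) == 0)
        stop_invalid("respiratory bin %d of prep %d holds no data", b, p)
      bin_counts[b, pi_] <- length(ils)
      traj_rows <- match_traj_rows(kspace, line_rows)
      bin_traj_rows[[b]] <- traj_rows
      Ks[[b]] <- all_sample_positions(traj, traj_rows)
      yb <- matrix(0i, nrow = nrow(Ks[[b]]), ncol = kspace$n_coils)
      for (c_ in seq_len(kspace$n_coils))
        yb[, c_] <- as.vector(kspace$data[, line_rows, c_])
      ys[[b]] <- yb
    }
    # shared initializer: the pooled (motion-averaged) adjoint of all of the
    # prep's lines. A per-bin adjoint would imprint each bin's own
    # undersampling artifacts, which the weakly coupled objective removes
    # only slowly; the pooled image is artifact-poor and bin-neutral.
    x0 <- adjoint_recon(kspace, traj, sens = sens, prep = p, plan = plan,
                        dcf_mode = config$dcf_mode)
    x <- replicate(B, x0, simplify = FALSE)
    # optional density-weighted least squares: with data_weighting =
    # "density" the data term is 1/2 sum_b ||W_b^(1/2)(E_b x_b - y_b)||^2,
    # which preconditions the radial normal equations (useful for
    # noiseless convergence studies; W^(1/2)E and E^H W^(1/2) remain an
    # exact adjoint pair). The default is the plain unweighted term: with
    # noisy data the weighting emphasizes the sparsely sampled high
    # frequencies and amplifies noise at practical iteration counts.
    weighted <- identical(config$data_weighting, "density")
    sw <- if (weighted) {
      W_analytic <- if (config$dcf_mode != "pipe-iterative")
        density_compensation(traj, mode = "radial-analytic") else NULL
      lapply(seq_len(B), function(b) {
        w <- if (is.null(W_analytic)) dcf_pipe(plan, Ks[[b]])
             else as.vector(W_analytic[, bin_traj_rows[[b]]])
        matrix(sqrt(w), nrow = nrow(Ks[[b]]), ncol = kspace$n_coils)
      })
    } else NULL
    if (weighted) for (b in seq_len(B)) ys[[b]] <- ys[[b]] * sw[[b]]
    x0max <- max(vapply(x, function(z) max(Mod(z)), numeric(1)))
    lam <- config$lambda_weight * x0max
    eps <- config$l1_smoothing_eps * max(x0max, .Machine$double.xmin)
    wmul <- function(z, b) if (weighted) z * sw[[b]] else z
    r <- lapply(seq_len(B), function(b)
      wmul(op_forward(plan, x[[b]], Ks[[b]], sens), b) - ys[[b]])
    data_term <- 0.5 * sum(vapply(r, function(z) sum(Mod(z)^2), numeric(1)))
    obj <- data_term + lam * reg_value(x, eps)
    trace <- data.frame(iteration = 0, objective = obj,
                        data_term = data_term,
                        regularizer = reg_value(x, eps))
    g_prev_norm <- NULL; g_prev <- NULL; pdir <- NULL
    for (it in seq_len(config$n_iterations)) {
      rg <- reg_grad(x, eps)
      g <- lapply(seq_len(B), function(b)
        op_adjoint(plan, wmul(r[[b]], b), Ks[[b]], sens, M) + lam * rg[[b]])
      gnorm <- cinner(g, g)
      if (!is.finite(gnorm))
        stop_invalid("non-finite gradient at iteration %d (objective trace: %s)",
                     it, paste(signif(trace$objective, 6), collapse = ", "))
      if (is.null(pdir)) {
        pdir <- lapply(g, function(z) -z)
      } else {
        # Polak-Ribiere+ with restart on loss of descent
        beta <- max(0, (gnorm - cinner(g, g_prev)) / g_prev_norm)
        pdir <- lapply(seq_len(B), function(b) -g[[b]] + beta * pdir[[b]])
        if (cinner(g, pdir) >= 0) pdir <- lapply(g, function(z) -z)  # restart
      }
      g_prev_norm <- gnorm
      g_prev <- g
      q <- lapply(seq_len(B), function(b)
        wmul(op_forward(plan, pdir[[b]], Ks[[b]], sens), b))
      qq <- sum(vapply(q, function(z) sum(Mod(z)^2), numeric(1)))
      rq <- sum(vapply(seq_len(B), function(b)
        sum(Re(Conj(r[[b]]) * q[[b]])), numeric(1)))
      alpha <- if (qq > 0) -rq / qq else 1
      if (alpha <= 0) alpha <- 1e-8
      slope <- cinner(g, pdir)      # directional derivative (< 0)
      ok <- FALSE
      for (ls in 1:20) {
        dt_ <- 0.5 * sum(vapply(seq_len(B), function(b)
          sum(Mod(r[[b]] + alpha * q[[b]])^2), numeric(1)))
        xn <- lapply(seq_len(B), function(b) x[[b]] + alpha * pdir[[b]])
        newobj <- dt_ + lam * reg_value(xn, eps)
        if (is.finite(newobj) && newobj <= obj + 1e-4 * alpha * slope) {
          ok <- TRUE; break
        }
        alpha <- alpha / 2
      }
      if (!ok) break               # no further descent possible
      x <- xn
      r <- lapply(seq_len(B), function(b) r[[b]] + alpha * q[[b]])
      relchg <- (obj - newobj) / max(obj, .Machine$double.xmin)
      obj <- newobj
      trace <- rbind(trace, data.frame(iteration = it, objective = obj,
                                       data_term = dt_,
                                       regularizer = reg_value(x, eps)))
      if (relchg < config$tol_rel_objective) break
    }
    vol <- array(0i, dim = c(M, M, M, B))
    for (b in seq_len(B)) vol[, , , b] <- x[[b]]
    volumes[[pi_]] <- vol
    traces[[pi_]] <- trace
  }
  structure(list(volumes = volumes, bin_counts = bin_counts,
                 objective = traces, preps = preps,
                 prep_durations_ms = kspace$prep_durations_ms[preps],
                 end_expiration_bin = signal$end_expiration_bin,
                 matrix = M, voxel_mm = kspace$fov_mm / M,
                 config = config),
            class = "binned_images")
}

#' Baseline self-navigated (1D-corrected) reconstruction
#'
#' Corrects every interleave for its estimated superior-inferior displacement
#' by the k-space translation theorem (per-sample linear phase along kz) and
#' then grids all lines of a prep together with [adjoint_recon()].
#'
#' @param kspace A `kspace_data` object.
#' @param traj Its trajectory.
#' @param disp An [estimate_si_displacement()] result with one displacement
#'   per navigator.
#' @param sens Optional coil sensitivities.
#' @param prep Prepared volume to reconstruct.
#' @return Complex image volume.
#' @export
selfnav_recon <- function(kspace, traj = kspace$traj, disp, sens = NULL,
                          prep = 1) {
  stopifnot(inherits(kspace, "kspace_data"), inherits(disp, "si_displacement"))
  h <- kspace$headers
  line_rows <- which(h$prep_index == prep & !h$is_navigator)
  sel <- if (is.null(disp$prep_index)) rep(TRUE, length(disp$displacement_mm))
         else disp$prep_index == prep
  dz_mm <- disp$displacement_mm[sel]
  ils <- disp$interleave[sel]
  idx <- match(h$interleave[line_rows], ils)
  if (any(is.na(idx)))
    stop_invalid("missing displacement for some interleaves of prep %d", prep)
  corrected <- kspace
  M <- kspace$matrix
  voxel <- kspace$fov_mm / M
  traj_rows <- match_traj_rows(kspace, line_rows)
  kz <- outer(traj$radii, traj$lines$dir_z[traj_rows])
  phase <- exp(2i * pi * kz *
                 matrix(dz_mm[idx] / voxel, nrow = kspace$samples_per_line,
                        ncol = length(line_rows), byrow = TRUE) / M)
  for (c_ in seq_len(kspace$n_coils))
    corrected$data[, line_rows, c_] <- kspace$data[, line_rows, c_] * phase
  adjoint_recon(corrected, traj, sens = sens, prep = prep)
}
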