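#' Two-parameter exponential T2 fit
#'
#' Least-squares fit of \eqn{S(t) = A e^{-t/T_2}} to the prepared signals
#' (the model used by routine 2D mapping, no offset). The closed-form
#' log-linear solution initializes a nonlinear least-squares refinement; two
#' points are solved exactly by the log ratio. Non-decaying signals are
#' reported as invalid fits, not errors.
#'
#' @param signals Positive signal values, one per prep duration.
#' @param times_ms Strictly increasing prep durations (ms).
#' @return List `a`, `t2_ms`, `valid`, `residual`.
#' @export
fit2 <- function(signals, times_ms) {
  if (length(signals) != length(times_ms) || length(signals) < 2)
    stop_invalid("need >= 2 signals with matching times")
  if (is.unsorted(times_ms, strictly = TRUE))
    stop_invalid("times must be strictly increasing")
  bad <- list(a = NA_real_, t2_ms = NA_real_, valid = FALSE,
              residual = NA_real_)
  if (any(!is.finite(signals)) || any(signals <= 0)) return(bad)
  if (length(signals) == 2) {
    if (signals[2] >= signals[1]) return(bad)
    t2 <- diff(times_ms) / log(signals[1] / signals[2])
    return(list(a = signals[1] * exp(times_ms[1] / t2), t2_ms = t2,
                valid = TRUE, residual = 0))
  }
  co <- unname(stats::coef(stats::lm(log(signals) ~ times_ms)))
  if (!is.finite(co[2]) || co[2] >= 0) return(bad)
  t2 <- -1 / co[2]; a <- exp(co[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ A * exp(-t / T2),
                      data = data.frame(s = signals, t = times_ms),
                      start = list(A = a, T2 = t2),
                      lower = c(0, 1e-3), upper = c(Inf, 5000),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    a <- unname(cf["A"]); t2 <- unname(cf["T2"])
  }
  if (!is.finite(t2) || t2 <= 0) return(bad)
  list(a = a, t2_ms = t2, valid = TRUE,
       residual = sqrt(mean((signals - a * exp(-times_ms / t2))^2)))
}

#' Three-parameter offset T2 fit
#'
#' Fit of \eqn{S(t) = A e^{-t/T_2} + B}; the offset B accounts for the T1
#' recovery during the bSSFP readout train, which makes the apparent
#' prepared signal affine rather than proportional in \eqn{e^{-\tau/T_2}}.
#' With exactly three points the system is exactly determined: T2 solves
#' \eqn{(S_1-S_2)/(S_2-S_3) = (e_1-e_2)/(e_2-e_3)} by 1D root finding on
#' \[1, 500\] ms, and (A, B) follow linearly. More points are fitted by a
#' profiled least squares over T2. Constraints: T2 in \[1, 500\] ms, A > 0;
#' degenerate (equal) signals are reported invalid.
#'
#' @param signals Nonnegative signal values.
#' @param times_ms Strictly increasing prep durations (ms).
#' @param t2_bounds_ms Admissible T2 range (default `c(1, 500)`).
#' @return List `a`, `b`, `t2_ms`, `valid`, `residual`.
#' @export
fit3 <- function(signals, times_ms, t2_bounds_ms = c(1, 500)) {
  if (length(signals) != length(times_ms) || length(signals) < 3)
    stop_invalid("need >= 3 signals with matching times")
  if (is.unsorted(times_ms, strictly = TRUE))
    stop_invalid("times must be strictly increasing")
  bad <- list(a = NA_real_, b = NA_real_, t2_ms = NA_real_, valid = FALSE,
              residual = NA_real_)
  if (any(!is.finite(signals)) || any(signals < 0)) return(bad)
  lo <- t2_bounds_ms[1]; hi <- t2_bounds_ms[2]
  solve_ab <- function(t2) {
    e <- exp(-times_ms / t2)
    X <- cbind(e, 1)
    co <- tryCatch(qr.solve(crossprod(X), crossprod(X, signals)),
                   error = function(e) c(NA, NA))
    c(co)
  }
  if (length(signals) == 3) {
    dS12 <- signals[1] - signals[2]; dS23 <- signals[2] - signals[3]
    if (dS12 == 0 && dS23 == 0) return(bad)   # flat: degenerate
    if (dS23 <= 0 || dS12 <= 0) {
      # not a monotone decay; fall through to bounded LS below
      t2 <- NA_real_
    } else {
      R <- dS12 / dS23
      g <- function(t2) {
        e <- exp(-times_ms / t2)
        (e[1] - e[2]) / (e[2] - e[3]) - R
      }
      glo <- g(lo); ghi <- g(hi)
      t2 <- if (is.finite(glo) && is.finite(ghi) && glo * ghi < 0)
        stats::uniroot(g, c(lo, hi), tol = 1e-10)$root else NA_real_
    }
    if (is.finite(t2)) {
      ab <- solve_ab(t2)
      if (all(is.finite(ab)) && ab[1] > 0) {
        res <- sqrt(mean((signals - ab[1] * exp(-times_ms / t2) - ab[2])^2))
        return(list(a = ab[1], b = ab[2], t2_ms = t2, valid = TRUE,
                    residual = res))
      }
    }
  }
  # profiled least squares over T2 (general case / fallback)
  sse <- function(t2) {
    ab <- solve_ab(t2)
    if (any(!is.finite(ab))) return(Inf)
    sum((signals - ab[1] * exp(-times_ms / t2) - ab[2])^2)
  }
  op <- stats::optimize(sse, c(lo, hi), tol = 1e-8)
  t2 <- op$minimum
  ab <- solve_ab(t2)
  if (any(!is.finite(ab)) || ab[1] <= 0 || !is.finite(t2)) return(bad)
  list(a = ab[1], b = ab[2], t2_ms = t2, valid = TRUE,
       residual = sqrt(op$objective / length(signals)))
}

#' Fit the parametrized edge sigmoid to a sampled T2 profile
#'
#' Nonlinear least-squares fit of
#' \eqn{T_2(x) = a / (1 + e^{-k(b + x)}) + c} to a profile sampled along a
#' line, where a, b, c are scaling variables and k (per mm) is the edge
#' sharpness. This is the per-line primitive behind [sharpness()].
#'
#' @param x_mm Sample positions along the line (mm).
#' @param y T2 values at those positions (ms).
#' @param k_max Upper bound on k; fits at the bound are treated as saturated
#'   by the caller.
#' @return Named coefficient vector `(a, b, c, k)`, or `NULL` if the fit
#'   fails or the profile is flat.
#' @export
fit_sigmoid <- function(x_mm, y, k_max = 25) {
  lo_y <- min(y); hi_y <- max(y)
  if (hi_y - lo_y < 1e-9) return(NULL)
  mid <- x_mm[which.max(abs(diff(y)))]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a / (1 + exp(-k * (b + x))) + c,
                      data = data.frame(x = x_mm, y = y),
                      start = list(a = hi_y - lo_y, b = -mid, c = lo_y,
                                   k = 1),
                      lower = c(-Inf, -Inf, -Inf, 1e-3),
                      upper = c(Inf, Inf, Inf, k_max),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  stats::coef(fit)
}

# Vectorized exactly-determined offset fit for 3-point decays: solves
# (S1-S2)/(S2-S3) = (e1-e2)/(e2-e3) by bisection on T2 (the ratio is
# monotone decreasing in T2) for all voxels at once; (A, B) follow linearly.
# Voxels without a bracketed root are left invalid for the scalar fallback.
fit3_bulk <- function(S, times_ms, t2_bounds_ms = c(1, 500)) {
  n <- nrow(S)
  out <- list(t2 = rep(NA_real_, n), a = rep(NA_real_, n),
              b = rep(NA_real_, n), valid = logical(n))
  dS12 <- S[, 1] - S[, 2]; dS23 <- S[, 2] - S[, 3]
  cand <- which(is.finite(dS12) & is.finite(dS23) & dS12 > 0 & dS23 > 0)
  if (length(cand) == 0) return(out)
  R <- dS12[cand] / dS23[cand]
  ratio_at <- function(t2) {
    e1 <- exp(-times_ms[1] / t2); e2 <- exp(-times_ms[2] / t2)
    e3 <- exp(-times_ms[3] / t2)
    (e1 - e2) / (e2 - e3)
  }
  lo <- rep(t2_bounds_ms[1], length(cand))
  hi <- rep(t2_bounds_ms[2], length(cand))
  bracket <- (ratio_at(lo) - R) * (ratio_at(hi) - R) < 0
  cand <- cand[bracket]
  if (length(cand) == 0) return(out)
  R <- R[bracket]; lo <- lo[bracket]; hi <- hi[bracket]
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    g <- ratio_at(mid) - R
    above <- g > 0           # ratio too large => T2 below the root
    lo[above] <- mid[above]
    hi[!above] <- mid[!above]
  }
  t2 <- (lo + hi) / 2
  e <- cbind(exp(-times_ms[1] / t2), exp(-times_ms[2] / t2),
             exp(-times_ms[3] / t2))
  # least-squares (A, B) given T2; exact for the bracketed 3-point system
  se <- rowSums(e); see <- rowSums(e^2); sy <- rowSums(S[cand, , drop = FALSE])
  sey <- rowSums(e * S[cand, , drop = FALSE])
  det <- 3 * see - se^2
  A <- (3 * sey - se * sy) / det
  B <- (sy - A * se) / 3
  good <- is.finite(A) & A > 0 & is.finite(B)
  out$t2[cand[good]] <- t2[good]
  out$a[cand[good]] <- A[good]
  out$b[cand[good]] <- B[good]
  out$valid[cand[good]] <- TRUE
  out
}

# Vectorized profiled grid search for 3-point fits that the exact solver
# rejects (non-monotone, noise-dominated voxels): closed-form (A, B) on a
# T2 grid, minimum SSE with parabolic refinement, A > 0 required.
fit3_grid <- function(S, times_ms, t2_bounds_ms = c(1, 500), n_grid = 120) {
  n <- nrow(S)
  out <- list(t2 = rep(NA_real_, n), a = rep(NA_real_, n),
              b = rep(NA_real_, n), resid = rep(NA_real_, n),
              valid = logical(n))
  flat <- !is.finite(rowSums(S)) | (S[, 1] == S[, 2] & S[, 2] == S[, 3])
  grid <- exp(seq(log(t2_bounds_ms[1]), log(t2_bounds_ms[2]),
                  length.out = n_grid))
  E <- exp(outer(-1 / grid, times_ms))          # n_grid x 3
  se <- rowSums(E); see <- rowSums(E^2)
  det3 <- 3 * see - se^2
  sy <- rowSums(S); sey <- S %*% t(E)           # n x n_grid
  A <- sweep(3 * sey, 2, det3, "/") - outer(sy, se / det3)
  Bm <- (matrix(sy, n, n_grid) - sweep(A, 2, se, "*")) / 3
  # SSE = sum_i (S_i - A e_i - B)^2, expanded with per-grid constants
  ss <- rowSums(S^2)
  sse <- matrix(ss, n, n_grid) - 2 * A * sey - 2 * Bm * sy +
    sweep(A^2, 2, see, "*") + 2 * A * Bm * matrix(se, n, n_grid,
                                                  byrow = TRUE) + 3 * Bm^2
  sse[A <= 0] <- Inf
  best <- max.col(-sse, ties.method = "first")
  okv <- !flat & is.finite(sse[cbind(seq_len(n), best)])
  out$t2[okv] <- grid[best[okv]]
  out$a[okv] <- A[cbind(seq_len(n), best)][okv]
  out$b[okv] <- Bm[cbind(seq_len(n), best)][okv]
  out$resid[okv] <- sqrt(pmax(sse[cbind(seq_len(n), best)][okv], 0) / 3)
  out$valid <- okv
  out
}

#' Voxel-wise T2 map from registered prepared volumes
#'
#' Fits every voxel inside the mask independently with [fit3()] (offset
#' model, the default for the 3D technique) or [fit2()] (the 2D-technique
#' model). The default validity mask keeps voxels whose prep-0 magnitude
#' exceeds 5% of the volume maximum; invalid fits are masked, residuals
#' stored.
#'
#' @param preps A [register_preps()] `registered_preps` object, or a list of
#'   aligned real volumes with `times_ms`/`voxel_mm` supplied.
#' @param model `"three_param"` (default) or `"two_param"`.
#' @param mask Optional logical volume restricting the fit.
#' @param times_ms,voxel_mm Required when `preps` is a bare list.
#' @return A `t2_map` object: `t2_ms`, `a`, `b` (offset model), `mask`,
#'   `residual` volumes, `voxel_mm`.
#' @export
map_volume <- function(preps, model = c("three_param", "two_param"),
                       mask = NULL, times_ms = NULL, voxel_mm = NULL) {
  model <- match.arg(model)
  if (inherits(preps, "registered_preps")) {
    vols <- preps$volumes; times_ms <- preps$times_ms
    voxel_mm <- preps$voxel_mm
  } else {
    vols <- preps
    if (is.null(times_ms)) stop_invalid("times_ms required for a bare list")
    if (is.null(voxel_mm)) voxel_mm <- 1
  }
  d <- dim(vols[[1]])
  if (is.null(mask)) mask <- vols[[1]] > 0.05 * max(vols[[1]])
  S <- vapply(vols, as.vector, numeric(prod(d)))
  idx <- which(as.vector(mask))
  t2 <- rep(NA_real_, prod(d)); a <- t2; b <- t2; resid <- t2
  ok <- logical(prod(d))
  if (model == "three_param" && length(times_ms) == 3) {
    # exactly determined voxels solved in bulk by bisection on the
    # difference-ratio equation; voxels without a monotone decay (noise)
    # fall back to a vectorized profiled grid search
    v <- fit3_bulk(S[idx, , drop = FALSE], times_ms)
    hit <- v$valid
    t2[idx[hit]] <- v$t2[hit]; a[idx[hit]] <- v$a[hit]
    b[idx[hit]] <- v$b[hit]; resid[idx[hit]] <- 0
    ok[idx[hit]] <- TRUE
    rest <- idx[!hit]
    if (length(rest) > 0) {
      g <- fit3_grid(S[rest, , drop = FALSE], times_ms)
      gh <- g$valid
      t2[rest[gh]] <- g$t2[gh]; a[rest[gh]] <- g$a[gh]
      b[rest[gh]] <- g$b[gh]; resid[rest[gh]] <- g$resid[gh]
      ok[rest[gh]] <- TRUE
    }
    idx <- integer(0)
  }
  for (i in idx) {
    f <- fit2(S[i, ], times_ms)
    if (f$valid) {
      t2[i] <- f$t2_ms; a[i] <- f$a; resid[i] <- f$residual
      ok[i] <- TRUE
    }
  }
  structure(list(t2_ms = array(t2, d), a = array(a, d),
                 b = if (model == "three_param") array(b, d) else NULL,
                 mask = array(ok, d), residual = array(resid, d),
                 model = model, times_ms = times_ms,
                 voxel_mm = voxel_mm),
            class = "t2_map")
}

#' Region statistics of a T2 map
#'
#' Mean, sample standard deviation, and coefficient of variation
#' (CoV = 100 * SD / mean, the inverse proxy of map precision) of the valid
#' T2 values inside a region of interest.
#'
#' @param map A [map_volume()] `t2_map`.
#' @param roi_mask Logical volume.
#' @return List `mean_t2_ms`, `sd_t2_ms`, `cov_percent`, `n_voxels`.
#' @export
region_stats <- function(map, roi_mask) {
  stopifnot(inherits(map, "t2_map"))
  vals <- map$t2_ms[roi_mask & map$mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2) stop_invalid("ROI holds fewer than 2 valid voxels")
  m <- mean(vals); s <- stats::sd(vals)
  list(mean_t2_ms = m, sd_t2_ms = s, cov_percent = 100 * s / m,
       n_voxels = length(vals))
}

#' Sigmoid edge sharpness of a T2 map
#'
#' Samples the T2 map along a line (0.5-voxel steps, trilinear
#' interpolation) from the mid-septal myocardium into the left-ventricular
#' blood pool and fits the parametrized sigmoid
#' \deqn{T_2(x) = a / (1 + e^{-k(b + x)}) + c}
#' where k (mm^-1) is the edge sharpness (higher = sharper). The fit is
#' repeated on five adjacent parallel lines (offsets -2..+2 voxels along the
#' in-plane normal) and the mean k is reported. Lines whose fit fails are
#' dropped with a warning; fewer than 3 surviving lines invalidates the
#' result. k saturating at the upper bound is flagged.
#'
#' @param map A `t2_map`.
#' @param line_start_voxel,line_end_voxel 1-based voxel coordinates (length
#'   3) of the line endpoints.
#' @param n_lines Number of adjacent lines (default 5).
#' @param k_max Upper bound on k (mm^-1) at which the fit is flagged as
#'   saturated (default 25).
#' @return A `sigmoid_fit` object: `k_per_line`, `mean_k`, `params` of the
#'   center line, `saturated`, `valid`.
#' @export
sharpness <- function(map, line_start_voxel, line_end_voxel, n_lines = 5,
                      k_max = 25) {
  stopifnot(inherits(map, "t2_map"))
  vol <- map$t2_ms
  vol[!map$mask] <- NA
  u <- line_end_voxel - line_start_voxel
  len_vox <- sqrt(sum(u^2))
  if (len_vox * 2 + 1 < 8) stop_invalid("line too short (< 8 samples)")
  u <- u / len_vox
  # slice plane: the axis with the smallest direction component is the slice
  # normal; the in-plane perpendicular is u x normal
  ax <- which.min(abs(u))
  nrm <- c(0, 0, 0); nrm[ax] <- 1
  perp <- c(u[2] * nrm[3] - u[3] * nrm[2],
            u[3] * nrm[1] - u[1] * nrm[3],
            u[1] * nrm[2] - u[2] * nrm[1])
  perp <- perp / sqrt(sum(perp^2))
  offsets <- seq_len(n_lines) - (n_lines + 1) / 2
  steps <- seq(0, len_vox, by = 0.5)
  x_mm <- steps * map$voxel_mm
  fit_one <- function(off) {
    p0 <- line_start_voxel + off * perp
    pts <- cbind(p0[1] + steps * u[1], p0[2] + steps * u[2],
                 p0[3] + steps * u[3])
    navol <- vol; navol[is.na(navol)] <- 0
    valid_s <- sample_trilinear((!is.na(vol)) * 1, pts) > 0.99
    y <- sample_trilinear(navol, pts)
    if (sum(valid_s) < 8) return(NULL)
    fit_sigmoid(x_mm[valid_s], y[valid_s], k_max = k_max)
  }
  fits <- lapply(offsets, fit_one)
  okl <- !vapply(fits, is.null, logical(1))
  if (any(!okl))
    warning(sprintf("%d of %d sharpness lines dropped (fit failure)",
                    sum(!okl), n_lines), call. = FALSE)
  ks <- vapply(fits[okl], function(cf) unname(cf["k"]), numeric(1))
  valid <- sum(okl) >= 3
  center <- NULL
  for (i in order(abs(offsets))) if (okl[i]) { center <- fits[[i]]; break }
  structure(list(k_per_line = ks, mean_k = if (valid) mean(ks) else NA_real_,
                 params = center, saturated = any(ks >= k_max * 0.999),
                 valid = valid, n_lines_used = sum(okl)),
            class = "sigmoid_fit")
}

#' Relative voxel volume of two protocols
#'
#' Ratio of a (possibly anisotropic) voxel volume to an isotropic one, the
#' standard way to report how much smaller the 3D technique's voxels are
#' than the routine 2D protocol's (1.9 x 1.9 x 8 mm vs 1.6 mm isotropic
#' rounds to 7).
#'
#' @param voxel_a_mm Length-3 voxel dimensions (mm) of the reference
#'   protocol (default `c(1.9, 1.9, 8)`).
#' @param voxel_b_mm Isotropic voxel size (mm) or length-3 dimensions of the
#'   comparison protocol (default 1.6).
#' @return List `ratio` (exact) and `ratio_rounded`.
#' @export
voxel_volume_ratio <- function(voxel_a_mm = c(1.9, 1.9, 8), voxel_b_mm = 1.6) {
  if (length(voxel_b_mm) == 1) voxel_b_mm <- rep(voxel_b_mm, 3)
  r <- prod(voxel_a_mm) / prod(voxel_b_mm)
  list(ratio = r, ratio_rounded = round(r))
}
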