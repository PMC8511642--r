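#' @useDynLib cardiot2, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft prcomp density rnorm optimize uniroot coef lm sd
#'   median quantile
NULL

# Centered voxel/frequency indices for a grid of size m: -floor(m/2) .. ceil(m/2)-1
centered_index <- function(m) seq_len(m) - 1L - m %/% 2L

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Separable 3D Gaussian blur
#'
#' Convolves a volume with an isotropic Gaussian kernel (edge-replicated
#' boundaries), used for smoothing displacement fields and for constructing
#' controlled blur in map-sharpness analyses.
#'
#' @param vol 3D numeric array.
#' @param sigma_vox Gaussian standard deviation in voxels.
#' @return Blurred array of the same dimensions.
#' @export
gaussian_blur3 <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  rad <- max(1L, ceiling(3 * sigma_vox))
  u <- seq(-rad, rad)
  kern <- exp(-u^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  d <- dim(vol)
  blur_axis <- function(x, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- matrix(xp, nrow = dp[1])
    # replicate-pad and convolve columns
    padded <- rbind(m[rep(1L, rad), , drop = FALSE], m,
                    m[rep(dp[1], rad), , drop = FALSE])
    out <- matrix(0, nrow = dp[1], ncol = ncol(m))
    for (j in seq_along(kern)) {
      out <- out + kern[j] * padded[j:(j + dp[1] - 1L), , drop = FALSE]
    }
    aperm(array(out, dp), order(perm))
  }
  out <- vol
  for (ax in 1:3) out <- blur_axis(out, ax)
  out
}

# Trilinear sampling of a real volume at fractional 1-based voxel coordinates
# (n x 3 matrix); clamped at the boundary.
sample_trilinear <- function(vol, pts) {
  cpp_trilinear(as.numeric(vol), as.integer(dim(vol)), pts - 1)
}

# Root-mean-square of a numeric/complex array
rms <- function(x) sqrt(mean(Mod(x)^2))

# Normalized root-mean-square error against a reference
nrmse <- function(x, ref) rms(x - ref) / rms(ref)
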