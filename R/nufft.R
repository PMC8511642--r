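#' Plan a 3D non-uniform Fourier transform
#'
#' Precomputes the Kaiser-Bessel gridding ingredients (oversampled grid size,
#' kernel shape parameter, image-domain deapodization, embedding indices) for
#' a cubic image grid. The forward transform evaluates
#' \deqn{y_j = \sum_m x_m e^{-2\pi i k_j \cdot m / M}}
#' with voxel offsets \eqn{m} centered on the grid and non-Cartesian
#' frequencies \eqn{k_j} in cycles/FOV (grid units, \eqn{|k| \le M/2}).
#' The adjoint is the exact conjugate-transpose of the implemented forward
#' operator, so operator pairs used in iterative reconstruction satisfy the
#' adjoint identity to rounding error.
#'
#' @param matrix Cubic image grid size M.
#' @param oversampling Grid oversampling factor (default 2).
#' @param width Kernel width in oversampled grid cells (default 5).
#' @return A `nufft_plan` object.
#' @export
nufft_plan <- function(matrix, oversampling = 2, width = 5) {
  if (matrix < 2) stop_invalid("matrix size must be >= 2")
  if (oversampling < 1.25) stop_invalid("oversampling must be >= 1.25")
  M <- as.integer(matrix)
  Mo <- as.integer(2 * ceiling(oversampling * M / 2))
  J <- as.integer(width)
  os <- Mo / M
  beta <- pi * sqrt((J / os)^2 * (os - 0.5)^2 - 0.8)
  # Fourier transform of the (unnormalized) Kaiser-Bessel kernel of width J:
  # used for image-domain deapodization.
  kb_ft <- function(x) {
    arg <- beta^2 - (pi * J * x)^2
    out <- numeric(length(arg))
    pos <- arg > 0
    out[pos] <- J * sinh(sqrt(arg[pos])) / sqrt(arg[pos])
    neg <- arg < 0
    out[neg] <- J * sin(sqrt(-arg[neg])) / sqrt(-arg[neg])
    out[arg == 0] <- J
    out
  }
  cidx <- centered_index(M)
  d1 <- 1 / kb_ft(cidx / Mo)
  deapod <- outer(outer(d1, d1), d1)
  # kernel lookup table (linear interpolation in C++); one-time Bessel cost
  ut <- seq(0, J / 2, length.out = 4097)
  table <- besselI(beta * sqrt(pmax(1 - (2 * ut / J)^2, 0)), 0)
  # linear indices of the centered M^3 cube inside the FFT-ordered Mo^3 array
  p <- ((cidx %% Mo) + Mo) %% Mo
  embed <- as.vector(outer(outer(p + 1L, p * Mo, "+"), p * Mo * Mo, "+"))
  structure(list(M = M, Mo = Mo, width = J, beta = beta, table = table,
                 deapod = deapod, embed = embed, scale = Mo / M),
            class = "nufft_plan")
}

#' Forward non-uniform Fourier transform
#'
#' @param plan A [nufft_plan()].
#' @param image Complex (or numeric) array of dim `c(M, M, M)`.
#' @param k Sample frequencies, n x 3 matrix in cycles/FOV (grid units).
#' @return Complex vector of n k-space samples.
#' @export
nufft_forward <- function(plan, image, k) {
  stopifnot(inherits(plan, "nufft_plan"))
  if (!all(dim(image) == plan$M)) stop_invalid("image dimension mismatch")
  big <- complex(plan$Mo^3)
  big[plan$embed] <- as.complex(image * plan$deapod)
  dim(big) <- rep(plan$Mo, 3)
  F <- stats::fft(big)
  cpp_kb_interp(as.vector(F), k * plan$scale, plan$Mo, plan$width,
                plan$table)
}

#' Adjoint non-uniform Fourier transform
#'
#' Exact adjoint of [nufft_forward()].
#'
#' @inheritParams nufft_forward
#' @param y Complex vector of k-space samples (length `nrow(k)`).
#' @return Complex array of dim `c(M, M, M)`.
#' @export
nufft_adjoint <- function(plan, y, k) {
  stopifnot(inherits(plan, "nufft_plan"))
  g <- cpp_kb_spread(as.complex(y), k * plan$scale, plan$Mo, plan$width,
                     plan$table)
  dim(g) <- rep(plan$Mo, 3)
  G <- stats::fft(g, inverse = TRUE)
  x <- G[plan$embed] * plan$deapod
  array(x, dim = rep(plan$M, 3))
}
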