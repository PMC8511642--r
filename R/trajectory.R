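#' 3D radial spiral-phyllotaxis trajectory
#'
#' Places `n_interleaves * lines_per_interleave` readout directions on the
#' unit hemisphere by spiral phyllotaxis: for global index n in 1..N the
#' azimuth advances by the golden angle (137.508 deg) and the polar angle is
#' `(pi/2) * (n/N)^exponent` (default square-root profile, giving
#' quasi-uniform area coverage). Interleave i takes every
#' `n_interleaves`-th point starting at i, so each interleave spirals from
#' the pole toward the equator. Every interleave is preceded by a
#' superior-inferior (+z) navigator line used for self-navigation.
#'
#' @param n_interleaves Number of interleaves.
#' @param lines_per_interleave Readout lines per interleave (navigator not
#'   counted).
#' @param samples_per_line Samples per full spoke (odd recommended so one
#'   sample falls exactly on k = 0).
#' @param fov_mm Field of view (mm), isotropic.
#' @param matrix Image matrix size.
#' @param exponent Polar-angle profile exponent (default 0.5).
#' @return A `trajectory` object; `$lines` is a data frame with one row per
#'   line (`interleave`, `line_in_interleave` with 0 = navigator,
#'   `dir_x/y/z`, `is_navigator`).
#' @export
spiral_phyllotaxis <- function(n_interleaves = 112, lines_per_interleave = 49,
                               samples_per_line = 129, fov_mm = 220,
                               matrix = 137, exponent = 0.5) {
  if (n_interleaves < 1 || lines_per_interleave < 1 || samples_per_line < 2)
    stop_invalid("counts must be >= 1 (and samples_per_line >= 2)")
  if (fov_mm <= 0 || matrix < 2)
    stop_invalid("fov_mm must be positive and matrix >= 2")
  N <- n_interleaves * lines_per_interleave
  n <- seq_len(N)
  golden <- 137.50776405003785 * pi / 180
  phi <- n * golden
  theta <- (pi / 2) * (n / N)^exponent
  dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  rows <- vector("list", n_interleaves)
  for (i in seq_len(n_interleaves)) {
    idx <- which((n - 1L) %% n_interleaves == (i - 1L))  # pole -> equator
    rows[[i]] <- data.frame(
      interleave = i,
      line_in_interleave = c(0L, seq_len(lines_per_interleave)),
      dir_x = c(0, dirs[idx, 1]),
      dir_y = c(0, dirs[idx, 2]),
      dir_z = c(1, dirs[idx, 3]),
      is_navigator = c(TRUE, rep(FALSE, lines_per_interleave)))
  }
  lines <- do.call(rbind, rows)
  kmax_grid <- matrix / 2
  radii <- seq(-kmax_grid, kmax_grid, length.out = samples_per_line)
  structure(list(lines = lines,
                 n_interleaves = as.integer(n_interleaves),
                 lines_per_interleave = as.integer(lines_per_interleave),
                 samples_per_line = as.integer(samples_per_line),
                 fov_mm = fov_mm, matrix = as.integer(matrix),
                 radii = radii,
                 kmax_cycles_per_mm = kmax_grid / fov_mm,
                 exponent = exponent),
            class = "trajectory")
}

#' Sample positions of one trajectory line
#'
#' Full symmetric spokes from -kmax to +kmax; coordinates in cycles/FOV
#' (grid units, within \[-matrix/2, matrix/2\]).
#'
#' @param traj A [spiral_phyllotaxis()] trajectory.
#' @param line Row index into `traj$lines`.
#' @return `samples_per_line` x 3 matrix of k-space coordinates.
#' @export
line_sample_positions <- function(traj, line) {
  stopifnot(inherits(traj, "trajectory"))
  if (line < 1 || line > nrow(traj$lines)) stop_invalid("line out of range")
  d <- unlist(traj$lines[line, c("dir_x", "dir_y", "dir_z")])
  outer(traj$radii, d)
}

# Sample positions for a set of lines, stacked: (S * nlines) x 3. Sample s of
# line j occupies row (j-1)*S + s.
all_sample_positions <- function(traj, line_rows = seq_len(nrow(traj$lines))) {
  d <- as.matrix(traj$lines[line_rows, c("dir_x", "dir_y", "dir_z")])
  S <- traj$samples_per_line
  # kron: for each line, radii outer direction
  kx <- outer(traj$radii, d[, 1])
  ky <- outer(traj$radii, d[, 2])
  kz <- outer(traj$radii, d[, 3])
  cbind(as.vector(kx), as.vector(ky), as.vector(kz))
}
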