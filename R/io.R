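# Raw-data container ---------------------------------------------------------
# Single-file binary container for k-space datasets with ISMRMRD-compatible
# field naming (data, traj/*, head/*). Tagged sections (name, type, dims,
# payload) written with writeBin; round-trips are bit-exact.

RAW_MAGIC <- "CARDIOT2RAW"
RAW_SCHEMA_VERSION <- 1L

write_section <- function(con, name, value) {
  type <- if (is.complex(value)) 3L else if (is.double(value)) 1L
          else if (is.integer(value)) 2L else if (is.logical(value)) 5L
          else if (is.character(value)) 4L else
            stop_invalid("unsupported section type for '%s'", name)
  nm <- charToRaw(name)
  writeBin(length(nm), con, size = 4)
  writeBin(nm, con)
  writeBin(type, con, size = 4)
  d <- if (is.null(dim(value))) length(value) else dim(value)
  writeBin(length(d), con, size = 4)
  writeBin(as.integer(d), con, size = 4)
  if (type == 4L) {
    raw <- charToRaw(paste(value, collapse = "\n"))
    writeBin(length(raw), con, size = 4)
    writeBin(raw, con)
  } else if (type == 5L) {
    writeBin(as.integer(value), con, size = 4)
  } else {
    writeBin(as.vector(value), con)
  }
}

read_section <- function(con) {
  nlen <- readBin(con, "integer", 1, size = 4)
  if (length(nlen) == 0) return(NULL)
  name <- rawToChar(readBin(con, "raw", nlen))
  type <- readBin(con, "integer", 1, size = 4)
  nd <- readBin(con, "integer", 1, size = 4)
  d <- readBin(con, "integer", nd, size = 4)
  n <- prod(d)
  value <- switch(as.character(type),
    "1" = readBin(con, "double", n),
    "2" = readBin(con, "integer", n),
    "3" = readBin(con, "complex", n),
    "4" = {
      rl <- readBin(con, "integer", 1, size = 4)
      strsplit(rawToChar(readBin(con, "raw", rl)), "\n", fixed = TRUE)[[1]]
    },
    "5" = as.logical(readBin(con, "integer", n, size = 4)),
    stop_invalid("unknown section type %d", type))
  if (nd > 1) dim(value) <- d
  list(name = name, value = value)
}

#' Write a k-space dataset to the raw container
#'
#' Stores the complex sample data, the trajectory (unit directions, radial
#' sample positions, navigator flags), and the per-line headers (prep index,
#' interleave, timestamp, navigator flag) in a tagged single-file binary
#' container with ISMRMRD-compatible field naming. `read_raw(write_raw(d))`
#' is bit-exact.
#'
#' @param dataset A `kspace_data` object.
#' @param path Output file path.
#' @export
write_raw <- function(dataset, path) {
  stopifnot(inherits(dataset, "kspace_data"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(RAW_MAGIC), con)
  writeBin(RAW_SCHEMA_VERSION, con, size = 4)
  t <- dataset$traj
  write_section(con, "data", dataset$data)
  write_section(con, "traj/directions",
                as.matrix(t$lines[, c("dir_x", "dir_y", "dir_z")]))
  write_section(con, "traj/radii", t$radii)
  write_section(con, "traj/interleave", as.integer(t$lines$interleave))
  write_section(con, "traj/line_in_interleave",
                as.integer(t$lines$line_in_interleave))
  write_section(con, "traj/is_navigator", t$lines$is_navigator)
  write_section(con, "traj/meta",
                c(t$n_interleaves, t$lines_per_interleave,
                  t$samples_per_line, t$matrix))
  write_section(con, "traj/fov_mm", t$fov_mm)
  write_section(con, "traj/exponent", t$exponent)
  h <- dataset$headers
  write_section(con, "head/prep_index", as.integer(h$prep_index))
  write_section(con, "head/interleave", as.integer(h$interleave))
  write_section(con, "head/line_in_interleave",
                as.integer(h$line_in_interleave))
  write_section(con, "head/is_navigator", h$is_navigator)
  write_section(con, "head/timestamp_ms", as.double(h$timestamp_ms))
  write_section(con, "prep_durations_ms", as.double(dataset$prep_durations_ms))
  write_section(con, "seed", as.integer(dataset$seed))
  invisible(path)
}

#' Read a k-space dataset from the raw container
#'
#' @param path File written by [write_raw()].
#' @return A `kspace_data` object.
#' @export
read_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(RAW_MAGIC)))
  if (!identical(magic, RAW_MAGIC))
    stop_invalid("not a raw k-space container (bad magic)")
  ver <- readBin(con, "integer", 1, size = 4)
  if (!identical(ver, RAW_SCHEMA_VERSION))
    stop_invalid("schema version mismatch: file %d, supported %d",
                 ver, RAW_SCHEMA_VERSION)
  sec <- list()
  repeat {
    s <- read_section(con)
    if (is.null(s)) break
    sec[[s$name]] <- s$value
  }
  needed <- c("data", "traj/directions", "traj/radii", "traj/meta",
              "traj/fov_mm", "head/prep_index")
  missing_ <- setdiff(needed, names(sec))
  if (length(missing_) > 0)
    stop_invalid("schema error: missing section(s) %s",
                 paste(missing_, collapse = ", "))
  meta <- sec[["traj/meta"]]
  lines <- data.frame(interleave = sec[["traj/interleave"]],
                      line_in_interleave = sec[["traj/line_in_interleave"]],
                      dir_x = sec[["traj/directions"]][, 1],
                      dir_y = sec[["traj/directions"]][, 2],
                      dir_z = sec[["traj/directions"]][, 3],
                      is_navigator = sec[["traj/is_navigator"]])
  traj <- structure(list(lines = lines,
                         n_interleaves = meta[1], lines_per_interleave = meta[2],
                         samples_per_line = meta[3], matrix = meta[4],
                         fov_mm = sec[["traj/fov_mm"]],
                         radii = sec[["traj/radii"]],
                         kmax_cycles_per_mm = (meta[4] / 2) / sec[["traj/fov_mm"]],
                         exponent = sec[["traj/exponent"]]),
                    class = "trajectory")
  data <- sec[["data"]]
  headers <- data.frame(interleave = sec[["head/interleave"]],
                        line_in_interleave = sec[["head/line_in_interleave"]],
                        dir_x = NA_real_, dir_y = NA_real_, dir_z = NA_real_,
                        is_navigator = sec[["head/is_navigator"]],
                        prep_index = sec[["head/prep_index"]],
                        timestamp_ms = sec[["head/timestamp_ms"]])
  traj_rows <- ((seq_len(nrow(headers)) - 1L) %% nrow(lines)) + 1L
  headers$dir_x <- lines$dir_x[traj_rows]
  headers$dir_y <- lines$dir_y[traj_rows]
  headers$dir_z <- lines$dir_z[traj_rows]
  if (nrow(headers) != dim(data)[2])
    stop_invalid("header line count (%d) does not match data line count (%d)",
                 nrow(headers), dim(data)[2])
  structure(list(data = data, headers = headers, traj = traj,
                 matrix = traj$matrix, fov_mm = traj$fov_mm,
                 samples_per_line = traj$samples_per_line,
                 n_coils = dim(data)[3],
                 prep_durations_ms = sec[["prep_durations_ms"]],
                 seed = sec[["seed"]],
                 schema_version = ver),
            class = "kspace_data")
}

# NIfTI output ---------------------------------------------------------------

#' Write a volume (or 4D bin stack) as NIfTI-1
#'
#' Complex input is written as magnitude (float32); voxel size is recorded
#' in the header (mm, RAS-aligned axes, z = superior-inferior).
#'
#' @param vol 3D or 4D array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_mm Isotropic voxel size (mm).
#' @export
write_volume_nifti <- function(vol, path, voxel_mm = 1) {
  if (is.complex(vol)) vol <- Mod(vol)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxel_mm, min(3, length(dim(vol))))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a deformation field as a NIfTI-1 vector volume
#'
#' @param field A `deformation_field`.
#' @param path Output path.
#' @param dim Grid dimensions (needed for translation-type fields).
#' @export
write_deformation_nifti <- function(field, path, dim = NULL) {
  stopifnot(inherits(field, "deformation_field"))
  disp <- if (field$type == "nonrigid") field$disp else {
    if (is.null(dim)) stop_invalid("grid dim required for translation fields")
    sh <- if (field$type == "translation") field$shift_vox else c(0, 0, 0)
    array(rep(sh, each = prod(dim)), dim = c(dim, 3))
  }
  write_volume_nifti(disp * field$voxel_mm, path, field$voxel_mm)
}

# Configuration --------------------------------------------------------------

#' Default pipeline run configuration
#'
#' All knobs of the end-to-end phantom pipeline in one (YAML-serializable)
#' list: phantom geometry scale, sequence parameters, binning, reconstruction
#' and registration settings, and the single seed from which all randomness
#' flows.
#'
#' @param matrix Grid size (default 48).
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
default_run_config <- function(matrix = 48, seed = 42L) {
  structure(list(
    seed = as.integer(seed),
    matrix = as.integer(matrix),
    fov_mm = 220,
    with_lesion = TRUE,
    samples_per_line = matrix + 1L,
    n_interleaves = 112L,
    n_coils = 4L,
    noise_sd = 3e-5,
    respiration = list(amplitude_mm = 10, period_s = 4,
                       waveform = "asymmetric", ap_fraction = 0.3),
    heart_rate_bpm = 67,
    n_bins = 4L,
    lambda_weight = 0.05,
    n_iterations = 15L,
    control_spacing_mm = 12,
    model = "three_param",
    log_level = "info"), class = c("run_config", "list"))
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base$seed <- as.integer(base$seed)
  base$matrix <- as.integer(base$matrix)
  base
}

#' @rdname read_config
#' @param config A `run_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
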