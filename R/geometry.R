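#' Acquisition geometry for a multi-echo gradient-echo (MGRE) protocol
#'
#' Bundles the grid, voxel size, static-field parameters and echo-time table
#' that every stage of the simulation and reconstruction needs. Defaults match
#' a 7T MGRE protocol with ten echoes (TE1 = 1.68 ms, dTE = 3.05 ms) at 0.8 mm
#' isotropic resolution.
#'
#' @param grid_shape integer vector of length 3, voxels per axis.
#' @param voxel_size numeric vector of length 3 (or scalar), mm per axis.
#' @param b0_strength static field strength in tesla.
#' @param b0_direction unit 3-vector of the main-field axis (normalised here).
#' @param gyromagnetic_ratio reduced gyromagnetic ratio, MHz/T.
#' @param echo_times strictly increasing echo times in ms.
#'
#' @return An object of class `acquisition_geometry`.
#' @examples
#' g <- acquisition_geometry(grid_shape = c(64, 64, 64))
#' g$echo_times
#' @export
acquisition_geometry <- function(grid_shape = c(96L, 96L, 96L),
                                 voxel_size = c(0.8, 0.8, 0.8),
                                 b0_strength = 7,
                                 b0_direction = c(0, 0, 1),
                                 gyromagnetic_ratio = 42.576,
                                 echo_times = default_echo_times()) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("grid_shape must be 3 positive integers")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive values (mm)")
  if (b0_strength <= 0) stop("b0_strength must be positive")
  nb <- sqrt(sum(b0_direction^2))
  if (nb == 0) stop("b0_direction must be a nonzero vector")
  b0_direction <- b0_direction / nb
  if (length(echo_times) < 1L || any(diff(echo_times) <= 0))
    stop("echo_times must be strictly increasing")
  structure(
    list(grid_shape = grid_shape,
         voxel_size = as.numeric(voxel_size),
         b0_strength = b0_strength,
         b0_direction = as.numeric(b0_direction),
         gyromagnetic_ratio = gyromagnetic_ratio,
         echo_times = as.numeric(echo_times)),
    class = "acquisition_geometry")
}

#' Default echo-time table (ms): TE1 = 1.68, dTE = 3.05, 10 echoes
#' @return numeric vector of 10 echo times in ms.
#' @export
default_echo_times <- function() 1.68 + (0:9) * 3.05

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("MGRE acquisition geometry\n")
  cat(sprintf("  grid: %s voxels at %s mm\n",
              paste(x$grid_shape, collapse = " x "),
              paste(format(x$voxel_size), collapse = " x ")))
  cat(sprintf("  B0: %g T along (%s), gamma-bar = %g MHz/T\n",
              x$b0_strength, paste(format(x$b0_direction, digits = 3), collapse = ", "),
              x$gyromagnetic_ratio))
  cat(sprintf("  echoes: %d (TE %.2f..%.2f ms)\n", length(x$echo_times),
              min(x$echo_times), max(x$echo_times)))
  invisible(x)
}

# Hz of field shift per ppm of susceptibility at this B0
hz_per_ppm <- function(geometry) geometry$gyromagnetic_ratio * geometry$b0_strength
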