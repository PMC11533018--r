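#' Write a simulated MGRE dataset to NIfTI-1 with a JSON sidecar
#'
#' Writes the 4-D magnitude and phase volumes, the 3-D truth maps (chi,
#' r2star, m0), the integer label volume and the brain mask, plus a JSON
#' sidecar with the echo times (ms), field strength and direction, voxel
#' size and seed.
#'
#' @param series an `echo_series`.
#' @param truth a `phantom_truth` (optional; truth maps are skipped if NULL).
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_mgre_dataset <- function(series, truth = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- series$geometry
  wr <- function(x, name) {
    path <- file.path(dir, paste0(name, ".nii.gz"))
    img <- RNifti::asNifti(x, reference = NULL)
    img <- RNifti::`pixdim<-`(img, c(g$voxel_size, 1)[seq_len(length(dim(x)))])
    RNifti::writeNifti(img, path)
    path
  }
  files <- c(wr(series$magnitude, "magnitude"), wr(series$phase, "phase"))
  if (!is.null(truth)) {
    files <- c(files,
               wr(truth$chi, "truth_chi"), wr(truth$r2star, "truth_r2star"),
               wr(truth$m0, "truth_m0"), wr(truth$labels + 0, "labels"),
               wr(truth$brain_mask + 0, "brain_mask"))
    utils::write.csv(truth$label_table, file.path(dir, "label_table.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(dir, "label_table.csv"))
  }
  sidecar <- list(echo_times_ms = g$echo_times, b0_strength = g$b0_strength,
                  b0_direction = g$b0_direction, voxel_size_mm = g$voxel_size,
                  grid_shape = g$grid_shape,
                  gyromagnetic_ratio = g$gyromagnetic_ratio,
                  seed = if (!is.null(truth)) truth$seed else NA)
  sc_path <- file.path(dir, "mgre.json")
  jsonlite::write_json(sidecar, sc_path, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sc_path))
}

#' Read an MGRE dataset written by [write_mgre_dataset()]
#'
#' @param dir directory containing magnitude.nii.gz, phase.nii.gz, mgre.json.
#' @return list with `series` (an `echo_series`) and, when present, `truth`
#'   fields (chi, r2star, m0, labels, brain_mask, label_table).
#' @export
read_mgre_dataset <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "mgre.json"), simplifyVector = TRUE)
  g <- acquisition_geometry(grid_shape = sc$grid_shape,
                            voxel_size = sc$voxel_size_mm,
                            b0_strength = sc$b0_strength,
                            b0_direction = sc$b0_direction,
                            gyromagnetic_ratio = sc$gyromagnetic_ratio,
                            echo_times = sc$echo_times_ms)
  rd <- function(name) {
    path <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(path)) return(NULL)
    x <- as.array(RNifti::readNifti(path))
    attributes(x) <- list(dim = dim(x))
    x
  }
  series <- structure(list(magnitude = rd("magnitude"), phase = rd("phase"),
                           geometry = g), class = "echo_series")
  out <- list(series = series)
  out$chi <- rd("truth_chi"); out$r2star <- rd("truth_r2star")
  out$m0 <- rd("truth_m0")
  lab <- rd("labels")
  if (!is.null(lab)) out$labels <- array(as.integer(round(lab)), dim = dim(lab))
  bm <- rd("brain_mask")
  if (!is.null(bm)) out$brain_mask <- bm > 0.5
  lt <- file.path(dir, "label_table.csv")
  if (file.exists(lt))
    out$label_table <- utils::read.csv(lt, stringsAsFactors = FALSE)
  out
}

#' Write a 3-D map as NIfTI-1
#' @param x 3-D array.
#' @param path output file path (.nii or .nii.gz).
#' @param voxel_size mm per axis.
#' @return invisibly, `path`.
#' @export
write_map_nifti <- function(x, path, voxel_size = c(0.8, 0.8, 0.8)) {
  img <- RNifti::asNifti(x)
  img <- RNifti::`pixdim<-`(img, voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}
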