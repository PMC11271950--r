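#' Read and write volumes as NIfTI
#'
#' Real 3D volumes map to one 3D NIfTI; complex volumes are stored as a 4D
#' NIfTI with real and imaginary parts stacked on the 4th axis; 4D coil
#' stacks of complex maps interleave (Re, Im) per coil. Voxel size is stored
#' in the header.
#'
#' @param volume 3D (real or complex) or 4D complex array.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param voxel_mm voxel size triple (mm).
#' @export
write_volume_nifti <- function(volume, path, voxel_mm = c(1, 1, 1)) {
  d <- dim(volume)
  if (is.complex(volume)) {
    if (length(d) == 3) {
      arr <- array(0, dim = c(d, 2))
      arr[, , , 1] <- Re(volume); arr[, , , 2] <- Im(volume)
    } else {
      arr <- array(0, dim = c(d[1:3], 2 * d[4]))
      for (c_i in seq_len(d[4])) {
        arr[, , , 2 * c_i - 1] <- Re(volume[, , , c_i])
        arr[, , , 2 * c_i] <- Im(volume[, , , c_i])
      }
    }
  } else arr <- volume
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- if (nd == 3) voxel_mm else c(voxel_mm, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param complex_data logical; reassemble complex data written by
#'   [write_volume_nifti()].
#' @return the array, with attribute `voxel_mm`.
#' @export
read_volume_nifti <- function(path, complex_data = FALSE) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  if (complex_data) {
    d <- dim(arr)
    nc <- d[4] / 2
    if (nc == 1) {
      out <- complex(real = arr[, , , 1], imaginary = arr[, , , 2])
      dim(out) <- d[1:3]
    } else {
      out <- array(0 + 0i, dim = c(d[1:3], nc))
      for (c_i in seq_len(nc))
        out[, , , c_i] <- complex(real = arr[, , , 2 * c_i - 1],
                                  imaginary = arr[, , , 2 * c_i])
    }
    arr <- out
  }
  attr(arr, "voxel_mm") <- vox
  arr
}

#' Read and write experiment configuration as YAML
#'
#' @param config nested list (see [default_experiment_config()]).
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) yaml::read_yaml(path)

#' Write a JSON report
#'
#' @param x list to serialize.
#' @param path file path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
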