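#' Read a grayscale image
#'
#' PNG and TIFF (8- or 16-bit) images are read losslessly and mapped to
#' integer levels `[0, levels - 1]`; 16-bit input is either processed at
#' `levels = 65536` or linearly requantized to 256 levels. A NIfTI volume
#' (requires the RNifti package) must be read with `slice` set; the axial
#' slice is linearly rescaled to `[0, levels - 1]`.
#'
#' @param path input file (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param levels number of gray levels for the returned image.
#' @param to_gray average the channels of an RGB input (otherwise RGB input
#'   is an error).
#' @param slice axial slice index for NIfTI input.
#' @return Numeric matrix with integer values in `[0, levels - 1]`.
#' @export
read_image <- function(path, levels = 256L, to_gray = FALSE, slice = NULL) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop_input("reading NIfTI requires the RNifti package")
    vol <- RNifti::asNifti(RNifti::readNifti(path))
    if (is.null(slice)) stop_input("NIfTI input requires a slice index")
    if (length(dim(vol)) < 3L) stop_input("NIfTI input must be a 3-D volume")
    if (slice < 1L || slice > dim(vol)[3L])
      stop_input(sprintf("slice index out of range 1..%d", dim(vol)[3L]))
    sl <- vol[, , slice]
    rng <- range(sl)
    if (diff(rng) == 0) return(matrix(0, nrow(sl), ncol(sl)))
    return(round_half_up((sl - rng[1]) / diff(rng) * (levels - 1)))
  }
  raw <- if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    tiff::readTIFF(path)
  } else {
    stop_input(sprintf("unsupported image format: %s", path))
  }
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3L] >= 3L && to_gray) {
      raw <- (raw[, , 1L] + raw[, , 2L] + raw[, , 3L]) / 3
    } else if (dim(raw)[3L] == 2L) {            # gray + alpha
      raw <- raw[, , 1L]
    } else {
      stop_input("RGB input; pass to_gray = TRUE to average the channels")
    }
  }
  round_half_up(raw * (levels - 1))
}

#' Write a grayscale image or a binary mask as PNG
#'
#' Masks are written with 0/255 coding. Round-trips through [read_image()]
#' are lossless for 8-bit data.
#'
#' @param img numeric matrix in `[0, levels - 1]` (or 0/1 for `write_mask`).
#' @param path output `.png` path; the parent directory must exist.
#' @param levels number of gray levels of `img`.
#' @export
write_image <- function(img, path, levels = 256L) {
  if (!dir.exists(dirname(path)))
    stop_input(sprintf("directory does not exist: %s", dirname(path)))
  png::writePNG(clamp(img, 0, levels - 1) / (levels - 1), path)
  invisible(path)
}

#' @rdname write_image
#' @param mask binary 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  check_binary_mask(mask)
  write_image(mask * 255, path)
}

#' Load a pipeline configuration from a flat YAML file
#'
#' Unknown keys are rejected; every value is range-checked by
#' [pipeline_config()] with the offending key named.
#'
#' @param path YAML file of `key: value` pairs matching the arguments of
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop_validation(sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  do.call(pipeline_config, vals)
}
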