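#' Image volume container
#'
#' A 3-D scalar intensity grid with voxel-spacing metadata. Axial slices are
#' indexed along the third array dimension; in-plane pixel spacing is given in
#' millimetres as (row, column) spacing, and slice thickness in millimetres.
#'
#' @param data numeric 3-D array `[rows, cols, slices]`.
#' @param pixel_spacing_mm positive length-2 numeric, in-plane spacing in mm.
#' @param slice_thickness_mm positive scalar, slice thickness in mm.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, pixel_spacing_mm = c(1, 1),
                         slice_thickness_mm = 3) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L)
  pixel_spacing_mm <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  if (any(pixel_spacing_mm <= 0) || slice_thickness_mm <= 0)
    stop("pixel spacing and slice thickness must be strictly positive")
  structure(
    list(data = data,
         pixel_spacing_mm = pixel_spacing_mm,
         slice_thickness_mm = as.numeric(slice_thickness_mm)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, %.3g x %.3g mm pixels, %.3g mm slices\n",
    d[1], d[2], d[3], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
    x$slice_thickness_mm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

# Volume of one voxel in cubic millimetres.
voxel_volume_mm3 <- function(vol) {
  prod(vol$pixel_spacing_mm) * vol$slice_thickness_mm
}

#' Restrict a volume or label map to a set of slices
#'
#' @param x an `image_volume` or `label_map`.
#' @param slices integer vector of slice indices (1-based, third dimension).
#' @return object of the same class containing only the requested slices.
#' @export
crop_slices <- function(x, slices) {
  stopifnot(all(slices >= 1), all(slices <= dim(x$data)[3]))
  x$data <- x$data[, , slices, drop = FALSE]
  x
}

#' Label map codes for the thigh segmentation taxonomy
#'
#' Integer codes: 0 background, 1 subcutaneous fat, 2 fascia-interior space
#' (between muscles / beneath fascia), 3 femur (cortical bone + marrow), and
#' 10..22 the thirteen thigh muscle compartments (rectus femoris, vastus
#' lateralis, vastus intermedius, vastus medialis, sartorius, adductor longus,
#' gracilis, adductor brevis, adductor magnus, semimembranosus,
#' semitendinosus, biceps femoris long head, biceps femoris short head).
#'
#' @return named integer vector mapping label names to codes.
#' @export
label_codes <- function() {
  c(background = 0L, subcutaneous_fat = 1L, fascia_interior = 2L, femur = 3L,
    rectus_femoris = 10L, vastus_lateralis = 11L, vastus_intermedius = 12L,
    vastus_medialis = 13L, sartorius = 14L, adductor_longus = 15L,
    gracilis = 16L, adductor_brevis = 17L, adductor_magnus = 18L,
    semimembranosus = 19L, semitendinosus = 20L,
    biceps_femoris_long = 21L, biceps_femoris_short = 22L)
}

muscle_codes <- function() unname(label_codes()[5:17])

#' Label map container
#'
#' Integer-coded anatomical segmentation on the same grid as an
#' [image_volume()]. See [label_codes()] for the code table.
#'
#' @param data integer 3-D array of label codes.
#' @param pixel_spacing_mm,slice_thickness_mm voxel geometry in mm.
#' @param codes named integer vector code table (default [label_codes()]).
#' @return an object of class `label_map`.
#' @export
label_map <- function(data, pixel_spacing_mm = c(1, 1),
                      slice_thickness_mm = 3, codes = label_codes()) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  storage.mode(data) <- "integer"
  structure(
    list(data = data,
         pixel_spacing_mm = rep_len(as.numeric(pixel_spacing_mm), 2L),
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         codes = codes),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_map> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  tab <- table(x$data)
  nm <- names(x$codes)[match(as.integer(names(tab)), x$codes)]
  nm[is.na(nm)] <- "?"
  cat(paste0("  ", nm, " (", names(tab), "): ", as.integer(tab),
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$data)

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti carrying the voxel geometry into and out of the
#' NIfTI header. `write_label_map()` additionally writes a JSON sidecar with
#' the label code table.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol an `image_volume`.
#' @return `read_image_volume()` returns an `image_volume`;
#'   `read_label_map()` a `label_map`; the writers return `path` invisibly.
#' @export
read_image_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  image_volume(unclass(img)[, , , drop = FALSE],
               pixel_spacing_mm = pd[1:2], slice_thickness_mm = pd[3])
}

#' @rdname read_image_volume
#' @export
write_image_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$pixel_spacing_mm, vol$slice_thickness_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_image_volume
#' @param labels a `label_map`.
#' @export
write_label_map <- function(labels, path) {
  img <- RNifti::asNifti(labels$data)
  RNifti::pixdim(img) <- c(labels$pixel_spacing_mm, labels$slice_thickness_mm)
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(as.list(labels$codes),
                       sub("\\.nii(\\.gz)?$", "_codes.json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname read_image_volume
#' @export
read_label_map <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  codes_path <- sub("\\.nii(\\.gz)?$", "_codes.json", path)
  codes <- label_codes()
  if (file.exists(codes_path)) {
    lst <- jsonlite::read_json(codes_path)
    codes <- stats::setNames(as.integer(unlist(lst)), names(lst))
  }
  label_map(unclass(img)[, , , drop = FALSE],
            pixel_spacing_mm = pd[1:2], slice_thickness_mm = pd[3],
            codes = codes)
}
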