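#' Derive intraMAT / interMAT / fascia region masks from a label map
#'
#' Combines the muscle, bone, and fascia segmentation into the binary region
#' masks used for fat quantification:
#' \describe{
#'   \item{intramat_roi}{union of the muscle compartments — intramuscular fat
#'     is counted here.}
#'   \item{intermat_roi}{the fascia-interior space between muscles and
#'     beneath the fascia (label code 2) — intermuscular fat is counted
#'     here.}
#'   \item{femur}{cortical bone + marrow, excluded from both ROIs so bright
#'     marrow fat never counts as interMAT.}
#'   \item{fascia_interior}{everything enclosed by the muscular fascia
#'     (the union of the above); used as the normalizing volume.}
#' }
#' Subcutaneous fat and background (outside the fascia) are excluded from
#' every ROI. The derivation is deterministic and uses only label codes,
#' never image intensities.
#'
#' @param labels a [label_map()] containing a fascia-interior region (code 2)
#'   and at least one muscle compartment (codes 10..22).
#' @return an object of class `region_masks`: logical arrays
#'   `fascia_interior`, `intramat_roi`, `intermat_roi`, `femur` on the label
#'   grid, plus the voxel geometry.
#' @export
derive_regions <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$data
  intramat <- lab >= 10L & lab <= 22L
  intermat <- lab == 2L
  femur <- lab == 3L
  if (!any(intramat | intermat | femur))
    stop("label map has no fascia-interior region")
  if (!any(intramat))
    stop("label map has no muscle compartments (codes 10..22)")

  # When the map carries an explicit fascia-interior marker (code 2), muscles
  # must lie inside the fascia: no muscle voxel may touch background or
  # subcutaneous fat in-plane. (Maps whose muscles tile the whole interior
  # carry no marker and are accepted as-is.)
  if (any(intermat)) {
    outside <- lab == 0L | lab == 1L
    d <- dim(lab)
    touches <- array(FALSE, d)
    sh <- function(a, di, dj) {
      out <- array(FALSE, d)
      ri <- max(1, 1 + di):min(d[1], d[1] + di)
      rj <- max(1, 1 + dj):min(d[2], d[2] + dj)
      out[ri, rj, ] <- a[ri - di, rj - dj, , drop = FALSE]
      out
    }
    for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      touches <- touches | sh(outside, s[1], s[2])
    bad <- intramat & touches
    if (any(bad)) {
      codes <- sort(unique(lab[bad]))
      stop("muscle voxels outside the fascia interior (codes: ",
           paste(codes, collapse = ", "), ")")
    }
  }

  structure(list(fascia_interior = intramat | intermat | femur,
                 intramat_roi = intramat,
                 intermat_roi = intermat,
                 femur = femur,
                 pixel_spacing_mm = labels$pixel_spacing_mm,
                 slice_thickness_mm = labels$slice_thickness_mm),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat("<region_masks>\n")
  for (nm in c("fascia_interior", "intramat_roi", "intermat_roi", "femur"))
    cat(sprintf("  %-16s %d voxels\n", nm, sum(x[[nm]])))
  invisible(x)
}

#' Write region masks as NIfTI volumes
#'
#' @param masks a `region_masks` object.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return invisibly, the written paths.
#' @export
write_region_masks <- function(masks, dir, prefix = "roi") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("fascia_interior", "intramat_roi", "intermat_roi", "femur")) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    arr <- array(as.integer(masks[[nm]]), dim(masks[[nm]]))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(masks$pixel_spacing_mm, masks$slice_thickness_mm)
    RNifti::writeNifti(img, p, datatype = "uint8")
    paths <- c(paths, p)
  }
  invisible(paths)
}
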