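#' Specification of a synthetic thigh phantom
#'
#' Describes the geometry, tissue intensities, fat burden, and corruption
#' model of a synthetic axial T1-weighted thigh volume. The default geometry
#' mirrors a typical mid-thigh acquisition: a 512 x 512 in-plane grid at
#' 1 x 1 mm pixels, 24 contiguous 3 mm slices, and a circular thigh
#' cross-section whose fascia encloses a femur and `n_muscles` wedge-shaped
#' muscle compartments separated by thin inter-compartment seams.
#'
#' Fat is placed in two ground-truth pools: intramuscular fat (intraMAT) as
#' small speckle clusters inside the muscle compartments, and intermuscular
#' fat (interMAT) as clusters along the seams between compartments and in the
#' thin layer beneath the fascia. `intramat_fraction` is the fraction of
#' muscle-compartment voxels converted to fat; `intermat_fraction` the
#' fraction of the seam/subfascial space filled with fat.
#'
#' The rendered image is corrupted by a smooth multiplicative in-plane bias
#' field (2nd-degree polynomial scaled to `1 +/- bias_amplitude`) followed by
#' Rician noise of scale `noise_sigma` (the magnitude-MRI noise model: the
#' modulus of the signal plus complex Gaussian noise).
#'
#' @param grid_shape integer triple (slices, rows, cols).
#' @param pixel_spacing_mm in-plane pixel spacing (mm), length 1 or 2.
#' @param slice_thickness_mm slice thickness (mm).
#' @param fascia_radius_mm radius of the muscular fascia (mm).
#' @param femur_radius_mm outer radius of the femur (mm).
#' @param n_muscles number of muscle compartments (default 13, the standard
#'   thigh taxonomy).
#' @param intramat_fraction target fat fraction inside muscle compartments,
#'   in `[0, 0.9]`.
#' @param intermat_fraction target fat fill of the seam/subfascial space,
#'   in `[0, 1)`.
#' @param intensity_model named numeric vector of noise-free tissue
#'   intensities (arbitrary T1-like units; fat must exceed muscle).
#' @param bias_amplitude peak fractional deviation of the bias field
#'   (0 disables it).
#' @param noise_sigma Rician noise scale in intensity units (0 disables it).
#' @param seed integer RNG seed; identical spec + seed gives a bit-identical
#'   phantom.
#' @param subcut_thickness_mm thickness of the subcutaneous fat ring (mm).
#' @param cortical_thickness_mm thickness of the dark cortical bone shell;
#'   the femur interior renders as bright marrow.
#' @param seam_halfwidth_px half-width of inter-compartment seams (pixels).
#' @param subfascial_ring_mm thickness of the beneath-fascia interMAT layer.
#' @param speckle_radius_px integer range of intraMAT speckle radii (pixels).
#' @param femur_offset_mm in-plane offset of the femur centre from the thigh
#'   axis (anatomically the femur is not centred).
#' @param profile `"full"` for the 512 x 512 acquisition-scale geometry or
#'   `"test"` for a reduced 128 x 128 grid with a proportionally smaller
#'   thigh, intended for fast validation runs.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(grid_shape = NULL,
                         pixel_spacing_mm = c(1, 1),
                         slice_thickness_mm = 3,
                         fascia_radius_mm = NULL,
                         femur_radius_mm = NULL,
                         n_muscles = 13L,
                         intramat_fraction = 0.03,
                         intermat_fraction = 0.30,
                         intensity_model = c(fat = 200, muscle = 90,
                                             cortical_bone = 30, marrow = 190,
                                             background = 10),
                         bias_amplitude = 0.2,
                         noise_sigma = 5,
                         seed = 1L,
                         subcut_thickness_mm = NULL,
                         cortical_thickness_mm = 3,
                         seam_halfwidth_px = 1,
                         subfascial_ring_mm = 2,
                         speckle_radius_px = c(1L, 3L),
                         femur_offset_mm = NULL,
                         profile = c("full", "test")) {
  profile <- match.arg(profile)
  if (is.null(grid_shape))
    grid_shape <- if (profile == "full") c(24L, 512L, 512L) else c(24L, 128L, 128L)
  if (is.null(fascia_radius_mm))
    fascia_radius_mm <- if (profile == "full") 80 else 40
  if (is.null(femur_radius_mm))
    femur_radius_mm <- if (profile == "full") 15 else 10
  if (is.null(subcut_thickness_mm))
    subcut_thickness_mm <- if (profile == "full") 15 else 8
  if (is.null(femur_offset_mm)) femur_offset_mm <- fascia_radius_mm / 4

  spec <- structure(
    list(grid_shape = as.integer(grid_shape),
         pixel_spacing_mm = rep_len(as.numeric(pixel_spacing_mm), 2L),
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         fascia_radius_mm = fascia_radius_mm,
         femur_radius_mm = femur_radius_mm,
         n_muscles = as.integer(n_muscles),
         intramat_fraction = intramat_fraction,
         intermat_fraction = intermat_fraction,
         intensity_model = intensity_model,
         bias_amplitude = bias_amplitude,
         noise_sigma = noise_sigma,
         seed = as.integer(seed),
         subcut_thickness_mm = subcut_thickness_mm,
         cortical_thickness_mm = cortical_thickness_mm,
         seam_halfwidth_px = seam_halfwidth_px,
         subfascial_ring_mm = subfascial_ring_mm,
         speckle_radius_px = as.integer(speckle_radius_px),
         femur_offset_mm = femur_offset_mm),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  gs <- spec$grid_shape
  if (length(gs) != 3L || any(gs < 4L))
    stop("grid_shape must be an integer triple (slices, rows, cols) >= 4")
  if (any(spec$pixel_spacing_mm <= 0) || spec$slice_thickness_mm <= 0)
    stop("voxel geometry must be strictly positive")
  if (spec$femur_radius_mm >= spec$fascia_radius_mm)
    stop("invalid phantom spec: femur_radius_mm must be smaller than fascia_radius_mm")
  if (spec$femur_offset_mm + spec$femur_radius_mm >= spec$fascia_radius_mm)
    stop("invalid phantom spec: femur (with offset) must lie inside the fascia")
  half_extent <- min(gs[2] * spec$pixel_spacing_mm[1],
                     gs[3] * spec$pixel_spacing_mm[2]) / 2
  if (spec$fascia_radius_mm + spec$subcut_thickness_mm >= half_extent)
    stop("invalid phantom spec: thigh cross-section does not fit inside the grid")
  if (spec$intramat_fraction < 0 || spec$intramat_fraction > 0.9)
    stop("intramat_fraction must lie in [0, 0.9]")
  if (spec$intermat_fraction < 0 || spec$intermat_fraction >= 1)
    stop("intermat_fraction must lie in [0, 1)")
  if (spec$bias_amplitude < 0 || spec$noise_sigma < 0)
    stop("bias_amplitude and noise_sigma must be nonnegative")
  if (spec$intensity_model[["fat"]] <= spec$intensity_model[["muscle"]])
    stop("intensity model must render fat brighter than muscle (T1 contrast)")
  if (spec$n_muscles < 1L) stop("need at least one muscle compartment")
  invisible(spec)
}

# Deterministic (given the RNG state) single-slice anatomy: label matrix plus
# the polar geometry needed for rendering. Consumes RNG draws for the
# compartment wedge widths, so call inside with_seed().
build_template <- function(spec) {
  nr <- spec$grid_shape[2]; nc <- spec$grid_shape[3]
  dx <- spec$pixel_spacing_mm[1]; dy <- spec$pixel_spacing_mm[2]
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  x <- (seq_len(nr) - cx) * dx
  y <- (seq_len(nc) - cy) * dy
  X <- matrix(x, nr, nc); Y <- matrix(y, nr, nc, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  r_fem <- sqrt((X - spec$femur_offset_mm)^2 + Y^2)
  theta <- atan2(Y, X) %% (2 * pi)

  # seeded angular partition into n_muscles wedges
  w <- stats::runif(spec$n_muscles, 0.5, 1.5)
  widths <- 2 * pi * w / sum(w)
  start <- stats::runif(1, 0, 2 * pi)
  breaks <- (start + cumsum(c(0, widths[-spec$n_muscles]))) %% (2 * pi)

  mcodes <- muscle_codes()[seq_len(spec$n_muscles)]
  ang_dist <- matrix(Inf, nr, nc)
  for (i in seq_along(breaks)) {
    d <- abs(theta - breaks[i])
    d <- pmin(d, 2 * pi - d)
    ang_dist <- pmin(ang_dist, d)
  }
  # wedge membership: angles below the smallest sorted break wrap to the
  # wedge that starts at the largest break
  ord <- order(breaks)
  idx <- findInterval(theta, c(0, breaks[ord]))
  lookup <- mcodes[ord][c(spec$n_muscles, seq_len(spec$n_muscles))]
  wedge_code <- lookup[idx]

  px_mm <- sqrt(dx * dy)
  lab <- matrix(label_codes()[["background"]], nr, nc)
  interior <- r < spec$fascia_radius_mm
  lab[interior] <- wedge_code[interior]
  # seams between compartments and the beneath-fascia layer -> code 2
  seam <- interior & (ang_dist * (r / px_mm) <= spec$seam_halfwidth_px |
                        r >= spec$fascia_radius_mm - spec$subfascial_ring_mm)
  lab[seam] <- label_codes()[["fascia_interior"]]
  lab[interior & r_fem <= spec$femur_radius_mm] <- label_codes()[["femur"]]
  subcut <- !interior & r < spec$fascia_radius_mm + spec$subcut_thickness_mm
  lab[subcut] <- label_codes()[["subcutaneous_fat"]]

  list(lab = lab, r = r, r_fem = r_fem)
}

# Seeded speckle placement: grow random small in-plane disc clusters inside
# `domain` (a logical 3-D array) until `target` voxels are fat.
place_speckles <- function(domain, target, radii) {
  dims <- dim(domain)
  fat <- array(FALSE, dims)
  if (target <= 0) return(fat)
  pool <- which(domain)
  if (target > 0.95 * length(pool))
    stop("requested fat volume exceeds the capacity of its compartment")
  offs <- lapply(min(radii):max(radii), function(rr) {
    g <- expand.grid(dr = -rr:rr, dc = -rr:rr)
    g[g$dr^2 + g$dc^2 <= rr^2, , drop = FALSE]
  })
  placed <- 0L
  guard <- 0L
  nrs <- dims[1]; ncs <- dims[2]
  while (placed < target) {
    guard <- guard + 1L
    if (guard > 200L * target) stop("speckle placement failed to converge")
    ctr <- pool[sample.int(length(pool), 1L)]
    ijk <- arrayInd(ctr, dims)
    o <- offs[[sample.int(length(offs), 1L)]]
    ii <- ijk[1] + o$dr; jj <- ijk[2] + o$dc
    ok <- ii >= 1L & ii <= nrs & jj >= 1L & jj <= ncs
    lin <- ii[ok] + (jj[ok] - 1L) * nrs + (ijk[3] - 1L) * nrs * ncs
    lin <- lin[domain[lin] & !fat[lin]]
    if (!length(lin)) next
    need <- target - placed
    if (length(lin) > need) lin <- lin[seq_len(need)]
    fat[lin] <- TRUE
    placed <- placed + length(lin)
  }
  fat
}

#' Generate a synthetic thigh phantom
#'
#' Builds the volume in four stages: (1) noise-free tissue-intensity
#' rendering of the labelled anatomy, (2) seeded fat placement (intraMAT
#' speckles inside muscle compartments; interMAT clusters along
#' inter-compartment seams and beneath the fascia), (3) multiplication by a
#' smooth polynomial bias field, (4) Rician corruption. The exact ground-truth
#' fat masks and their volumes (voxel count x voxel volume, in cm^3) are
#' returned alongside the image and label map.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom`: a list with elements `image`
#'   (`image_volume`), `labels` (`label_map`), logical truth masks
#'   `truth_intramat_mask` / `truth_intermat_mask`, truth volumes
#'   `truth_intramat_cm3`, `truth_intermat_cm3`, `truth_fascia_cm3`, and the
#'   generating `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(profile = "test", seed = 7))
#' ph$truth_intramat_cm3
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  nsl <- spec$grid_shape[1]
  with_seed(spec$seed, {
    tpl <- build_template(spec)
    dims <- c(dim(tpl$lab), nsl)
    lab3 <- array(tpl$lab, dims)

    is_muscle <- lab3 >= 10L
    is_seam <- lab3 == label_codes()[["fascia_interior"]]
    n_intra <- round(spec$intramat_fraction * sum(is_muscle))
    n_inter <- round(spec$intermat_fraction * sum(is_seam))
    intr <- place_speckles(is_muscle, n_intra, spec$speckle_radius_px)
    inter <- place_speckles(is_seam, n_inter,
                            pmin(spec$speckle_radius_px, 2L))

    im <- spec$intensity_model
    base <- matrix(im[["background"]], dims[1], dims[2])
    base[tpl$lab == 1L] <- im[["fat"]]
    base[tpl$lab == 2L] <- im[["muscle"]]  # connective/other soft tissue
    base[tpl$lab >= 10L] <- im[["muscle"]]
    fem <- tpl$lab == 3L
    base[fem] <- ifelse(tpl$r_fem[fem] > spec$femur_radius_mm -
                          spec$cortical_thickness_mm,
                        im[["cortical_bone"]], im[["marrow"]])
    img <- array(base, dims)
    img[intr | inter] <- im[["fat"]]

    if (spec$bias_amplitude > 0) {
      xn <- seq(-1, 1, length.out = dims[1])
      yn <- seq(-1, 1, length.out = dims[2])
      Xn <- matrix(xn, dims[1], dims[2]); Yn <- matrix(yn, dims[1], dims[2], byrow = TRUE)
      a <- stats::runif(5, -1, 1)
      f <- a[1] * Xn + a[2] * Yn + a[3] * Xn^2 + a[4] * Xn * Yn + a[5] * Yn^2
      rng <- range(f)
      field <- 1 - spec$bias_amplitude +
        2 * spec$bias_amplitude * (f - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
      img <- img * array(field, dims)
    }
    if (spec$noise_sigma > 0) {
      n <- length(img)
      img <- sqrt((img + stats::rnorm(n, 0, spec$noise_sigma))^2 +
                    stats::rnorm(n, 0, spec$noise_sigma)^2)
      dim(img) <- dims
    }

    vv <- prod(spec$pixel_spacing_mm) * spec$slice_thickness_mm / 1000 # cm^3
    fascia_interior <- lab3 == 2L | lab3 == 3L | lab3 >= 10L
    structure(
      list(image = image_volume(img, spec$pixel_spacing_mm,
                                spec$slice_thickness_mm),
           labels = label_map(lab3, spec$pixel_spacing_mm,
                              spec$slice_thickness_mm),
           truth_intramat_mask = intr,
           truth_intermat_mask = inter,
           truth_intramat_cm3 = sum(intr) * vv,
           truth_intermat_cm3 = sum(inter) * vv,
           truth_fascia_cm3 = sum(fascia_interior) * vv,
           spec = spec),
      class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$image$data)
  cat(sprintf("<phantom> %d x %d x %d voxels (seed %d)\n",
              d[1], d[2], d[3], x$spec$seed))
  cat(sprintf("  truth: intraMAT %.2f cm^3, interMAT %.2f cm^3, fascia %.1f cm^3\n",
              x$truth_intramat_cm3, x$truth_intermat_cm3, x$truth_fascia_cm3))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes the image and label map as NIfTI-1 and a JSON truth sidecar holding
#' the three ground-truth volumes and the full generating spec (seed
#' included), so a phantom on disk is fully reproducible.
#'
#' @param phantom a `phantom`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(prefix, "_image.nii.gz"))
  p_lab <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  p_json <- file.path(dir, paste0(prefix, "_truth.json"))
  write_image_volume(phantom$image, p_img)
  write_label_map(phantom$labels, p_lab)
  spec <- phantom$spec
  spec$intensity_model <- as.list(spec$intensity_model)
  jsonlite::write_json(
    list(truth_intramat_cm3 = phantom$truth_intramat_cm3,
         truth_intermat_cm3 = phantom$truth_intermat_cm3,
         truth_fascia_cm3 = phantom$truth_fascia_cm3,
         spec = unclass(spec)),
    p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(image = p_img, labels = p_lab, truth = p_json))
}
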