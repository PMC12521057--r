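# Synthetic CT phantoms with known noise ground truth: an elliptical
# soft-tissue body on an air background, optional anatomy-surrogate inserts
# replicated on every slice, and zero-mean Gaussian noise that is white
# (sharp-kernel surrogate) or spatially correlated by an isotropic Gaussian
# filter (smooth-kernel surrogate).

#' Specify a synthetic CT phantom
#'
#' @param shape Integer (slices, rows, cols). The default, 20 slices of
#'   512 x 512, matches a clinical abdominal acquisition.
#' @param pixel_spacing_mm In-plane spacing (mm); 0.7 gives a 358 mm FOV.
#' @param slice_thickness_mm Slice thickness (mm); 3 is the CMS reference.
#' @param body_axes_mm Full axes (width, height) of the elliptical body in
#'   mm.
#' @param body_center_mm Body centre offset (x, y) from the image centre.
#' @param tissue_hu Body HU; must sit inside the soft-tissue threshold
#'   window.
#' @param air_hu Background HU; must sit inside the air threshold window.
#' @param sigma_hu Target per-pixel noise SD (HU) in the final image.
#' @param kernel_fwhm_mm Gaussian correlation length of the noise: 0 is
#'   white noise (sharp reconstruction kernel surrogate), > 0 correlates
#'   the noise (smooth kernel surrogate).
#' @param rescale_noise Rescale the (possibly filtered) noise field so its
#'   marginal SD equals `sigma_hu` (default). Turning this off keeps the
#'   pre-filter white-noise amplitude at `sigma_hu`, which is how a smooth
#'   kernel lowers the realised noise relative to a sharp one.
#' @param inserts List of anatomy surrogates replicated on all slices; each
#'   is a list with `shape` ("disc" or "rect"), `hu`, `center_mm` (x, y
#'   offset from image centre) and `size_mm` (disc radius, or rect
#'   c(width, height)).
#' @param seed Integer seed making the phantom reproducible.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(20, 512, 512), pixel_spacing_mm = 0.7,
                         slice_thickness_mm = 3,
                         body_axes_mm = c(300, 200), body_center_mm = c(0, 0),
                         tissue_hu = 50, air_hu = -1000,
                         sigma_hu = 10, kernel_fwhm_mm = 0,
                         rescale_noise = TRUE, inserts = list(),
                         seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= c(2, 8, 8)),
            pixel_spacing_mm > 0, slice_thickness_mm > 0,
            length(body_axes_mm) == 2, all(body_axes_mm > 0),
            sigma_hu >= 0, kernel_fwhm_mm >= 0)
  fov <- rev(shape[2:3]) * pixel_spacing_mm  # (x, y) extent
  if (any(abs(body_center_mm) + body_axes_mm / 2 > fov / 2)) {
    stop("body ellipse exceeds the field of view", call. = FALSE)
  }
  structure(list(shape = as.integer(shape),
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 body_axes_mm = body_axes_mm, body_center_mm = body_center_mm,
                 tissue_hu = tissue_hu, air_hu = air_hu,
                 sigma_hu = sigma_hu, kernel_fwhm_mm = kernel_fwhm_mm,
                 rescale_noise = isTRUE(rescale_noise),
                 inserts = inserts, seed = as.integer(seed)),
            class = "phantom_spec")
}

# pixel-centre coordinates (mm) relative to the image centre
phantom_coords <- function(nr, nc, spacing) {
  list(x = (seq_len(nc) - (nc + 1) / 2) * spacing,
       y = (seq_len(nr) - (nr + 1) / 2) * spacing)
}

# noiseless structure image shared by all slices
phantom_structure <- function(spec) {
  nr <- spec$shape[2]; nc <- spec$shape[3]
  co <- phantom_coords(nr, nc, spec$pixel_spacing_mm)
  xs <- matrix(co$x, nr, nc, byrow = TRUE) - spec$body_center_mm[1]
  ys <- matrix(co$y, nr, nc) - spec$body_center_mm[2]
  img <- matrix(spec$air_hu, nr, nc)
  a <- spec$body_axes_mm[1] / 2; b <- spec$body_axes_mm[2] / 2
  img[(xs / a)^2 + (ys / b)^2 <= 1] <- spec$tissue_hu
  for (ins in spec$inserts) {
    dx <- matrix(co$x, nr, nc, byrow = TRUE) - ins$center_mm[1]
    dy <- matrix(co$y, nr, nc) - ins$center_mm[2]
    inside <- switch(ins$shape,
      disc = dx^2 + dy^2 <= ins$size_mm^2,
      rect = abs(dx) <= ins$size_mm[1] / 2 & abs(dy) <= ins$size_mm[2] / 2,
      stop("unknown insert shape '", ins$shape, "'", call. = FALSE))
    img[inside] <- ins$hu
  }
  img
}

# circularly wrapped FFT convolution kernel for isotropic Gaussian smoothing
gaussian_kernel_image <- function(nr, nc, fwhm_mm, spacing) {
  sigma_px <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
  half <- max(1L, ceiling(3 * sigma_px))
  g <- exp(-0.5 * ((-half:half) / sigma_px)^2)
  k2 <- outer(g, g)
  k2 <- k2 / sum(k2)
  if (2 * half + 1 > min(nr, nc)) stop("smoothing kernel exceeds the slice")
  kimg <- matrix(0, nr, nc)
  idx_r <- ((-half:half) %% nr) + 1
  idx_c <- ((-half:half) %% nc) + 1
  kimg[idx_r, idx_c] <- k2
  kimg
}

#' Generate a synthetic CT phantom volume
#'
#' Builds the noiseless structure (elliptical body plus inserts on an air
#' background), adds zero-mean Gaussian noise drawn independently per
#' slice, optionally correlates it with an isotropic Gaussian filter, and
#' quantises the result to the 0.1 HU DICOM storage grid so the volume
#' survives a write/load round trip bit-exactly.
#'
#' @param spec A [phantom_spec()].
#' @param exam_id,series_id Identifiers for the resulting volume.
#' @return A list: `volume` (a [ct_volume()]) and `ground_truth` with the
#'   target `sigma_hu`, the noiseless-compartment `tissue_mask` and
#'   `air_mask`, the structure image, and the seed.
#' @examples
#' p <- make_phantom(phantom_spec(shape = c(2, 32, 32), sigma_hu = 0))
#' range(p$volume$slices)
#' @export
make_phantom <- function(spec, exam_id = "phantom-1", series_id = "series-1") {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape[2]; nc <- spec$shape[3]
  structure_img <- phantom_structure(spec)
  set.seed(spec$seed)
  vol <- array(0, spec$shape)
  kimg <- NULL
  scale <- 1
  if (spec$kernel_fwhm_mm > 0) {
    kimg <- gaussian_kernel_image(nr, nc, spec$kernel_fwhm_mm,
                                  spec$pixel_spacing_mm)
    if (spec$rescale_noise) scale <- 1 / sqrt(sum(kimg^2))
    kf <- fft(kimg)
  }
  for (i in seq_len(spec$shape[1])) {
    noise <- matrix(rnorm(nr * nc), nr, nc)
    if (!is.null(kimg)) {
      noise <- Re(fft(fft(noise) * kf, inverse = TRUE)) / (nr * nc)
    }
    vol[i, , ] <- structure_img + spec$sigma_hu * scale * noise
  }
  # snap to the DICOM storage grid (slope 0.1 HU, intercept -1024)
  vol <- round((vol + 1024) / 0.1) * 0.1 - 1024
  volume <- ct_volume(vol, spec$pixel_spacing_mm, spec$slice_thickness_mm,
                      slice_positions_mm = seq_len(spec$shape[1]) * spec$slice_thickness_mm,
                      series_id = series_id, exam_id = exam_id)
  list(volume = volume,
       ground_truth = list(
         sigma_hu = spec$sigma_hu,
         tissue_mask = structure_img >= 0 & structure_img <= 100,
         air_mask = structure_img >= -1024 & structure_img <= -950,
         structure_hu = structure_img,
         seed = spec$seed))
}

#' Generate a synthetic exam cohort
#'
#' Draws a per-exam noise level from a stated distribution and builds one
#' phantom exam per draw, optionally writing each as a DICOM series.
#'
#' @param spec_template A [phantom_spec()] whose `sigma_hu` is replaced per
#'   exam.
#' @param n_exams Number of exams, >= 1.
#' @param sigma_distribution A list: `list(type = "constant", value = s)`
#'   or `list(type = "lognormal", median = m, gsd = g)` (geometric SD).
#' @param seed Cohort seed; per-exam phantom seeds derive from it.
#' @param dir Optional output directory; when given, each exam is written
#'   as a DICOM series under `dir/<exam_id>/` along with
#'   `ground_truth.csv` and a `manifest.json`, and volumes are not kept in
#'   memory.
#' @return A list: `ground_truth` tibble (`exam_id`, `sigma_hu`, `seed`,
#'   and `path` when written) and `volumes` (list of [ct_volume()], absent
#'   when `dir` is given).
#' @export
make_cohort <- function(spec_template, n_exams,
                        sigma_distribution = list(type = "constant", value = 10),
                        seed = 1L, dir = NULL) {
  stopifnot(inherits(spec_template, "phantom_spec"))
  if (n_exams < 1) stop("`n_exams` must be >= 1", call. = FALSE)
  set.seed(seed)
  sigmas <- switch(sigma_distribution$type,
    constant = rep(sigma_distribution$value, n_exams),
    lognormal = {
      if (sigma_distribution$median <= 0 || sigma_distribution$gsd <= 1) {
        stop("lognormal needs median > 0 and gsd > 1", call. = FALSE)
      }
      rlnorm(n_exams, meanlog = log(sigma_distribution$median),
             sdlog = log(sigma_distribution$gsd))
    },
    stop("unknown sigma_distribution type '", sigma_distribution$type, "'",
         call. = FALSE))
  exam_ids <- sprintf("exam-%03d", seq_len(n_exams))
  exam_seeds <- (as.numeric(seed) * 10007 + seq_len(n_exams)) %% .Machine$integer.max
  gt <- tibble::tibble(exam_id = exam_ids, sigma_hu = sigmas,
                       seed = as.integer(exam_seeds))
  volumes <- list()
  paths <- character(n_exams)
  for (i in seq_len(n_exams)) {
    sp <- spec_template
    sp$sigma_hu <- sigmas[i]
    sp$seed <- as.integer(exam_seeds[i])
    ph <- make_phantom(sp, exam_id = exam_ids[i])
    if (is.null(dir)) {
      volumes[[exam_ids[i]]] <- ph$volume
    } else {
      paths[i] <- file.path(dir, exam_ids[i])
      write_ct_series(ph$volume, paths[i])
    }
  }
  if (!is.null(dir)) {
    gt$path <- exam_ids  # relative to `dir`, keeping outputs location-independent
    write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n_exams = n_exams, seed = seed,
           sigma_distribution = sigma_distribution,
           exams = gt),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    return(list(ground_truth = gt))
  }
  list(ground_truth = gt, volumes = volumes)
}
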