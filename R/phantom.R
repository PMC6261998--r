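## Synthetic embryo phantom: a sphere (yolk + blastoderm) whose
## histone-labelled nuclei sit in a shell-shaped cap around the animal pole.
## Positions are in micrometres in the lab frame; the sphere centre defaults
## to the origin, which render_view() places at the centre of the volume.

#' Construct an embryo phantom
#'
#' Low-level constructor with validation. Most users will call
#' [make_phantom()] instead.
#'
#' @param sphere_center numeric 3-vector, micrometres.
#' @param sphere_radius sphere radius in micrometres.
#' @param nuclei data.frame with columns `x`, `y`, `z` (centre, micrometres),
#'   `radius` (micrometres) and `intensity` (peak intensity, arbitrary
#'   units). May have zero rows.
#' @param cap_axis unit 3-vector pointing from the sphere centre toward the
#'   animal pole (the animal-vegetal axis).
#' @param cap_half_angle angular half-extent of the nucleus-bearing cap, in
#'   degrees, in `(0, 180]`.
#' @param seed integer seed recorded for provenance.
#' @return An object of class `embryo_phantom`.
#' @export
embryo_phantom <- function(sphere_center, sphere_radius, nuclei, cap_axis,
                           cap_half_angle, seed = NA_integer_) {
  check_positive_scalar(sphere_radius, "sphere_radius")
  if (!is.numeric(sphere_center) || length(sphere_center) != 3L) {
    stop_invalid_parameter("`sphere_center` must be a numeric 3-vector")
  }
  if (!is_scalar_number(cap_half_angle) || cap_half_angle <= 0 || cap_half_angle > 180) {
    stop_invalid_parameter("`cap_half_angle` must be in (0, 180] degrees")
  }
  if (!is.numeric(cap_axis) || length(cap_axis) != 3L || sum(cap_axis^2) == 0) {
    stop_invalid_parameter("`cap_axis` must be a non-zero numeric 3-vector")
  }
  cap_axis <- cap_axis / sqrt(sum(cap_axis^2))
  need <- c("x", "y", "z", "radius", "intensity")
  if (!is.data.frame(nuclei) || !all(need %in% names(nuclei))) {
    stop_invalid_parameter("`nuclei` must be a data.frame with columns x, y, z, radius, intensity")
  }
  nuclei <- nuclei[, need, drop = FALSE]
  if (nrow(nuclei) > 0) {
    if (any(nuclei$radius <= 0) || any(nuclei$intensity <= 0)) {
      stop_invalid_parameter("nucleus radii and intensities must be > 0")
    }
    rel <- sweep(as.matrix(nuclei[, c("x", "y", "z")]), 2, sphere_center)
    r <- sqrt(rowSums(rel^2))
    if (any(r > sphere_radius * (1 + 1e-9))) {
      stop_invalid_parameter("all nucleus centres must lie inside the sphere")
    }
    cosang <- as.vector(rel %*% cap_axis) / pmax(r, .Machine$double.eps)
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    if (any(ang > cap_half_angle + 1e-6 & r > 1e-9)) {
      stop_invalid_parameter("all nucleus centres must lie within the cap half-angle")
    }
  }
  structure(
    list(sphere_center = as.numeric(sphere_center),
         sphere_radius = sphere_radius,
         nuclei = nuclei,
         cap_axis = cap_axis,
         cap_half_angle = cap_half_angle,
         seed = seed),
    class = "embryo_phantom")
}

#' @export
print.embryo_phantom <- function(x, ...) {
  cat(sprintf(
    "embryo_phantom: radius %.0f um, %d nuclei in a %.0f deg cap about (%.2f, %.2f, %.2f)\n",
    x$sphere_radius, nrow(x$nuclei), x$cap_half_angle,
    x$cap_axis[1], x$cap_axis[2], x$cap_axis[3]))
  invisible(x)
}

#' Generate a synthetic embryo phantom
#'
#' Draws nuclei uniformly over a spherical-shell cap: directions uniform on
#' the spherical cap of half-angle `cap_half_angle` about `cap_axis`, radii
#' uniform (by volume) in the blastoderm shell
#' `[sphere_radius - shell_thickness, sphere_radius - nucleus radius]`.
#' This emulates a histone-labelled early zebrafish embryo: a sphere whose
#' nuclei occupy a cellular cap at the animal pole while the vegetal yolk is
#' unlabelled. The defaults describe a scaled-down embryo (100 um radius,
#' large early blastomeres) whose geometry ratios match a ~50%-epiboly embryo
#' but which fits a 128 x 128 px field at 2 um pixels with the nuclei
#' Nyquist-resolved - the regime in which the local-entropy quality statistic
#' is meaningful.
#'
#' The same parameters and seed always produce the same phantom.
#'
#' @param sphere_radius embryo radius in micrometres.
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param cap_half_angle cap half-angle in degrees, `(0, 180]`.
#' @param seed integer seed for reproducibility.
#' @param shell_thickness blastoderm thickness in micrometres.
#' @param nucleus_radius mean nucleus radius, micrometres.
#' @param nucleus_radius_sd SD of nucleus radii (truncated at 20% of mean).
#' @param intensity_mean,intensity_sd peak nucleus intensity distribution
#'   (truncated normal, arbitrary units).
#' @param cap_axis animal-vegetal axis; defaults to the tube (vertical, +y)
#'   axis, the orientation in which an embryo hangs in the sample tube.
#' @param sphere_center sphere centre, micrometres.
#' @return An [embryo_phantom()] object.
#' @export
#' @examples
#' ph <- make_phantom(seed = 1)
#' ph
make_phantom <- function(sphere_radius = 100, n_nuclei = 150,
                         cap_half_angle = 90, seed = 1L,
                         shell_thickness = 30,
                         nucleus_radius = 10, nucleus_radius_sd = 1.5,
                         intensity_mean = 1000, intensity_sd = 150,
                         cap_axis = c(0, 1, 0),
                         sphere_center = c(0, 0, 0)) {
  check_positive_scalar(sphere_radius, "sphere_radius")
  if (!is_scalar_number(n_nuclei) || n_nuclei < 0 || n_nuclei != round(n_nuclei)) {
    stop_invalid_parameter("`n_nuclei` must be a non-negative integer")
  }
  if (!is_scalar_number(cap_half_angle) || cap_half_angle <= 0 || cap_half_angle > 180) {
    stop_invalid_parameter("`cap_half_angle` must be in (0, 180] degrees")
  }
  n <- as.integer(n_nuclei)
  nuclei <- with_seed(seed, {
    if (n == 0L) {
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                 radius = numeric(0), intensity = numeric(0))
    } else {
      rad <- pmax(nucleus_radius * 0.2,
                  rnorm(n, nucleus_radius, nucleus_radius_sd))
      ## direction: uniform over the cap about +z, then rotated to cap_axis
      cmin <- cos(cap_half_angle * pi / 180)
      u <- runif(n, cmin, 1)        # cos(polar angle), uniform on the cap area
      phi <- runif(n, 0, 2 * pi)
      s <- sqrt(pmax(0, 1 - u^2))
      dirs <- cbind(s * cos(phi), s * sin(phi), u)
      R <- rotation_between(c(0, 0, 1), cap_axis)
      dirs <- dirs %*% t(R)
      ## radial position: volume-uniform within the shell, nucleus fully inside
      r_out <- sphere_radius - rad
      r_in <- pmin(pmax(sphere_radius - shell_thickness, 0), r_out)
      r <- (r_in^3 + runif(n) * (r_out^3 - r_in^3))^(1 / 3)
      pos <- dirs * r
      inten <- pmax(intensity_mean * 0.1,
                    rnorm(n, intensity_mean, intensity_sd))
      data.frame(x = pos[, 1] + sphere_center[1],
                 y = pos[, 2] + sphere_center[2],
                 z = pos[, 3] + sphere_center[3],
                 radius = rad, intensity = inten)
    }
  })
  embryo_phantom(sphere_center, sphere_radius, nuclei, cap_axis,
                 cap_half_angle, seed = as.integer(seed))
}

#' Rotate a phantom about its sphere centre
#'
#' Applies a proper rotation to every nucleus position and to the
#' animal-vegetal axis, modelling (noiselessly) the magnetic reorientation of
#' the embryo inside the sample tube.
#'
#' @param phantom an [embryo_phantom()].
#' @param rotation 3x3 proper rotation matrix.
#' @return The rotated phantom.
#' @export
rotate_phantom <- function(phantom, rotation) {
  stopifnot(inherits(phantom, "embryo_phantom"))
  check_rotation(rotation)
  ph <- phantom
  if (nrow(ph$nuclei) > 0) {
    rel <- sweep(as.matrix(ph$nuclei[, c("x", "y", "z")]), 2, ph$sphere_center)
    rot <- rel %*% t(rotation)
    ph$nuclei$x <- rot[, 1] + ph$sphere_center[1]
    ph$nuclei$y <- rot[, 2] + ph$sphere_center[2]
    ph$nuclei$z <- rot[, 3] + ph$sphere_center[3]
  }
  ph$cap_axis <- as.vector(rotation %*% ph$cap_axis)
  ph
}

#' SPIM optics / degradation model
#'
#' Parameterizes the two depth-dependent degradations of light-sheet imaging
#' that the quality statistic is designed to detect: Beer-Lambert attenuation
#' of the illumination sheet along its path through tissue, and detection
#' blur growing linearly with the tissue path toward the detection objective.
#' Camera background is Gaussian with the given mean and SD (clipped at 0;
#' keep `background_mean >= 5 * background_sd` so clipping is negligible).
#'
#' @param attenuation_length 1/e decay length of illumination intensity per
#'   micrometre of tissue; `Inf` disables attenuation.
#' @param blur_sigma0 detection PSF sigma at zero tissue depth, micrometres.
#' @param blur_growth added PSF sigma per micrometre of detection-path
#'   tissue (dimensionless).
#' @param axial_ratio ratio of axial (detection-axis) to lateral PSF width;
#'   the whole detection-path degradation is `axial_ratio` times wider along
#'   z than in-plane, the usual light-sheet anisotropy that multi-view
#'   fusion is designed to compensate.
#' @param surface_aberration scale (micrometres) of the extra detection blur
#'   caused by refraction where the detection ray exits the curved sample
#'   surface: added sigma = `surface_aberration * (1/cos(theta) - 1)` with
#'   `theta` the exit incidence angle (clamped at ~84 degrees). Grazing exits
#'   near the sphere's tangent - the situation of an on-axis pole viewed from
#'   the side, which no tube rotation can change - are strongly aberrated;
#'   normal-incidence exits (pole facing the detector) are unaffected.
#' @param background_mean,background_sd camera background, intensity units.
#' @param dual_sided_illumination if `TRUE` the sheet enters alternately from
#'   both x sides and each point sees the lesser of the two tissue paths.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(attenuation_length = 150, blur_sigma0 = 2,
                         blur_growth = 0.08, surface_aberration = 8,
                         axial_ratio = 1, background_mean = 100,
                         background_sd = 2,
                         dual_sided_illumination = TRUE) {
  check_positive_scalar(attenuation_length, "attenuation_length", allow_inf = TRUE)
  if (!is_scalar_number(blur_sigma0) || blur_sigma0 < 0) {
    stop_invalid_parameter("`blur_sigma0` must be >= 0")
  }
  if (!is_scalar_number(blur_growth) || blur_growth < 0) {
    stop_invalid_parameter("`blur_growth` must be >= 0")
  }
  if (!is_scalar_number(surface_aberration) || surface_aberration < 0) {
    stop_invalid_parameter("`surface_aberration` must be >= 0")
  }
  if (!is_scalar_number(axial_ratio) || axial_ratio < 1) {
    stop_invalid_parameter("`axial_ratio` must be >= 1")
  }
  if (!is_scalar_number(background_sd) || background_sd < 0) {
    stop_invalid_parameter("`background_sd` must be >= 0")
  }
  structure(
    list(attenuation_length = attenuation_length,
         blur_sigma0 = blur_sigma0, blur_growth = blur_growth,
         surface_aberration = surface_aberration, axial_ratio = axial_ratio,
         background_mean = background_mean, background_sd = background_sd,
         dual_sided_illumination = isTRUE(dual_sided_illumination)),
    class = "optics_model")
}

#' Image stack container
#'
#' A 3D non-negative intensity volume indexed `[z, y, x]` with physical
#' spacings. Plane `z = 1` is the plane nearest the detection objective;
#' depth increases with z.
#'
#' @param voxels numeric 3D array, `dim = c(nz, ny, nx)`, finite and >= 0.
#' @param pixel_size in-plane pixel size, micrometres.
#' @param plane_spacing spacing between z planes, micrometres.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size, plane_spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || any(dim(voxels) < 1L)) {
    stop_invalid_input("`voxels` must be a 3D array with positive dimensions")
  }
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    stop_invalid_input("stack intensities must be finite and non-negative")
  }
  check_positive_scalar(pixel_size, "pixel_size")
  check_positive_scalar(plane_spacing, "plane_spacing")
  structure(list(voxels = voxels, pixel_size = pixel_size,
                 plane_spacing = plane_spacing, z_direction = "toward-detection"),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d planes of %dx%d px (%.3g um px, %.3g um planes)\n",
              d[1], d[2], d[3], x$pixel_size, x$plane_spacing))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

## Tissue path lengths through the embryo sphere for a set of interior points
## (rows of `p`, lab-frame um).  `axis_index` 1 = x (illumination),
## 3 = z (detection); `toward` -1 means toward the negative-axis surface.
## For the ray from p toward -e_k, the in-tissue path is
## (p_k - c_k) + sqrt(R^2 - rho^2) with rho the distance from the axis line.
tissue_path <- function(p, center, radius, axis_index, toward = -1) {
  rel <- sweep(p, 2, center)
  rho2 <- rowSums(rel[, -axis_index, drop = FALSE]^2)
  half <- sqrt(pmax(radius^2 - rho2, 0))
  len <- -toward * rel[, axis_index] + half
  out <- pmax(len, 0)
  out[rho2 > radius^2] <- 0   # outside the cylinder shadow: no tissue crossed
  out
}

illumination_path <- function(p, center, radius, dual_sided) {
  l_minus <- tissue_path(p, center, radius, 1L, toward = -1)
  if (!dual_sided) return(l_minus)
  l_plus <- tissue_path(p, center, radius, 1L, toward = +1)
  pmin(l_minus, l_plus)
}

detection_path <- function(p, center, radius) {
  tissue_path(p, center, radius, 3L, toward = -1)
}

## Cosine of the incidence angle at which the detection ray (along -z) exits
## the sphere surface; 1 for a normal (pole-facing) exit, -> 0 near-tangent.
## Points outside the sphere's z shadow exit no surface: cos = 1.
detection_exit_cos <- function(p, center, radius) {
  rel <- sweep(p, 2, center)
  rho2 <- rel[, 1]^2 + rel[, 2]^2
  ct <- sqrt(pmax(radius^2 - rho2, 0)) / radius
  ct[rho2 >= radius^2] <- 1
  ct
}

#' Render a SPIM view of a phantom
#'
#' Forward image-formation model. Each nucleus contributes a separable
#' Gaussian blob centred at its position:
#' * the in-plane (x, y) sigma is
#'   `sigma_xy = sqrt((radius/2)^2 + (blur_sigma0 + blur_growth * l_det)^2)`,
#'   where `l_det` is the tissue path toward the detection objective (-z);
#'   the axial (z) sigma stays at the zero-depth reference
#'   `sigma_ref = sqrt((radius/2)^2 + blur_sigma0^2)` (the light sheet, not
#'   the detection path, sets axial resolution);
#' * the peak value is
#'   `intensity * exp(-l_illum / attenuation_length) * (sigma_ref/sigma_xy)^2`,
#'   where `l_illum` is the tissue chord from the nearer illumination side
#'   (x axis; minimum of the two sides under dual-sided illumination).
#'   The `(sigma_ref/sigma_xy)^2` factor makes lateral blur energy-conserving:
#'   a deep nucleus is rendered wider and dimmer, with its total energy
#'   depending only on the illumination attenuation.
#' Tissue paths are analytic ray-sphere chords against the embryo sphere.
#' Gaussian background noise is added everywhere and the result clipped at 0.
#' In the degradation-free limit (`blur_growth = 0`, infinite attenuation
#' length) a nucleus renders at its nominal peak intensity.
#'
#' The volume is centred on the lab-frame origin: voxel `[k, j, i]` sits at
#' physical position `((i - 1/2) px - Lx/2, (j - 1/2) px - Ly/2,
#' (k - 1/2) dz - Lz/2)`; plane `k = 1` is nearest the detection objective.
#'
#' @param phantom an [embryo_phantom()].
#' @param optics an [optics_model()].
#' @param shape integer 3-vector `c(nz, ny, nx)`.
#' @param pixel_size,plane_spacing physical spacings, micrometres.
#' @param seed integer seed for the background noise.
#' @return An [image_stack()].
#' @export
#' @examples
#' ph <- make_phantom(80, 30, 90, seed = 2, shell_thickness = 40)
#' st <- render_view(ph, optics_model(), c(16, 32, 32), 6, 12, seed = 2)
#' dim(st)
render_view <- function(phantom, optics, shape, pixel_size, plane_spacing,
                        seed = 1L) {
  stopifnot(inherits(phantom, "embryo_phantom"), inherits(optics, "optics_model"))
  if (length(shape) != 3L || any(shape < 1) || any(shape != round(shape))) {
    stop_invalid_parameter("`shape` must be positive integers c(nz, ny, nx)")
  }
  check_positive_scalar(pixel_size, "pixel_size")
  check_positive_scalar(plane_spacing, "plane_spacing")
  nz <- as.integer(shape[1]); ny <- as.integer(shape[2]); nx <- as.integer(shape[3])
  Lx <- nx * pixel_size; Ly <- ny * pixel_size; Lz <- nz * plane_spacing
  xs <- (seq_len(nx) - 0.5) * pixel_size - Lx / 2
  ys <- (seq_len(ny) - 0.5) * pixel_size - Ly / 2
  zs <- (seq_len(nz) - 0.5) * plane_spacing - Lz / 2

  vol <- array(0, dim = c(nz, ny, nx))
  nuc <- phantom$nuclei
  if (nrow(nuc) > 0) {
    p <- as.matrix(nuc[, c("x", "y", "z")])
    l_il <- illumination_path(p, phantom$sphere_center, phantom$sphere_radius,
                              optics$dual_sided_illumination)
    l_dt <- detection_path(p, phantom$sphere_center, phantom$sphere_radius)
    att <- if (is.finite(optics$attenuation_length))
      exp(-l_il / optics$attenuation_length) else 1
    ct <- detection_exit_cos(p, phantom$sphere_center, phantom$sphere_radius)
    aberr <- optics$surface_aberration * (1 / pmax(ct, 0.1) - 1)
    sig_n2 <- (nuc$radius / 2)^2
    sig_det <- optics$blur_sigma0 + optics$blur_growth * l_dt + aberr
    sig_ref_xy <- sqrt(sig_n2 + optics$blur_sigma0^2)
    sig_ref_z <- sqrt(sig_n2 + (optics$axial_ratio * optics$blur_sigma0)^2)
    sig_xy <- sqrt(sig_n2 + sig_det^2)
    sig_z <- sqrt(sig_n2 + (optics$axial_ratio * sig_det)^2)
    ## 3D energy conservation: wider blobs are dimmer; total blob energy
    ## depends on the illumination attenuation alone
    amp <- nuc$intensity * att * (sig_ref_xy / sig_xy)^2 * (sig_ref_z / sig_z)
    for (i in seq_len(nrow(nuc))) {
      vol <- add_blob(vol, xs, ys, zs, p[i, ], amp[i], sig_xy[i], sig_z[i])
    }
  }
  if (optics$background_sd > 0 || optics$background_mean != 0) {
    noise <- with_seed(seed, rnorm(length(vol), optics$background_mean,
                                   optics$background_sd))
    vol <- vol + array(noise, dim = dim(vol))
  }
  vol[vol < 0] <- 0
  image_stack(vol, pixel_size, plane_spacing)
}

## Add one separable Gaussian blob to `vol` (dim nz,ny,nx) over a +-4 sigma
## window; `sigma_xy` is the lateral width, `sigma_z` the axial width, `amp`
## the value at the blob centre.
add_blob <- function(vol, xs, ys, zs, center, amp, sigma_xy, sigma_z = sigma_xy) {
  ext <- 4 * sigma_xy
  ix <- which(abs(xs - center[1]) <= ext)
  iy <- which(abs(ys - center[2]) <= ext)
  iz <- which(abs(zs - center[3]) <= 4 * sigma_z)
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  gx <- exp(-((xs[ix] - center[1])^2) / (2 * sigma_xy^2))
  gy <- exp(-((ys[iy] - center[2])^2) / (2 * sigma_xy^2))
  gz <- exp(-((zs[iz] - center[3])^2) / (2 * sigma_z^2))
  blob <- amp * (gz %o% gy %o% gx)
  vol[iz, iy, ix] <- vol[iz, iy, ix] + blob
  vol
}
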