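## Three acquisition modes on one phantom: a single view, a four-view fusion
## over tube rotations (0/45/180/225 degrees about the vertical tube axis),
## and a single "multi-axis" view taken after magnetically reorienting the
## animal pole toward the detection objective.

TUBE_AXIS <- c(0, 1, 0)        # vertical sample-tube axis (lab y)
DETECTION_DIR <- c(0, 0, -1)   # toward the detection objective (low z)

#' View configuration
#'
#' A tube rotation (about the vertical tube axis) composed with an optional
#' pre-rotation of the sample (modelling magnetic reorientation) applied
#' before the tube rotation.
#'
#' @param tube_rotation degrees in `[0, 360)`.
#' @param pre_rotation 3x3 proper rotation applied to the phantom first.
#' @param label optional text label.
#' @return An object of class `view_config`.
#' @export
view_config <- function(tube_rotation = 0, pre_rotation = diag(3),
                        label = sprintf("view_%g", tube_rotation)) {
  if (!is_scalar_number(tube_rotation) || tube_rotation < 0 || tube_rotation >= 360) {
    stop_invalid_parameter("`tube_rotation` must be in [0, 360) degrees")
  }
  check_rotation(pre_rotation, "pre_rotation")
  structure(list(tube_rotation = tube_rotation, pre_rotation = pre_rotation,
                 label = label),
            class = "view_config")
}

#' Full rotation of a view configuration
#'
#' @param config a [view_config()].
#' @return The 3x3 matrix `R_tube(tube_rotation) %*% pre_rotation`.
#' @export
view_rotation <- function(config) {
  stopifnot(inherits(config, "view_config"))
  rotation_axis_angle(TUBE_AXIS, config$tube_rotation) %*% config$pre_rotation
}

#' Acquire a set of views of one phantom
#'
#' Renders one stack per configuration, rotating the phantom by the view's
#' full rotation first. Per-view noise seeds are derived deterministically
#' from the master seed.
#'
#' @param phantom an [embryo_phantom()].
#' @param optics an [optics_model()].
#' @param configs non-empty list of [view_config()]s.
#' @param shape `c(nz, ny, nx)`.
#' @param pixel_size,plane_spacing micrometres.
#' @param seed master seed.
#' @return List of [image_stack()]s, one per config, named by label.
#' @export
acquire_views <- function(phantom, optics, configs, shape, pixel_size,
                          plane_spacing, seed = 1L) {
  if (length(configs) == 0) stop_invalid_parameter("`configs` must be non-empty")
  stacks <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    stopifnot(inherits(cfg, "view_config"))
    ph <- rotate_phantom(phantom, view_rotation(cfg))
    stacks[[i]] <- render_view(ph, optics, shape, pixel_size, plane_spacing,
                               seed = derive_seed(seed, i))
  }
  names(stacks) <- vapply(configs, `[[`, character(1), "label")
  stacks
}

#' Resample a stack under a rotation about the volume centre
#'
#' Trilinear interpolation; output voxels whose source position falls outside
#' the input volume are `NA` ("not covered").
#'
#' @param stack an [image_stack()].
#' @param rotation 3x3 proper rotation to apply to the volume content.
#' @return A list: `voxels` (3D array with `NA` where uncovered) and the
#'   spacings.
#' @export
resample_rotated <- function(stack, rotation) {
  stopifnot(inherits(stack, "image_stack"))
  check_rotation(rotation)
  v <- resample_rotated_cpp(stack$voxels, dim(stack$voxels),
                            stack$pixel_size, stack$plane_spacing,
                            solve(rotation))
  list(voxels = v, pixel_size = stack$pixel_size,
       plane_spacing = stack$plane_spacing)
}

#' Fuse views using known (ground-truth) rotations
#'
#' Each stack is resampled into the reference frame by the inverse of its
#' known acquisition rotation (trilinear interpolation); the fused voxel is
#' the arithmetic mean (default) over all views covering it, and 0 where no
#' view covers. Registration is deliberately bypassed: the synthetic views
#' have exactly known geometry.
#'
#' @param stacks list of >= 2 [image_stack()]s of identical shape/spacing.
#'   (A single stack is accepted for identity checks.)
#' @param known_rotations list of the 3x3 rotations used to acquire each view.
#' @param method fusion arithmetic over covering views: `"mean"` or `"max"`.
#' @return An [image_stack()] in the reference frame.
#' @export
fuse_views <- function(stacks, known_rotations, method = c("mean", "max")) {
  method <- match.arg(method)
  if (length(stacks) != length(known_rotations)) {
    stop_invalid_input("`stacks` and `known_rotations` must have equal length")
  }
  d0 <- dim(stacks[[1]]$voxels)
  for (s in stacks) {
    if (!inherits(s, "image_stack") || !all(dim(s$voxels) == d0) ||
        s$pixel_size != stacks[[1]]$pixel_size ||
        s$plane_spacing != stacks[[1]]$plane_spacing) {
      stop_invalid_input("all stacks must share shape and spacing")
    }
  }
  acc <- array(0, d0); cnt <- array(0L, d0)
  mx <- array(-Inf, d0)
  for (i in seq_along(stacks)) {
    r <- resample_rotated(stacks[[i]], solve(known_rotations[[i]]))
    ok <- !is.na(r$voxels)
    acc[ok] <- acc[ok] + r$voxels[ok]
    mx[ok] <- pmax(mx[ok], r$voxels[ok])
    cnt[ok] <- cnt[ok] + 1L
  }
  fused <- if (method == "mean") {
    ifelse(cnt > 0, acc / pmax(cnt, 1L), 0)
  } else {
    ifelse(cnt > 0, mx, 0)
  }
  fused[fused < 0] <- 0
  image_stack(array(fused, d0), stacks[[1]]$pixel_size,
              stacks[[1]]$plane_spacing)
}

#' Compare single-view, multi-view and multi-axis acquisition quality
#'
#' Simulates the three acquisition modes on a common phantom and runs each
#' through [quality_profile()], with all depth axes aligned along the
#' animal-vegetal (A-V) axis:
#'
#' * `single_view` - one stack with the A-V axis along the tube axis
#'   (animal pole at the "north pole" of the mounted embryo);
#' * `multi_view` - ground-truth fusion of four views at tube rotations
#'   `angles` (default 0, 45, 180, 225 degrees) in the same orientation;
#' * `multi_axis` - one stack after reorienting the sample so the animal
#'   pole faces the detection objective.
#'
#' For profiling, the single-view and fused volumes are resliced (trilinear,
#' ground-truth rotation) into the analysis frame in which the A-V axis runs
#' along +z with the pole at low z; the multi-axis stack is acquired in that
#' frame already (identity reslice). Choose `shape`/spacings so the physical
#' volume is a cube, keeping 90-degree reslices inside the field of view.
#'
#' @param phantom an [embryo_phantom()] with `cap_half_angle < 180`.
#' @param optics an [optics_model()].
#' @param shape `c(nz, ny, nx)`; the default with the default spacings gives
#'   an isotropic 256 um physical cube around the default 100 um phantom, so
#'   90-degree reslices map the volume onto itself.
#' @param pixel_size,plane_spacing micrometres.
#' @param seed master seed; every stochastic step derives from it.
#' @param radius,corner_size,levels passed to [quality_profile()];
#'   `corner_size` defaults to `round(min(ny, nx) / 8)` so the corners stay
#'   outside the projected embryo at synthetic frame sizes.
#' @param angles tube rotation angles (degrees) fused in `multi_view` mode.
#' @return An object of class `comparison_table`: `table` (tidy data.frame
#'   `mode`, `z_index`, `depth_um`, `score_bits`, `omitted`), `profiles`
#'   (named list of [quality_profile()]s), and the cap depth range
#'   `cap_depth_range` (micrometres along the A-V axis, relative to the
#'   sphere's leading edge) used to define the pole region.
#' @export
compare_modes <- function(phantom, optics = optics_model(),
                          shape = c(64, 128, 128),
                          pixel_size = 2, plane_spacing = 4,
                          seed = 1L, radius = 5L,
                          corner_size = NULL, levels = 256L,
                          angles = c(0, 45, 180, 225)) {
  stopifnot(inherits(phantom, "embryo_phantom"))
  if (phantom$cap_half_angle >= 180) {
    stop_invalid_parameter("compare_modes needs a phantom with a nucleus cap (cap_half_angle < 180)")
  }
  if (nrow(phantom$nuclei) == 0) {
    stop_orientspim("phantom contains no nuclei: no sample boundary can be detected",
                    "orientspim_boundary_not_found")
  }
  if (is.null(corner_size)) corner_size <- max(4L, round(min(shape[2:3]) / 8))

  ## acquisition frame: A-V axis along the tube axis
  ph_a <- rotate_phantom(phantom, rotation_between(phantom$cap_axis, TUBE_AXIS))
  ## analysis frame: A-V axis along the detection axis, pole toward detector
  r_align <- rotation_between(TUBE_AXIS, DETECTION_DIR)
  ph_c <- rotate_phantom(ph_a, r_align)

  ## (a) single view, resliced into the analysis frame
  st_single <- render_view(ph_a, optics, shape, pixel_size, plane_spacing,
                           seed = derive_seed(seed, 101L))
  an_single <- reslice_stack(st_single, r_align)

  ## (b) four-view ground-truth fusion, composed with the analysis alignment
  ## in a single resampling step per view (one interpolation, like mode a)
  cfgs <- lapply(angles, function(a) view_config(a))
  views <- acquire_views(ph_a, optics, cfgs, shape, pixel_size, plane_spacing,
                         seed = derive_seed(seed, 202L))
  rots_to_analysis <- lapply(cfgs, function(cfg) view_rotation(cfg) %*% solve(r_align))
  an_multi <- fuse_views(views, rots_to_analysis)

  ## (c) multi-axis: acquired directly in the analysis frame
  st_axis <- render_view(ph_c, optics, shape, pixel_size, plane_spacing,
                         seed = derive_seed(seed, 303L))
  an_axis <- reslice_stack(st_axis, diag(3))

  ## common units across modes: one quantization range and one (most
  ## conservative) foreground threshold, so score differences reflect image
  ## structure rather than per-stack segmentation jitter
  qrange <- range(c(range(an_single$voxels), range(an_multi$voxels),
                    range(an_axis$voxels)))
  fg_thr <- max(vapply(list(an_single, an_multi, an_axis), function(s)
    background_model(max_projection(s$voxels), corner_size = corner_size)$threshold,
    numeric(1)))
  qp <- function(stack) quality_profile(stack, radius = radius,
                                        corner_size = corner_size,
                                        levels = levels, range = qrange,
                                        background_threshold = fg_thr)
  prof_single <- qp(an_single)
  prof_multi <- qp(an_multi)
  prof_axis <- qp(an_axis)

  profiles <- list(single_view = prof_single, multi_view = prof_multi,
                   multi_axis = prof_axis)
  ## depth axes aligned by known geometry: depth 0 at the pole-side sphere
  ## edge, identical for all modes (robust to +-1-plane jitter in each
  ## stack's own Otsu z0, which still governs the omission rule)
  edge_z <- ph_c$sphere_center[3] - ph_c$sphere_radius
  for (m in names(profiles)) {
    ps <- profiles[[m]]$plane_scores
    plane_z <- (ps$z_index - 0.5) * plane_spacing - shape[1] * plane_spacing / 2
    ps$depth_um <- plane_z - edge_z
    profiles[[m]]$plane_scores <- ps
  }
  tab <- do.call(rbind, lapply(names(profiles), function(m) {
    cbind(mode = m, profiles[[m]]$plane_scores)
  }))
  structure(
    list(table = tab, profiles = profiles,
         cap_depth_range = cap_depth_range(ph_c),
         params = list(shape = shape, pixel_size = pixel_size,
                       plane_spacing = plane_spacing, seed = seed,
                       radius = radius, corner_size = corner_size,
                       levels = levels, angles = angles)),
    class = "comparison_table")
}

## Reslice a stack for analysis, filling uncovered voxels with 0.
reslice_stack <- function(stack, rotation) {
  if (max(abs(rotation - diag(3))) < 1e-12) return(stack)
  r <- resample_rotated(stack, rotation)
  v <- r$voxels
  v[is.na(v)] <- 0
  v[v < 0] <- 0
  image_stack(v, stack$pixel_size, stack$plane_spacing)
}

## Depth extent (um) of the nucleus cap along the A-V axis, measured from the
## sphere's leading edge on the pole side, for a phantom already in the
## analysis frame (cap axis along -z).  Defines the testable "pole region":
## its first quartile.
cap_depth_range <- function(phantom_analysis_frame) {
  ph <- phantom_analysis_frame
  if (nrow(ph$nuclei) == 0) return(c(NA_real_, NA_real_))
  rel <- sweep(as.matrix(ph$nuclei[, c("x", "y", "z")]), 2, ph$sphere_center)
  along_pole <- as.vector(rel %*% ph$cap_axis)   # +R at the pole tip
  depth <- ph$sphere_radius - along_pole         # 0 at the pole-side sphere edge
  range(depth)
}

#' Pole / away-from-pole summary of a comparison
#'
#' The "pole region" is defined as profile depths within the first quartile
#' of the depth range spanned by the nucleus cap along the A-V axis; "away"
#' is the remainder of the cap's depth range. Mean scores are taken over
#' non-omitted, defined planes.
#'
#' @param comparison a [compare_modes()] result.
#' @return data.frame with one row per mode: `pole_mean`, `away_mean`,
#'   `n_pole`, `n_away`.
#' @export
pole_summary <- function(comparison) {
  stopifnot(inherits(comparison, "comparison_table"))
  rng <- comparison$cap_depth_range
  q1 <- rng[1] + 0.25 * (rng[2] - rng[1])
  out <- lapply(names(comparison$profiles), function(m) {
    ps <- comparison$profiles[[m]]$plane_scores
    ok <- !ps$omitted & !is.na(ps$score_bits)
    pole <- ok & ps$depth_um >= rng[1] & ps$depth_um <= q1
    away <- ok & ps$depth_um > q1 & ps$depth_um <= rng[2]
    data.frame(mode = m,
               pole_mean = if (any(pole)) mean(ps$score_bits[pole]) else NA_real_,
               away_mean = if (any(away)) mean(ps$score_bits[away]) else NA_real_,
               n_pole = sum(pole), n_away = sum(away))
  })
  do.call(rbind, out)
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("comparison_table: single_view / multi_view / multi_axis\n")
  print(pole_summary(x))
  invisible(x)
}

#' Write a comparison table to tidy CSV
#'
#' @param comparison a [compare_modes()] result.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "comparison_table"))
  write.csv(comparison$table, path, row.names = FALSE)
  invisible(path)
}

#' Plot quality-vs-depth curves for the three modes
#'
#' @param comparison a [compare_modes()] result.
#' @param path optional PNG path; if `NULL`, plots to the active device.
#' @return Invisibly, `path` (or `NULL`).
#' @export
plot_comparison <- function(comparison, path = NULL) {
  stopifnot(inherits(comparison, "comparison_table"))
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  tab <- comparison$table
  tab <- tab[!tab$omitted & !is.na(tab$score_bits), ]
  cols <- c(single_view = "#1b9e77", multi_view = "#d95f02",
            multi_axis = "#7570b3")
  graphics::plot(NA, xlim = range(tab$depth_um), ylim = range(tab$score_bits),
                 xlab = "depth along animal-vegetal axis (um)",
                 ylab = "quality (mean masked local entropy, bits)")
  for (m in names(cols)) {
    sub <- tab[tab$mode == m, ]
    graphics::lines(sub$depth_um, sub$score_bits, col = cols[[m]], lwd = 2)
  }
  graphics::legend("topright", legend = names(cols), col = unname(cols), lwd = 2)
  invisible(path)
}
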