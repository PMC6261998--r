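## Depth-resolved image quality for SPIM stacks.
##
## The statistic works plane by plane: a background threshold is estimated
## from the four corners of the maximum projection (worst-corner
## mean + 3 SD), each plane is masked to its foreground, the local Shannon
## entropy over a 5 px radius disk is computed, and the masked entropy sum is
## normalized by the foreground pixel count.  An Otsu threshold on the
## maximum projection defines the z = 0 boundary plane and omits
## uninformative planes.

#' Maximum intensity projection
#'
#' @param stack an [image_stack()] or a 3D array indexed `[z, y, x]`.
#' @return A `ny x nx` matrix, pixel `(y, x)` = max over z.
#' @export
max_projection <- function(stack) {
  v <- stack_voxels(stack)
  if (length(v) == 0) stop_invalid_input("empty stack")
  apply(v, c(2, 3), max)
}

stack_voxels <- function(stack) {
  if (inherits(stack, "image_stack")) return(stack$voxels)
  if (is.array(stack) && length(dim(stack)) == 3L) return(stack)
  stop_invalid_input("`stack` must be an image_stack or 3D array")
}

#' Background model from projection corners
#'
#' Extracts `corner_size` x `corner_size` sub-images flush with the four
#' corners of the maximum projection (order: top-left, top-right,
#' bottom-left, bottom-right), records each corner's mean and population SD,
#' and sets the foreground threshold to the largest corner value of
#' mean + 3 SD.  Under Gaussian noise more than 99.7% of true background
#' pixels fall below this threshold.
#'
#' Corners must not contain sample signal for the model to be meaningful.
#' If the image is smaller than `corner_size` per side, the corner shrinks to
#' `floor(min_dim / 2)`; if smaller than `2 * corner_size` per side the
#' corners overlap. Both cases warn and proceed.
#'
#' @param projection 2D numeric matrix (usually from [max_projection()]).
#' @param corner_size corner sub-image side length in pixels.
#' @return An object of class `background_model` with elements
#'   `corner_stats` (data.frame corner/mean/sd), `threshold`, `corner_size`.
#' @export
background_model <- function(projection, corner_size = 100L) {
  if (!is.matrix(projection) || !is.numeric(projection)) {
    stop_invalid_input("`projection` must be a numeric matrix")
  }
  check_positive_scalar(corner_size, "corner_size")
  ny <- nrow(projection); nx <- ncol(projection)
  md <- min(ny, nx)
  cs <- as.integer(corner_size)
  if (md < cs) {
    cs <- max(1L, md %/% 2L)
    warning(sprintf("image smaller than corner_size; shrinking corners to %d px", cs))
  } else if (md < 2L * cs) {
    warning("corner sub-images overlap (image smaller than 2*corner_size); proceeding")
  }
  rows_top <- seq_len(cs); rows_bot <- seq.int(ny - cs + 1L, ny)
  cols_lef <- seq_len(cs); cols_rig <- seq.int(nx - cs + 1L, nx)
  corners <- list(
    top_left = projection[rows_top, cols_lef, drop = FALSE],
    top_right = projection[rows_top, cols_rig, drop = FALSE],
    bottom_left = projection[rows_bot, cols_lef, drop = FALSE],
    bottom_right = projection[rows_bot, cols_rig, drop = FALSE])
  mu <- vapply(corners, mean, numeric(1))
  ## population SD (divide by n): the estimator choice is documented, and at
  ## 10^4 corner pixels it is indistinguishable from the sample SD.
  sdev <- vapply(corners, function(m) sqrt(mean((m - mean(m))^2)), numeric(1))
  stats <- data.frame(corner = names(corners), mean = unname(mu),
                      sd = unname(sdev), row.names = NULL)
  structure(list(corner_stats = stats,
                 threshold = max(mu + 3 * sdev),
                 corner_size = cs),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: threshold %.4g (%d px corners)\n",
              x$threshold, x$corner_size))
  print(x$corner_stats)
  invisible(x)
}

#' Foreground mask of a plane
#'
#' Pixels strictly above the background threshold.
#'
#' @param plane 2D numeric matrix.
#' @param threshold intensity threshold (e.g. from [background_model()]).
#' @return Logical matrix, `TRUE` where `plane > threshold`.
#' @export
foreground_mask <- function(plane, threshold) {
  if (!is.matrix(plane)) stop_invalid_input("`plane` must be a matrix")
  plane > threshold
}

## Linear quantization of intensities to `levels` symbols over `range`.
## Values at or beyond the upper edge fall in the top bin; a degenerate range
## maps everything to symbol 0.
quantize_image <- function(img, levels = 256L, range = NULL) {
  if (is.null(range)) range <- base::range(img)
  lo <- range[1]; hi <- range[2]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    return(matrix(0L, nrow(img), ncol(img)))
  }
  q <- floor((img - lo) / (hi - lo) * levels)
  q[q < 0] <- 0
  q[q > levels - 1] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' Local entropy map of a plane
#'
#' Shannon entropy (bits) of the quantized intensity histogram over a digital
#' disk `{(dy,dx): dy^2 + dx^2 <= radius^2}` centred at each pixel; at image
#' borders the disk is cropped to valid pixels.  Sharp, high-contrast texture
#' yields high entropy; blurred or flat regions yield low entropy.  The
#' default 5 px radius approximately matches the size of a single cell in
#' the intended images.
#'
#' Intensities are linearly quantized to `levels` symbols over `range`
#' (defaults to the plane's own min-max; pass the stack-wide range to make
#' plane maps comparable across a stack).
#'
#' @param plane 2D numeric matrix.
#' @param radius disk radius in pixels (>= 1).
#' @param levels number of quantization levels.
#' @param range length-2 numeric, quantization range.
#' @return Numeric matrix of entropies in `[0, log2(levels)]`.
#' @export
local_entropy <- function(plane, radius = 5L, levels = 256L, range = NULL) {
  if (!is.matrix(plane)) stop_invalid_input("`plane` must be a matrix")
  if (!is_scalar_number(radius) || radius < 1) {
    stop_invalid_parameter("`radius` must be >= 1")
  }
  q <- quantize_image(plane, levels = levels, range = range)
  local_entropy_cpp(q, as.integer(radius), as.integer(levels))
}

#' Plane quality score: masked mean entropy
#'
#' Sums the entropy map over the foreground mask and normalizes by the
#' foreground pixel count, so planes with little content do not artificially
#' score low.  An empty mask yields `NA` (undefined), never zero.
#'
#' @param entropy_map matrix from [local_entropy()].
#' @param mask logical matrix from [foreground_mask()], same shape.
#' @return Scalar score in entropy bits, or `NA_real_` for an empty mask.
#' @export
plane_score <- function(entropy_map, mask) {
  if (!is.matrix(entropy_map) || !is.matrix(mask) ||
      !all(dim(entropy_map) == dim(mask))) {
    stop_invalid_input("`entropy_map` and `mask` must be matrices of the same shape")
  }
  n <- sum(mask)
  if (n == 0) return(NA_real_)
  sum(entropy_map[mask]) / n
}

#' Otsu threshold of an image
#'
#' Classic between-class-variance maximization on a 256-bin histogram over
#' the image's min-max range. Ties are broken toward the lower threshold.
#' Returns an intensity on the image's own scale (the upper edge of the last
#' background bin), so "pixel > threshold" selects the foreground class.
#'
#' @param img numeric matrix or array.
#' @param bins histogram bin count.
#' @return Scalar threshold intensity.
#' @export
otsu_threshold <- function(img, bins = 256L) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  bw <- (hi - lo) / bins
  q <- pmin(floor((v - lo) / bw), bins - 1)
  counts <- tabulate(q + 1L, nbins = bins)
  p <- counts / sum(counts)
  omega <- cumsum(p)                      # class-1 weight for split after bin k
  mu <- cumsum(p * (seq_len(bins) - 1))   # partial means (bin indices)
  mu_t <- mu[bins]
  k <- seq_len(bins - 1L)
  w0 <- omega[k]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, bins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[k][valid])^2 / (w0[valid] * w1[valid])
  k_star <- which.max(sigma_b)            # which.max takes the first (lowest) tie
  lo + k_star * bw
}

#' Embryo boundary plane (z = 0)
#'
#' Applies the Otsu threshold to the maximum projection; the first plane in
#' the stack containing any pixel strictly above that threshold is declared
#' the z = 0 boundary of the sample.
#'
#' @param stack an [image_stack()] or 3D array.
#' @return List with `z0_index` (1-based plane index) and `otsu_threshold`.
#' @export
boundary_plane <- function(stack) {
  v <- stack_voxels(stack)
  thr <- otsu_threshold(max_projection(v))
  hit <- which(apply(v, 1, function(pl) any(pl > thr)))
  if (length(hit) == 0) {
    stop_orientspim("no plane exceeds the Otsu threshold: boundary not found",
                    "orientspim_boundary_not_found")
  }
  list(z0_index = hit[1], otsu_threshold = thr)
}

#' Depth-resolved quality profile of a stack
#'
#' Composes the full per-plane analysis: background threshold from the
#' projection corners, z = 0 boundary via Otsu on the projection, then for
#' every plane from z0 onward a foreground mask and the masked mean local
#' entropy.  Planes (at or after z0) with no pixel above the Otsu threshold
#' are flagged `omitted` and carry no score; planes whose foreground mask is
#' empty score `NA`.  Entropy is quantized over the stack-wide intensity
#' range so scores are comparable across planes.
#'
#' @param stack an [image_stack()]; a bare 3D array is accepted with
#'   `pixel_size = plane_spacing = 1`.
#' @param radius local-entropy disk radius, pixels.
#' @param corner_size background corner sub-image size, pixels.
#' @param levels quantization levels for the entropy histogram.
#' @param range quantization range for the entropy histogram; defaults to
#'   the stack's own min-max. Pass a common range when scores must be
#'   compared across stacks (see [compare_modes()]).
#' @param background_threshold optional externally supplied foreground
#'   threshold; by default the worst-corner mean + 3 SD of this stack's own
#'   projection. Pass a common value when masks must be comparable across
#'   stacks.
#' @return An object of class `quality_profile`: a list with
#'   `plane_scores` (data.frame `z_index`, `depth_um`, `score_bits`,
#'   `omitted`), `z0_index`, `otsu_threshold`, `background`
#'   (the [background_model()]) and `params`.
#' @export
#' @examples
#' ph <- make_phantom(80, 40, 90, seed = 3, shell_thickness = 40)
#' st <- render_view(ph, optics_model(), c(16, 48, 48), 4, 12, seed = 3)
#' qp <- quality_profile(st, corner_size = 6)
#' head(qp$plane_scores)
quality_profile <- function(stack, radius = 5L, corner_size = 100L,
                            levels = 256L, range = NULL,
                            background_threshold = NULL) {
  if (!inherits(stack, "image_stack")) {
    stack <- image_stack(stack_voxels(stack), 1, 1)
  }
  v <- stack$voxels
  proj <- max_projection(v)
  bg <- background_model(proj, corner_size = corner_size)
  fg_thr <- if (is.null(background_threshold)) bg$threshold else background_threshold
  bp <- boundary_plane(stack)
  zs <- seq.int(bp$z0_index, dim(v)[1])
  rng <- if (is.null(range)) base::range(v) else range
  scores <- numeric(length(zs)); omitted <- logical(length(zs))
  for (i in seq_along(zs)) {
    plane <- v[zs[i], , ]
    if (!any(plane > bp$otsu_threshold)) {
      omitted[i] <- TRUE
      scores[i] <- NA_real_
      next
    }
    ent <- local_entropy(plane, radius = radius, levels = levels, range = rng)
    scores[i] <- plane_score(ent, foreground_mask(plane, fg_thr))
  }
  structure(
    list(plane_scores = data.frame(
           z_index = zs,
           depth_um = (zs - bp$z0_index) * stack$plane_spacing,
           score_bits = scores,
           omitted = omitted),
         z0_index = bp$z0_index,
         otsu_threshold = bp$otsu_threshold,
         background = bg,
         params = list(radius = as.integer(radius),
                       foreground_threshold = fg_thr,
                       corner_size = bg$corner_size,
                       levels = as.integer(levels),
                       plane_spacing = stack$plane_spacing)),
    class = "quality_profile")
}

#' @export
print.quality_profile <- function(x, ...) {
  ps <- x$plane_scores
  cat(sprintf(
    "quality_profile: %d planes from z0 = %d (%d omitted), background thr %.4g, Otsu thr %.4g\n",
    nrow(ps), x$z0_index, sum(ps$omitted), x$background$threshold, x$otsu_threshold))
  cat(sprintf("  mean score %.3f bits over %d scored planes\n",
              mean(ps$score_bits, na.rm = TRUE), sum(!is.na(ps$score_bits))))
  invisible(x)
}

#' Write a quality profile to CSV (+ JSON sidecar)
#'
#' @param profile a [quality_profile()].
#' @param path output CSV path; a `.json` sidecar with thresholds and
#'   parameters is written next to it.
#' @return Invisibly, the CSV path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "quality_profile"))
  write.csv(profile$plane_scores, path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  meta <- list(z0_index = profile$z0_index,
               otsu_threshold = profile$otsu_threshold,
               background_threshold = profile$background$threshold,
               corner_stats = profile$background$corner_stats,
               params = profile$params)
  jsonlite::write_json(meta, paste0(side, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
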