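## Geometric model of the tetrahedral electromagnet array used to reorient a
## bead-injected embryo: four coil tips point at the sample from the vertices
## of a regular tetrahedron (109.47 degrees apart).  The embryo's magnetic
## handle aligns with the resultant field direction, modelled as the
## current-weighted sum of the magnet directions; reorientation time scales
## inversely with the applied current.  Force magnitudes, torque dynamics and
## viscous settling are deliberately not modelled.

#' Canonical tetrahedral magnet directions
#'
#' Four unit vectors from the sample centre toward the magnet tips at regular
#' tetrahedron vertices; the first points along +z of the lab frame. Any two
#' directions subtend arccos(-1/3) = 109.47 degrees and the four sum to zero.
#'
#' @return A 4x3 matrix, one unit direction per row (M1..M4).
#' @export
#' @examples
#' d <- tetrahedral_directions()
#' acos(sum(d[1, ] * d[2, ])) * 180 / pi  # 109.4712...
tetrahedral_directions <- function() {
  s2 <- sqrt(2); s23 <- sqrt(2 / 3)
  m <- rbind(
    c(0, 0, 1),
    c(2 * s2 / 3, 0, -1 / 3),
    c(-s2 / 3, s23, -1 / 3),
    c(-s2 / 3, -s23, -1 / 3))
  rownames(m) <- paste0("M", 1:4)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Magnet array with applied currents
#'
#' @param currents length-4 non-negative currents, amperes (order M1..M4).
#' @param directions 4x3 matrix of unit directions; must form a regular
#'   tetrahedron (pairwise dot products -1/3, zero sum).
#' @return An object of class `magnet_array`.
#' @export
magnet_array <- function(currents, directions = tetrahedral_directions()) {
  if (!is.numeric(currents) || length(currents) != 4L ||
      any(!is.finite(currents)) || any(currents < 0)) {
    stop_invalid_parameter("`currents` must be four finite non-negative amperes")
  }
  if (!is.matrix(directions) || !all(dim(directions) == c(4L, 3L))) {
    stop_invalid_parameter("`directions` must be a 4x3 matrix")
  }
  nrm <- sqrt(rowSums(directions^2))
  if (max(abs(nrm - 1)) > 1e-12) {
    stop_invalid_parameter("magnet directions must be unit vectors")
  }
  g <- directions %*% t(directions)
  if (max(abs(g[upper.tri(g)] + 1 / 3)) > 1e-9 ||
      max(abs(colSums(directions))) > 1e-9) {
    stop_invalid_parameter("magnet directions must form a regular tetrahedron")
  }
  structure(list(directions = directions, currents = as.numeric(currents)),
            class = "magnet_array")
}

#' Resultant sample orientation for a set of currents
#'
#' The embryo aligns with the resultant field, modelled as the normalized
#' current-weighted sum of the magnet directions. Scaling all currents by a
#' common factor leaves the orientation unchanged; sweeping the current ratio
#' between two magnets rotates the axis continuously along the geodesic arc
#' between their directions.
#'
#' @param array a [magnet_array()].
#' @return An object of class `orientation_state`: list with `axis` (unit
#'   3-vector) and `angles_deg` (angle to each magnet direction, degrees).
#' @export
#' @examples
#' resultant_direction(magnet_array(c(1, 0, 1, 0)))
resultant_direction <- function(array) {
  stopifnot(inherits(array, "magnet_array"))
  if (all(array$currents == 0)) {
    stop_orientspim("all currents are zero: no field", "orientspim_no_field")
  }
  w <- as.vector(t(array$directions) %*% array$currents)
  n <- sqrt(sum(w^2))
  if (n < 1e-12 * sum(array$currents)) {
    stop_orientspim("currents produce a vanishing resultant field",
                    "orientspim_degenerate_field")
  }
  axis <- w / n
  ang <- acos(pmin(1, pmax(-1, as.vector(array$directions %*% axis)))) * 180 / pi
  structure(list(axis = axis, angles_deg = setNames(ang, rownames(array$directions))),
            class = "orientation_state")
}

#' @export
print.orientation_state <- function(x, ...) {
  cat(sprintf("orientation_state: axis (%.4f, %.4f, %.4f)\n",
              x$axis[1], x$axis[2], x$axis[3]))
  print(round(x$angles_deg, 2))
  invisible(x)
}

#' Reorientation transition time
#'
#' Transition time between magnet orientations is inversely proportional to
#' the applied current: `t = k / current`.
#'
#' @param current applied current, amperes (> 0).
#' @param k proportionality constant, ampere-seconds.
#' @return Transition time in seconds.
#' @export
transition_time <- function(current, k) {
  check_positive_scalar(k, "k")
  if (!is.numeric(current) || any(!is.finite(current)) || any(current <= 0)) {
    stop_invalid_parameter("`current` must be positive")
  }
  k / current
}

#' Fit the inverse current-time law
#'
#' Least-squares estimate of `k` in `t = k / I` from observed
#' (current, time) pairs; closed form
#' `k = sum(t_i / I_i) / sum(1 / I_i^2)`.
#'
#' @param observations data.frame (or list) with elements/columns `current`
#'   (amperes, > 0) and `time` (seconds). At least two observations with
#'   positive currents are required (repeated currents are allowed and give
#'   the weighted solution).
#' @return Scalar estimate of `k`.
#' @export
fit_inverse_law <- function(observations) {
  I <- observations$current
  t <- observations$time
  if (is.null(I) || is.null(t) || length(I) != length(t)) {
    stop_invalid_input("`observations` needs matching `current` and `time`")
  }
  keep <- is.finite(I) & is.finite(t) & I > 0
  if (sum(keep) < 2L) {
    stop_orientspim("need at least 2 observations with positive currents",
                    "orientspim_insufficient_data")
  }
  I <- I[keep]; t <- t[keep]
  sum(t / I) / sum(1 / I^2)
}
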