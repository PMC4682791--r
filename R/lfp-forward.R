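# Extracellular forward model: line-source approximation in an infinite
# homogeneous resistive medium. Units: um, nA, S/m in; uV out.

#' Laminar electrode grid
#'
#' Point electrodes along a vertical line, by default the central axis of
#' the column, spanning depths -400 to +400 um at 25 um intervals
#' (a laminar multielectrode).
#'
#' @param z Electrode depths (um).
#' @param x,y Lateral position (um), recycled across depths.
#' @return A tibble with columns `electrode`, `x`, `y`, `z`.
#' @export
electrode_grid <- function(z = seq(-400, 400, by = 25), x = 0, y = 0) {
  tibble(electrode = seq_along(z), x = x, y = y, z = z)
}

# internal: electrode x compartment mapping matrix (uV per nA)
ls_potential_matrix <- function(comps, electrodes, sigma = 0.3) {
  check_positive(sigma, "sigma")
  n <- nrow(comps)
  dxs <- comps$x1 - comps$x0; dys <- comps$y1 - comps$y0; dzs <- comps$z1 - comps$z0
  ds <- sqrt(dxs^2 + dys^2 + dzs^2)
  r_min <- comps$diam / 2
  m <- matrix(0, nrow(electrodes), n)
  pointlike <- ds < 1e-9
  for (e in seq_len(nrow(electrodes))) {
    rx <- electrodes$x[e] - comps$x0
    ry <- electrodes$y[e] - comps$y0
    rz <- electrodes$z[e] - comps$z0
    phi <- numeric(n)
    li <- !pointlike
    if (any(li)) {
      proj <- (rx[li] * dxs[li] + ry[li] * dys[li] + rz[li] * dzs[li]) / ds[li]
      rho2 <- rx[li]^2 + ry[li]^2 + rz[li]^2 - proj^2
      rho <- pmax(sqrt(pmax(rho2, 0)), r_min[li])
      phi[li] <- (asinh((ds[li] - proj) / rho) + asinh(proj / rho)) / ds[li]
    }
    if (any(pointlike)) {
      ex <- electrodes$x[e] - comps$xm[pointlike]
      ey <- electrodes$y[e] - comps$ym[pointlike]
      ez <- electrodes$z[e] - comps$zm[pointlike]
      r <- pmax(sqrt(ex^2 + ey^2 + ez^2), r_min[pointlike])
      phi[pointlike] <- 1 / r
    }
    m[e, ] <- phi
  }
  m * 1e3 / (4 * pi * sigma)
}

#' Extracellular potential of a single line source
#'
#' Potential of a uniform line current in an infinite homogeneous medium of
#' conductivity `sigma`. A zero-length segment falls back to the point-source
#' formula `I / (4 pi sigma r)`.
#'
#' @param segment_start,segment_end Length-3 segment end points (um).
#' @param current Segment current (nA, positive outward).
#' @param electrode Length-3 electrode position (um).
#' @param sigma Conductivity (S/m).
#' @param diam Segment diameter (um): the perpendicular distance is clamped
#'   to the segment radius so on-axis electrodes stay finite.
#' @return Potential (uV).
#' @export
#' @examples
#' # point-source limit: 1 nA at 100 um in sigma = 0.3 S/m, about 2.653 uV
#' line_source_potential(c(0, 0, 0), c(0, 0, 0), 1, c(100, 0, 0))
line_source_potential <- function(segment_start, segment_end, current, electrode,
                                  sigma = 0.3, diam = 1) {
  comps <- tibble(
    x0 = segment_start[1], y0 = segment_start[2], z0 = segment_start[3],
    x1 = segment_end[1], y1 = segment_end[2], z1 = segment_end[3],
    xm = (segment_start[1] + segment_end[1]) / 2,
    ym = (segment_start[2] + segment_end[2]) / 2,
    zm = (segment_start[3] + segment_end[3]) / 2,
    diam = diam
  )
  el <- tibble(x = electrode[1], y = electrode[2], z = electrode[3])
  as.numeric(ls_potential_matrix(comps, el, sigma)) * current
}

new_lfp_array <- function(lfp, electrodes, time, subset, sigma) {
  structure(
    list(lfp = lfp, electrodes = electrodes, time = time,
         subset = subset %||% "all", sigma = sigma),
    class = "lfp_array"
  )
}

#' @export
print.lfp_array <- function(x, ...) {
  cat(sprintf("<lfp_array> %d electrodes x %d samples (%s contribution)\n",
              nrow(x$lfp), ncol(x$lfp),
              paste(x$subset, collapse = "+")))
  invisible(x)
}

#' Compute the LFP from compartment currents
#'
#' Superposition of line-source potentials over all (or a cell-type subset
#' of) compartments. Requires the current matrix to have been kept
#' (`keep_currents = TRUE`); for long runs prefer streaming via
#' [simulate_currents()]'s `electrodes` argument, which produces the same
#' result chunk-wise.
#'
#' @param currents A `compartment_currents` with its current matrix.
#' @param electrodes An [electrode_grid()].
#' @param sigma Extracellular conductivity (S/m).
#' @param subset Optional cell-type subset (`"pyr"`, `"int"`) whose
#'   compartments contribute.
#' @return An `lfp_array`: electrode-by-time matrix of potentials (uV) plus
#'   electrode geometry and time axis.
#' @export
compute_lfp <- function(currents, electrodes = electrode_grid(), sigma = 0.3,
                        subset = NULL) {
  stopifnot(inherits(currents, "compartment_currents"))
  if (is.null(currents$currents)) {
    abort("current matrix not kept; rerun simulate_currents(keep_currents = TRUE) or stream via `electrodes`")
  }
  # conservation sanity: per-cell current sums should vanish
  probe <- currents$currents[, min(2L, ncol(currents$currents)), drop = TRUE]
  tot <- abs(sum(probe))
  percell <- vapply(split(probe, currents$geometry$cell), sum, numeric(1))
  if (sum(abs(probe)) > 0 && max(abs(percell)) > 1e-6 * sum(abs(probe))) {
    warn("per-cell transmembrane currents do not sum to zero; potentials may be biased")
  }
  sel <- if (is.null(subset)) seq_len(nrow(currents$geometry)) else {
    which(currents$geometry$cell_type %in% subset)
  }
  m <- ls_potential_matrix(currents$geometry[sel, ], electrodes, sigma)
  new_lfp_array(m %*% currents$currents[sel, , drop = FALSE],
                electrodes, currents$time, subset, sigma)
}

#' Population current dipole moment along depth
#'
#' `d_z(t) = sum_i z_i I_i(t)` over compartments `i` with transmembrane
#' currents `I_i` at depths `z_i`; the scalar summary usually reported is
#' the standard deviation of `d_z` over time.
#'
#' @param currents A `compartment_currents` (current matrix kept), or the
#'   streamed result of [simulate_currents()] which already carries the
#'   dipole trace.
#' @param subset Optional cell-type subset.
#' @return A tibble with columns `time` and `dz` (nA um), carrying the
#'   amplitude (sd over time) as attribute `"amplitude"`.
#' @export
dipole_moment <- function(currents, subset = NULL) {
  stopifnot(inherits(currents, "compartment_currents"))
  if (is.null(currents$currents)) {
    if (!is.null(currents$dipole) &&
        (is.null(subset) || identical(subset, currents$subset))) {
      out <- currents$dipole
      attr(out, "amplitude") <- sd(out$dz)
      return(out)
    }
    abort("current matrix not kept; dipole for this subset is unavailable")
  }
  sel <- if (is.null(subset)) seq_len(nrow(currents$geometry)) else {
    which(currents$geometry$cell_type %in% subset)
  }
  dz <- as.numeric(currents$geometry$zm[sel] %*% currents$currents[sel, , drop = FALSE])
  out <- tibble(time = currents$time, dz = dz)
  attr(out, "amplitude") <- sd(dz)
  out
}

#' @rdname dipole_moment
#' @param dipole A dipole tibble from [dipole_moment()].
#' @return `dipole_amplitude()`: the standard deviation of `d_z` over time.
#' @export
dipole_amplitude <- function(dipole) {
  attr(dipole, "amplitude") %||% sd(dipole$dz)
}
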