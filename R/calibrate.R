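#' Calibrate the taper scale to a target somatic input resistance
#'
#' Grows a small population of morphologies, then root-finds the
#' multiplicative dendritic diameter scale for which the population-mean
#' somatic input resistance matches the target (thicker dendrites mean more
#' membrane and less axial shielding, so input resistance decreases
#' monotonically with the scale). This is how the default taper `scale`
#' values of [taper_defaults()] were frozen: pyramidal cells to about
#' 200 MOhm and stellate cells to about 175 MOhm under the
#' `"calibration"` passive set.
#'
#' @param cell_type `"pyr"` or `"int"`.
#' @param target Target mean input resistance (MOhm).
#' @param n_cells Population size used for the calibration average.
#' @param geometry A [column_geometry()].
#' @param passive Passive parameter row for the cell type.
#' @param seed Integer seed.
#' @param interval Search interval for the scale.
#' @return A list with the calibrated `scale`, the achieved `mean_rin`
#'   (MOhm) and the per-cell input resistances.
#' @export
calibrate_taper <- function(cell_type = c("pyr", "int"),
                            target = NULL, n_cells = 10,
                            geometry = column_geometry(),
                            passive = NULL, seed = 1L,
                            interval = c(0.2, 12)) {
  cell_type <- match.arg(cell_type)
  if (is.null(target)) target <- if (cell_type == "pyr") 200 else 175
  if (is.null(passive)) {
    pd <- passive_defaults("calibration")
    passive <- pd[pd$cell_type == cell_type, ]
  }
  trees <- if (cell_type == "pyr") {
    generate_population(geometry, n_pyr = n_cells, n_int = 0, seed = seed)
  } else {
    generate_population(geometry, n_pyr = 0, n_int = n_cells, seed = seed)
  }
  base <- taper_defaults(cell_type)
  rin_at <- function(mult) {
    vapply(trees, function(tr) {
      tr2 <- tr
      dend <- tr2$nodes$type != 1L
      tr2$nodes$radius[dend] <- tr2$nodes$radius[dend] * mult / base$scale
      input_resistance(discretize(tr2, passive))
    }, numeric(1))
  }
  f <- function(mult) mean(rin_at(mult)) - target
  root <- stats::uniroot(f, interval, tol = 1e-3)
  rins <- rin_at(root$root)
  list(scale = root$root, mean_rin = mean(rins), rin = rins,
       cell_type = cell_type, n_cells = n_cells)
}
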