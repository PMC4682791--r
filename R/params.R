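#' Default LIF neuron parameters
#'
#' Membrane and spiking parameters for the two point-neuron populations.
#' Voltages are referenced to the resting potential (rest = 0 mV), so the
#' spike threshold sits 18 mV and the post-spike reset 11 mV above rest.
#'
#' @return A tibble with one row per population (`exc`, `inh`) and columns
#'   `tau_m` (membrane time constant, ms), `v_thr` (threshold, mV above rest),
#'   `v_reset` (reset, mV above rest) and `tau_refr` (absolute refractory
#'   period, ms).
#' @export
#' @examples
#' lif_neuron_defaults()
lif_neuron_defaults <- function() {
  tibble(
    population = c("exc", "inh"),
    tau_m      = c(20, 10),
    v_thr      = c(18, 18),
    v_reset    = c(11, 11),
    tau_refr   = c(2, 1)
  )
}

#' Default LIF synapse parameters
#'
#' Rise/decay time constants and strengths of the four synapse classes seen by
#' each postsynaptic population: recurrent AMPA (`ampa_rec`), thalamic AMPA
#' (`ampa_th`), long-range cortico-cortical AMPA (`ampa_cc`) and GABA.
#' Strengths `j` are in mV: in the current-based point-neuron model the
#' synaptic drive enters the membrane equation with a tau_m prefactor so that
#' postsynaptic currents carry voltage units.
#'
#' @return A tibble with columns `population` (postsynaptic target), `class`,
#'   `tau_r`, `tau_d` (ms), `j` (mV) and `latency` (conduction delay, ms;
#'   applies to recurrent connections only).
#' @export
lif_synapse_defaults <- function() {
  tibble(
    population = rep(c("exc", "inh"), each = 4L),
    class      = rep(c("ampa_rec", "ampa_th", "ampa_cc", "gaba"), 2L),
    tau_r      = c(0.4, 0.4, 0.4, 0.25, 0.2, 0.2, 0.2, 0.25),
    tau_d      = c(2, 2, 2, 5, 2, 2, 2, 5),
    j          = c(0.42, 0.55, 0.42, -1.7, 0.7, 0.95, 0.7, -2.7),
    latency    = 1
  )
}

#' Default passive membrane parameters for the multicompartment stage
#'
#' Two sets are in circulation for this model: the forward-model table set
#' (`"table"`: R_m 30/20 kOhm cm2 for pyramidal/stellate cells) and the
#' morphology-calibration set (`"calibration"`: R_m 20/10 kOhm cm2) under
#' which the quoted somatic input resistances of about 200 MOhm (pyramidal)
#' and 175 MOhm (stellate) hold. Both are exposed; forward simulations
#' default to the table set.
#'
#' @param set `"table"` or `"calibration"`.
#' @return A tibble with columns `cell_type` (`pyr`, `int`), `r_m`
#'   (specific membrane resistance, Ohm cm2), `r_a` (specific axial
#'   resistance, Ohm cm) and `c_m` (specific capacitance, uF/cm2).
#' @export
passive_defaults <- function(set = c("table", "calibration")) {
  set <- match.arg(set)
  r_m <- switch(set, table = c(30000, 20000), calibration = c(20000, 10000))
  tibble(
    cell_type = c("pyr", "int"),
    r_m = r_m,
    r_a = 150,
    c_m = 1.0
  )
}

#' Default synapse parameters for the multicompartment stage
#'
#' Bi-exponential synapse parameters per connection class and postsynaptic
#' cell type. `j` is the peak current (nA, current-based mode), `g` the peak
#' conductance (uS, conductance-based mode) and `e_syn` the reversal
#' potential (mV, conductance-based mode). The bi-exponential waveform is
#' normalised so that its peak equals `j` (or `g`).
#'
#' @return A tibble with columns `cell_type` (postsynaptic `pyr`/`int`),
#'   `class`, `tau_r`, `tau_d` (ms), `j` (nA), `g` (uS), `e_syn` (mV).
#' @export
syn3d_defaults <- function() {
  tibble(
    cell_type = rep(c("pyr", "int"), each = 4L),
    class     = rep(c("ampa_rec", "ampa_th", "ampa_cc", "gaba"), 2L),
    tau_r     = c(0.4, 0.4, 0.4, 0.25, 0.2, 0.2, 0.2, 0.25),
    tau_d     = c(2, 2, 2, 5, 1, 1, 1, 5),
    j         = c(0.070, 0.091, 0.070, -0.145, 0.093, 0.126, 0.093, -0.092),
    g         = c(0.014, 0.0027, 0.014, 0.0057, 0.0023, 0.0047, 0.023, 0.090),
    e_syn     = c(0, 0, 0, -90, 0, 0, 0, -90)
  )
}

#' Column geometry of the simulated cortical patch
#'
#' The population lives in two stacked cylinders. The lower cylinder
#' (containing all somata) spans depths `[-height, 0]`; the upper cylinder is
#' the lower one shifted upward by `cylinder_distance`, spanning
#' `[cylinder_distance - height, cylinder_distance]`. At the reference
#' separation of 250 um the two cylinders are juxtaposed (upper spans
#' `[0, 250]` um) and z = 0 marks their junction; at separation 0 they
#' coincide (the stellate, closed-field arrangement).
#'
#' @param radius Cylinder radius (um).
#' @param height Cylinder height (um).
#' @param cylinder_distance Vertical offset between the two cylinders (um),
#'   swept 0-500 to morph stellate into increasingly pyramidal arrangements.
#' @return A list of class `column_geometry`.
#' @export
column_geometry <- function(radius = 250, height = 250, cylinder_distance = 250) {
  check_positive(radius, "radius")
  check_positive(height, "height")
  check_nonnegative(cylinder_distance, "cylinder_distance")
  structure(
    list(radius = radius, height = height, cylinder_distance = cylinder_distance,
         lower = c(-height, 0),
         upper = c(cylinder_distance - height, cylinder_distance)),
    class = "column_geometry"
  )
}

#' @export
print.column_geometry <- function(x, ...) {
  cat(sprintf(
    "<column_geometry> radius %g um, lower cylinder [%g, %g] um, upper cylinder [%g, %g] um\n",
    x$radius, x$lower[1], x$lower[2], x$upper[1], x$upper[2]
  ))
  invisible(x)
}
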