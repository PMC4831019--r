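# Single-myocyte interface to the compiled cable engine.

# default reversal potentials (mV) of the reduced ventricular model
ENA_SIM <- 70
EK_SIM <- -91
ECA_SIM <- 50
ACT_THRESHOLD <- -20  # mV, upstroke-crossing detector

#' Derive an INa variant from a splice-variant preset
#'
#' Maps a biophysical preset to the two numbers the tissue models consume:
#' the depolarising translation of the fast-Na activation gate (applied
#' identically to its steady state and time constant) and the conductance
#' multiplier. The inactivation gates are untouched.
#'
#' @param preset a [channel_preset()] (or its name).
#' @return an object of class `ina_variant`: list with `act_shift` (mV),
#'   `g_scale`, `source`.
#' @examples
#' make_ina_variant("fetal")  # +7 mV, 0.55
#' @export
make_ina_variant <- function(preset) {
  if (is.character(preset)) preset <- channel_preset(preset)
  validate_preset(preset)
  adult <- channel_preset("adult")
  structure(list(act_shift = preset$v_half_act - adult$v_half_act,
                 g_scale = preset$g_scale, source = preset$name),
            class = "ina_variant")
}

#' @export
print.ina_variant <- function(x, ...) {
  cat(sprintf("<ina_variant '%s'>  activation shift %+.1f mV, g_scale %.2f\n",
              x$source, x$act_shift, x$g_scale))
  invisible(x)
}

# Per-node membrane parameter row for a ventricular layer.
# Transmural heterogeneity enters through the IKr-like conductance
# (Epi > Endo > M), giving the M layer the longest action potential.
ventricular_params <- function(cell_type = c("Endo", "M", "Epi"),
                               variant = make_ina_variant("adult"),
                               gna_multiplier = 1) {
  cell_type <- match.arg(cell_type)
  gkr_scale <- switch(cell_type, Endo = 1.0, M = 0.55, Epi = 1.6)
  c(gNa = 14.838 * gna_multiplier * variant$g_scale,
    shift = variant$act_shift,
    gK1 = 0.5,
    gKr = 0.025 * gkr_scale,
    gCaL = 0.10,
    gleak = 0,
    Eleak = 0,
    hshift = 0)
}

#' Simulate a paced single ventricular myocyte
#'
#' Runs the reduced ventricular membrane model for one cell type under
#' regular pacing and reports the final-beat action potential with its
#' maximal upstroke velocity, APD90 and resting potential.
#'
#' @param cell_type `"Endo"`, `"M"` or `"Epi"`.
#' @param variant an `ina_variant` (default adult).
#' @param cycle_length pacing cycle, ms.
#' @param n_beats number of beats; the final beat is analysed.
#' @param stim_amplitude stimulus current, uA/uF (0 = unpaced).
#' @param stim_duration stimulus duration, ms.
#' @param gna_multiplier scale on the fast-Na conductance (the tissue models
#'   use 2).
#' @param dt time step, ms.
#' @param record_every sampling interval of the returned trace, ms.
#' @return list with `time` (ms, relative to the final-beat stimulus), `v`
#'   (mV), `dvdt_max` (mV/ms), `apd90` (ms), `v_rest` (mV), `activated`.
#' @export
run_cell <- function(cell_type = "Endo", variant = make_ina_variant("adult"),
                     cycle_length = 1000, n_beats = 2, stim_amplitude = 60,
                     stim_duration = 2, gna_multiplier = 1, dt = 0.005,
                     record_every = 0.25) {
  stopifnot(inherits(variant, "ina_variant"))
  if (n_beats < 1) stop("n_beats must be >= 1", call. = FALSE)
  p <- matrix(ventricular_params(cell_type, variant, gna_multiplier), nrow = 1)
  rec_start <- (n_beats - 1) * cycle_length
  out <- cpp_run_cable(p, dx = 0.01, dt = dt, total_ms = n_beats * cycle_length,
                       d_edges = numeric(0), stim_nodes = 0L,
                       stim_amp = stim_amplitude, stim_dur_ms = stim_duration,
                       stim_period_ms = cycle_length, stim_start_ms = 10,
                       record_start_ms = rec_start, record_every_ms = record_every,
                       ena = ENA_SIM, ek = EK_SIM, eca = ECA_SIM,
                       act_threshold = ACT_THRESHOLD)
  v <- out$v[, 1]
  t <- out$time - rec_start
  v_rest <- v[which.min(abs(t - 5))]  # just before the final-beat stimulus
  peak <- max(v)
  activated <- peak > ACT_THRESHOLD
  apd90 <- NA_real_
  if (activated) {
    up <- which(v >= ACT_THRESHOLD)[1]
    v90 <- v_rest + 0.1 * (peak - v_rest)
    below <- which(t > t[up] & v <= v90)
    if (length(below)) apd90 <- t[below[1]] - t[up]
  }
  list(time = t, v = v, dvdt_max = out$dvdt_max[1], apd90 = apd90,
       v_rest = v_rest, activated = activated)
}
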