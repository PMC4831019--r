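# Forward model of oocyte sodium-current families.
#
# Hodgkin-Huxley m^3 h kinetics with a linear driving force:
#   I(t, V) = g_eff * m(t)^3 * h(t) * (V - ENa)
# Gates relax exponentially (closed form) from their holding-potential values
# to the Boltzmann steady states of the preset. The voltage dependence of both
# time constants is translated by the preset's activation shift, and the
# steady-state inactivation curve is shared across presets, so that the
# normalised-conductance curve of a shifted preset is an exact voltage
# translation of the adult one. The effective conductance is normalised such
# that the noise-free peak current at the -10 mV reference potential equals
# g_scale times the adult peak: amplitude reductions are defined, as measured
# experimentally, on peak currents.

# Voltage dependence of the activation time constant (ms); bell around -45 mV.
tau_m_base <- function(v) 0.05 + 0.3 * exp(-((v + 45) / 25)^2)

# Voltage dependence of the inactivation time constant (ms); slow at negative
# potentials, ~0.8 ms near -10 mV.
tau_h_base <- function(v) 0.5 + 8 / (1 + exp((v + 40) / 10))

# Unit-conductance gating trajectory factor m(t)^3 h(t) for one test potential.
clamp_gate_factor <- function(v, t, preset) {
  vm <- v - preset$tau_h_shift   # translated time-constant axis
  m_inf <- boltzmann(v, preset$v_half_act, preset$slope_act)
  m0 <- boltzmann(preset_holding(preset), preset$v_half_act, preset$slope_act)
  h_inf <- boltzmann(v, preset$v_half_inact, preset$slope_inact)
  h0 <- boltzmann(preset_holding(preset), preset$v_half_inact, preset$slope_inact)
  m <- m_inf + (m0 - m_inf) * exp(-t / tau_m_base(vm))
  h <- h_inf + (h0 - h_inf) * exp(-t / tau_h_base(vm))
  m^3 * h
}

# Holding potential used when computing gate initial conditions; stored on the
# preset by gen_clamp_family (default -120 mV).
preset_holding <- function(preset) preset$holding %||% -120

# Unit-conductance peak |I| at the reference potential for a preset.
unit_peak_at <- function(preset, v_ref, protocol) {
  t <- seq(0, protocol$sweep_duration, by = protocol$sample_interval)
  max(clamp_gate_factor(v_ref, t, preset)) * abs(v_ref - ena_oocyte())
}

#' Generate a synthetic voltage-clamp current family
#'
#' Simulates the whole-cell sodium-current family an oocyte expressing the
#' given splice-variant preset would produce under the step protocol, with
#' optional additive Gaussian recording noise. With `noise_sd = 0` the family
#' is fully deterministic and the peak inward current at -10 mV equals
#' `g_scale` times the adult peak.
#'
#' @param preset a [channel_preset()].
#' @param protocol a [clamp_protocol()].
#' @param noise_sd additive Gaussian noise s.d. in current units (uA).
#' @param seed integer seed; the generator uses an isolated RNG stream.
#' @param gmax_adult adult maximal conductance scale (uA/mV); the default
#'   yields adult peaks near -4.6 uA at -10 mV, below the 6 uA quality cutoff.
#' @param v_ref reference potential (mV) at which `g_scale` is defined.
#' @return an object of class `current_family`: list with `protocol`, `time`
#'   (ms), `sweeps` (matrix, time x test potential), `preset`, `ena`, `meta`.
#' @examples
#' fam <- gen_clamp_family(channel_preset("adult"), clamp_protocol(), noise_sd = 0)
#' dim(fam$sweeps)
#' @export
gen_clamp_family <- function(preset, protocol = clamp_protocol(),
                             noise_sd = 0, seed = 1,
                             gmax_adult = 0.085, v_ref = -10) {
  validate_preset(preset)
  stopifnot(inherits(protocol, "clamp_protocol"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  preset$holding <- protocol$holding_potential
  adult <- channel_preset("adult")
  adult$holding <- protocol$holding_potential
  # conductance normalised so peak(v_ref) = g_scale * adult peak(v_ref)
  g_eff <- preset$g_scale * gmax_adult *
    unit_peak_at(adult, v_ref, protocol) / unit_peak_at(preset, v_ref, protocol)
  t <- seq(0, protocol$sweep_duration, by = protocol$sample_interval)
  ena <- ena_oocyte()
  sweeps <- vapply(protocol$test_potentials, function(v) {
    g_eff * clamp_gate_factor(v, t, preset) * (v - ena)
  }, numeric(length(t)))
  colnames(sweeps) <- protocol$test_potentials
  if (noise_sd > 0) {
    sweeps <- sweeps + with_local_seed(seed, {
      matrix(rnorm(length(sweeps), 0, noise_sd), nrow = nrow(sweeps))
    })
  }
  structure(list(protocol = protocol, time = t, sweeps = sweeps,
                 preset = preset, ena = ena,
                 meta = list(variant = preset$name, noise_sd = noise_sd,
                             seed = seed, g_eff = g_eff, v_ref = v_ref)),
            class = "current_family")
}

#' @export
print.current_family <- function(x, ...) {
  cat(sprintf("<current_family '%s'>  %d sweeps (%g..%g mV), %.1f ms @ %.2f ms\n",
              x$meta$variant, ncol(x$sweeps),
              min(x$protocol$test_potentials), max(x$protocol$test_potentials),
              x$protocol$sweep_duration, x$protocol$sample_interval))
  invisible(x)
}

#' Generate a steady-state inactivation (availability) curve
#'
#' Channel availability after long conditioning prepulses, h_inf(V), for a
#' preset. Identical across presets by construction (the splice variants show
#' no SSI difference).
#'
#' @param preset a [channel_preset()].
#' @param prepulse_potentials conditioning potentials, mV.
#' @param noise_sd,seed additive Gaussian noise and seed.
#' @return data.frame with `voltage` and `availability`.
#' @export
gen_ssi_curve <- function(preset, prepulse_potentials = seq(-130, -40, by = 5),
                          noise_sd = 0, seed = 1) {
  validate_preset(preset)
  y <- boltzmann(prepulse_potentials, preset$v_half_inact, preset$slope_inact)
  if (noise_sd > 0)
    y <- y + with_local_seed(seed, rnorm(length(y), 0, noise_sd))
  data.frame(voltage = prepulse_potentials, availability = y)
}

#' Generate a recovery-from-inactivation curve
#'
#' Fractional recovery 1 - exp(-t / tau_rec) at increasing interpulse
#' intervals.
#'
#' @param preset a [channel_preset()].
#' @param intervals interpulse intervals, ms (positive, increasing).
#' @param noise_sd,seed additive Gaussian noise and seed.
#' @return data.frame with `interval` and `recovery`.
#' @export
gen_recovery_curve <- function(preset, intervals = c(1, 2, 5, 10, 20, 50, 100, 200),
                               noise_sd = 0, seed = 1) {
  validate_preset(preset)
  if (any(intervals <= 0) || any(diff(intervals) <= 0))
    stop("intervals must be positive and increasing", call. = FALSE)
  y <- 1 - exp(-intervals / preset$tau_rec)
  if (noise_sd > 0)
    y <- y + with_local_seed(seed, rnorm(length(y), 0, noise_sd))
  data.frame(interval = intervals, recovery = y)
}

#' Write a current family as TSV + JSON sidecar
#'
#' @param family a `current_family`.
#' @param path output TSV path (time in column 1, one column per potential);
#'   a `.json` sidecar with the protocol and generator parameters is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_clamp_family <- function(family, path) {
  stopifnot(inherits(family, "current_family"))
  df <- data.frame(time_ms = family$time, family$sweeps, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", "", path)
  jsonlite::write_json(
    list(protocol = unclass(family$protocol),
         preset = unclass(family$preset), meta = family$meta),
    paste0(sidecar, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
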