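#' Biophysical presets for the SCN5A splice variants
#'
#' Returns the parameter set describing one of the three channel populations
#' studied in oocytes: the adult isoform (exon 6B, hNav1.5), the fetal isoform
#' (exon 6A, hNav1.5e) and an equimolar mix of both. The fetal preset carries a
#' +7 mV depolarising shift of steady-state activation and a peak-current scale
#' of 0.55 relative to adult (a 45% amplitude reduction at the -10 mV reference
#' potential); the mix carries +3.8 mV and 0.70. Steady-state inactivation and
#' recovery from inactivation are identical across presets, while the voltage
#' dependence of the inactivation time constant is translated together with
#' activation.
#'
#' @param name one of `"adult"`, `"fetal"`, `"mix"`.
#' @return an object of class `channel_preset`: a list with fields
#'   `name`, `v_half_act` (mV), `slope_act` (mV), `g_scale`,
#'   `v_half_inact` (mV), `slope_inact` (mV, negative), `tau_h_shift` (mV)
#'   and `tau_rec` (ms).
#' @examples
#' channel_preset("fetal")$v_half_act - channel_preset("adult")$v_half_act  # +7
#' @export
channel_preset <- function(name = c("adult", "fetal", "mix")) {
  name <- match.arg(name)
  base <- list(
    v_half_act   = -40,   # mV, adult mid-activation
    slope_act    = 7,     # mV
    v_half_inact = -85,   # mV, shared across presets (no SSI difference)
    slope_inact  = -6,    # mV, falling-sigmoid convention
    tau_rec      = 20     # ms, shared (no recovery difference)
  )
  shift <- switch(name, adult = 0, fetal = 7, mix = 3.8)
  preset <- c(list(name = name), base)
  preset$v_half_act  <- base$v_half_act + shift
  preset$g_scale     <- switch(name, adult = 1.0, fetal = 0.55, mix = 0.70)
  preset$tau_h_shift <- shift
  structure(preset, class = "channel_preset")
}

#' @export
print.channel_preset <- function(x, ...) {
  cat(sprintf(
    "<channel_preset '%s'>  V1/2(act) %.1f mV, slope %.1f mV, g_scale %.2f\n",
    x$name, x$v_half_act, x$slope_act, x$g_scale))
  cat(sprintf("  V1/2(inact) %.1f mV (slope %.1f), tau_h shift %.1f mV, tau_rec %.0f ms\n",
              x$v_half_inact, x$slope_inact, x$tau_h_shift, x$tau_rec))
  invisible(x)
}

validate_preset <- function(preset) {
  need <- c("name", "v_half_act", "slope_act", "g_scale",
            "v_half_inact", "slope_inact", "tau_h_shift", "tau_rec")
  if (!all(need %in% names(preset)))
    stop("preset is missing fields: ",
         paste(setdiff(need, names(preset)), collapse = ", "), call. = FALSE)
  vals <- unlist(preset[setdiff(need, "name")])
  if (!all(is.finite(vals))) stop("preset parameters must be finite", call. = FALSE)
  if (preset$g_scale <= 0 || preset$g_scale > 1)
    stop("g_scale must lie in (0, 1]", call. = FALSE)
  invisible(preset)
}

#' Voltage-clamp step protocol
#'
#' Describes the two-electrode voltage-clamp protocol used throughout: steps
#' from a -120 mV holding potential to a series of increasing test potentials,
#' sampled at 50 kHz.
#'
#' @param holding_potential holding potential, mV.
#' @param test_potentials strictly increasing test potentials, mV.
#' @param sweep_duration sweep length, ms.
#' @param sample_interval sampling interval, ms (0.02 ms = 50 kHz).
#' @return an object of class `clamp_protocol`.
#' @export
clamp_protocol <- function(holding_potential = -120,
                           test_potentials = seq(-80, 20, by = 5),
                           sweep_duration = 25,
                           sample_interval = 0.02) {
  if (any(diff(test_potentials) <= 0))
    stop("test_potentials must be strictly increasing", call. = FALSE)
  if (sample_interval <= 0) stop("sample_interval must be > 0", call. = FALSE)
  if (sweep_duration <= sample_interval)
    stop("sweep_duration must exceed sample_interval", call. = FALSE)
  structure(list(holding_potential = holding_potential,
                 test_potentials = as.numeric(test_potentials),
                 sweep_duration = sweep_duration,
                 sample_interval = sample_interval),
            class = "clamp_protocol")
}

# Sodium reversal potential used by the forward model: Nernst potential for
# the oocyte bath ([Na]o = 96 mM) against a nominal [Na]i = 10 mM at 22 C.
ena_oocyte <- function(na_out = 96, na_in = 10, temp_c = 22) {
  R <- 8.314462; F_ <- 96485.332
  1000 * R * (273.15 + temp_c) / F_ * log(na_out / na_in)
}
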