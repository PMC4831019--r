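# Channel-kinetics fitting: Boltzmann steady-state activation/inactivation,
# inactivation time constants, recovery, Hill binding curves, and variant
# comparison.

#' Signed peak current of a sweep
#'
#' Returns the extremum of largest magnitude (inward currents negative).
#'
#' @param sweep numeric time series of current (uA).
#' @return signed peak amplitude.
#' @export
peak_current <- function(sweep) {
  if (length(sweep) == 0) stop("empty sweep", call. = FALSE)
  if (all(is.na(sweep))) stop("all-NA sweep", call. = FALSE)
  sweep[which.max(abs(sweep))]
}

#' Current-voltage relation and reversal potential
#'
#' Tabulates peak current per test potential and estimates the reversal
#' potential by linear interpolation between the two peaks flanking zero.
#' If the peaks never change sign the reversal potential is reported as `NA`
#' with a flag (never extrapolated).
#'
#' @param family a `current_family`.
#' @return list with `iv` (data.frame voltage, peak) and `erev` (mV or NA)
#'   and `erev_available`.
#' @export
iv_and_reversal <- function(family) {
  stopifnot(inherits(family, "current_family"))
  v <- family$protocol$test_potentials
  peaks <- apply(family$sweeps, 2, peak_current)
  iv <- data.frame(voltage = v, peak = as.numeric(peaks))
  s <- sign(iv$peak)
  cross <- which(s[-1] * s[-length(s)] < 0 | (s[-length(s)] != 0 & s[-1] == 0))
  if (length(cross) == 0) {
    return(list(iv = iv, erev = NA_real_, erev_available = FALSE))
  }
  i <- cross[length(cross)]  # crossing on the ascending limb
  x1 <- iv$voltage[i]; x2 <- iv$voltage[i + 1]
  y1 <- iv$peak[i]; y2 <- iv$peak[i + 1]
  erev <- x1 - y1 * (x2 - x1) / (y2 - y1)
  list(iv = iv, erev = erev, erev_available = TRUE)
}

boltz_fit_engine <- function(v, y, init_vhalf, init_slope) {
  df <- data.frame(v = v, y = y)
  fit <- try(minpack.lm::nlsLM(
    y ~ 1 / (1 + exp(-(v - vh) / s)), data = df,
    start = list(vh = unname(init_vhalf), s = unname(init_slope)),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Boltzmann fit failed: ", attr(fit, "condition")$message, call. = FALSE)
  cf <- coef(fit)
  structure(list(v_half = unname(cf["vh"]), slope = unname(cf["s"]),
                 residual_sse = sum(residuals(fit)^2), n_points = length(y)),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit>  V1/2 = %.3f mV, slope = %.3f mV (SSE %.3g, n = %d)\n",
              x$v_half, x$slope, x$residual_sse, x$n_points))
  invisible(x)
}

# deterministic, data-driven start: voltage where y crosses 0.5
init_vhalf_from_curve <- function(v, y, falling = FALSE) {
  yy <- if (falling) rev(y) else y
  vv <- if (falling) rev(v) else v
  i <- which(yy >= 0.5)[1]
  if (is.na(i) || i == 1) return(stats::median(v))
  vv[i - 1] + (0.5 - yy[i - 1]) * (vv[i] - vv[i - 1]) / (yy[i] - yy[i - 1])
}

#' Fit steady-state activation from a current family
#'
#' Converts peak currents to conductance `G(V) = Ipeak / (V - Erev)`
#' (dropping any test potential equal to `erev`), normalises to the maximum,
#' and least-squares fits the Boltzmann sigmoid
#' `m_inf = 1 / (1 + exp(-(V - Vm)/s))`.
#'
#' @param family a `current_family`.
#' @param erev reversal potential, mV (estimate it with [iv_and_reversal()]
#'   on a protocol that brackets the reversal).
#' @return a `boltzmann_fit`.
#' @export
fit_activation <- function(family, erev) {
  stopifnot(inherits(family, "current_family"))
  if (!is.finite(erev)) stop("erev must be finite", call. = FALSE)
  v <- family$protocol$test_potentials
  if (length(v) < 5) stop("need at least 5 test potentials", call. = FALSE)
  peaks <- apply(family$sweeps, 2, peak_current)
  keep <- abs(v - erev) > 1e-9
  g <- peaks[keep] / (v[keep] - erev)
  g <- g / max(g)
  boltz_fit_engine(v[keep], g, init_vhalf_from_curve(v[keep], g), 7)
}

#' Fit the inactivation time constant of a sweep
#'
#' Single-exponential decay `A * exp(-(t - t0)/tau)` fitted to the post-peak
#' current by nonlinear least squares (log-linear initialisation).
#'
#' @param sweep current time series (uA).
#' @param time time base, ms.
#' @param window optional `c(start, end)` ms fit window; defaults to from
#'   just after the peak to the end of the sweep.
#' @return list with `tau` (ms), `amplitude`, `residual_sse`.
#' @export
fit_inactivation_tau <- function(sweep, time, window = NULL) {
  stopifnot(length(sweep) == length(time))
  ipk <- which.max(abs(sweep))
  if (is.null(window)) window <- c(time[min(ipk + 2L, length(time))], max(time))
  if (window[1] < time[ipk])
    stop("fit window must start after the peak", call. = FALSE)
  sel <- time >= window[1] & time <= window[2]
  y <- sweep[sel]; t <- time[sel]
  if (length(y) < 4) stop("fit window too short", call. = FALSE)
  a <- abs(y)
  if (a[length(a)] >= a[1])
    stop("window is not decaying; tau fit flagged as failed", call. = FALSE)
  pos <- a > max(a) * 1e-9
  lf <- lm(log(a[pos]) ~ t[pos])
  tau0 <- -1 / coef(lf)[2]
  df <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-(t - t[1]) / tau), data = df,
                           start = list(A = y[1], tau = max(tau0, 1e-3)),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  cf <- coef(fit)
  list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]),
       residual_sse = sum(residuals(fit)^2))
}

#' Fit steady-state inactivation (availability) as a falling Boltzmann
#'
#' @param prepulse_voltages conditioning potentials, mV.
#' @param availability normalised peak currents after each prepulse.
#' @return a `boltzmann_fit` with negative slope.
#' @export
fit_inactivation_ssi <- function(prepulse_voltages, availability) {
  if (length(prepulse_voltages) < 5)
    stop("need at least 5 prepulse voltages", call. = FALSE)
  boltz_fit_engine(prepulse_voltages, availability,
                   init_vhalf_from_curve(prepulse_voltages, availability,
                                         falling = TRUE), -7)
}

#' Fit recovery from inactivation
#'
#' Mono-exponential recovery `1 - exp(-t / tau_rec)`.
#'
#' @param intervals interpulse intervals, ms (positive, increasing).
#' @param recovery fractional recovery values in \[0, 1.05\].
#' @return list with `tau_rec` (ms), `residual_sse`, `t_half` (`tau * ln 2`).
#' @export
fit_recovery <- function(intervals, recovery) {
  if (any(intervals <= 0) || any(diff(intervals) <= 0))
    stop("intervals must be positive and increasing", call. = FALSE)
  if (any(recovery < 0 | recovery > 1.05))
    stop("recovery fractions outside [0, 1.05]", call. = FALSE)
  df <- data.frame(t = intervals, y = recovery)
  half <- intervals[which(recovery >= 0.5)[1]] %||% stats::median(intervals)
  if (is.na(half)) half <- stats::median(intervals)
  fit <- minpack.lm::nlsLM(y ~ 1 - exp(-t / tau), data = df,
                           start = list(tau = half / log(2)),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  tau <- unname(coef(fit)["tau"])
  list(tau_rec = tau, residual_sse = sum(residuals(fit)^2), t_half = tau * log(2))
}

#' Fit a Hill binding curve to gel-shift data
#'
#' Least-squares fit of `y = min + (max - min) / (1 + (x/IC50)^(-HillSlope))`,
#' the sigmoidal reading of the EMSA fitting equation. A flat dataset (no
#' binding, e.g. a mutated probe) is flagged as degenerate instead of
#' returning a spurious IC50.
#'
#' @param concentrations protein concentrations, nM.
#' @param bound_fractions bound probe fractions.
#' @return an object of class `hill_fit`: list with `min_b`, `max_b`, `ic50`,
#'   `hill_slope`, `residual_sse`, `degenerate`.
#' @export
fit_hill <- function(concentrations, bound_fractions) {
  x <- concentrations; y <- bound_fractions
  if (length(x) < 4) stop("need >= 4 concentrations", call. = FALSE)
  if (max(x) / min(x) < 10)
    stop("concentrations must span at least one decade", call. = FALSE)
  if (sd(y) < 1e-6 * max(abs(y), 1)) {
    return(structure(list(min_b = mean(y), max_b = mean(y), ic50 = NA_real_,
                          hill_slope = NA_real_, residual_sse = sum((y - mean(y))^2),
                          degenerate = TRUE), class = "hill_fit"))
  }
  df <- data.frame(x = x, y = y)
  # perfectly noiseless curves can trip the initial-gradient rank check;
  # retry from deterministically perturbed starts before giving up
  starts <- list(
    list(minb = min(y), maxb = max(y), ic50 = exp(mean(log(x))), hill = 1),
    list(minb = min(y) - 0.02, maxb = max(y) + 0.02,
         ic50 = 1.3 * exp(mean(log(x))), hill = 1.6),
    list(minb = min(y) - 0.05, maxb = max(y) + 0.05,
         ic50 = 0.7 * exp(mean(log(x))), hill = 0.7))
  fit <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nlsLM(
      y ~ minb + (maxb - minb) / (1 + (x / ic50)^(-hill)), data = df,
      start = st, lower = c(-Inf, -Inf, min(x) / 100, 0.05),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (!inherits(fit, "try-error")) break
  }
  if (inherits(fit, "try-error"))
    stop("Hill fit failed: ", attr(fit, "condition")$message, call. = FALSE)
  cf <- coef(fit)
  structure(list(min_b = unname(cf["minb"]), max_b = unname(cf["maxb"]),
                 ic50 = unname(cf["ic50"]), hill_slope = unname(cf["hill"]),
                 residual_sse = sum(residuals(fit)^2), degenerate = FALSE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$degenerate) cat("<hill_fit>  degenerate (flat curve, no binding)\n")
  else cat(sprintf("<hill_fit>  IC50 = %.3g nM, Hill slope = %.3g, range %.3g-%.3g\n",
                   x$ic50, x$hill_slope, x$min_b, x$max_b))
  invisible(x)
}

#' Oocyte-style quality control on current families
#'
#' Families whose largest absolute peak exceeds `max_peak` (default 6 uA) are
#' excluded from kinetics, mirroring experimental practice; exclusions are
#' reported via a message.
#'
#' @param families list of `current_family`.
#' @param max_peak exclusion threshold, uA.
#' @return the retained families, with an attribute `excluded` naming the
#'   dropped ones.
#' @export
qc_families <- function(families, max_peak = 6) {
  peaks <- vapply(families, function(f) max(abs(apply(f$sweeps, 2, peak_current))),
                  numeric(1))
  drop <- peaks > max_peak
  if (any(drop))
    message(sum(drop), " famil", if (sum(drop) == 1) "y" else "ies",
            " excluded by QC (peak > ", max_peak, " uA)")
  structure(families[!drop], excluded = which(drop))
}

# two-sample pooled-variance Student t (two-sided)
pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    return(list(t = Inf * sign(mean(x) - mean(y)), p = 0))
  }
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, p = 2 * pt(-abs(tt), nx + ny - 2))
}

#' Compare two channel-variant groups of clamp families
#'
#' Reports the activation mid-potential difference, the percent peak-current
#' reduction at the reference potential, the steady-state inactivation
#' mid-potential difference (when SSI curves are supplied), and two-sided
#' pooled-variance Student t p-values when each group holds at least three
#' replicates.
#'
#' @param reference,test lists of `current_family` (reference = adult-like).
#' @param erev reversal potential used for conductance conversion, mV.
#' @param v_ref test potential for the peak comparison, mV (default -10).
#' @param ssi_reference,ssi_test optional lists of SSI data.frames
#'   (`voltage`, `availability`) per replicate.
#' @param qc apply [qc_families()] before fitting.
#' @return an object of class `variant_comparison`.
#' @export
compare_variants <- function(reference, test, erev, v_ref = -10,
                             ssi_reference = NULL, ssi_test = NULL, qc = TRUE) {
  if (inherits(reference, "current_family")) reference <- list(reference)
  if (inherits(test, "current_family")) test <- list(test)
  proto_sig <- function(f) paste(f$protocol$test_potentials, collapse = ",")
  sigs <- vapply(c(reference, test), proto_sig, character(1))
  if (length(unique(sigs)) != 1)
    stop("mismatched protocols across families", call. = FALSE)
  if (qc) {
    reference <- qc_families(reference)
    test <- qc_families(test)
  }
  peak_at <- function(f) {
    i <- which(abs(f$protocol$test_potentials - v_ref) < 1e-9)
    if (length(i) != 1) stop("reference potential not in protocol", call. = FALSE)
    peak_current(f$sweeps[, i])
  }
  vh <- function(fs) vapply(fs, function(f) fit_activation(f, erev)$v_half, numeric(1))
  pk <- function(fs) vapply(fs, peak_at, numeric(1))
  vh_ref <- vh(reference); vh_test <- vh(test)
  pk_ref <- pk(reference); pk_test <- pk(test)
  res <- list(
    delta_v_half_act = mean(vh_test) - mean(vh_ref),
    percent_peak_reduction = 100 * (1 - mean(abs(pk_test)) / mean(abs(pk_ref))),
    delta_v_half_inact = NA_real_,
    n_per_group = c(reference = length(reference), test = length(test)),
    v_ref = v_ref)
  p_values <- list()
  if (length(reference) >= 3 && length(test) >= 3) {
    p_values$v_half_act <- pooled_t(vh_test, vh_ref)$p
    p_values$peak <- pooled_t(abs(pk_test), abs(pk_ref))$p
  }
  if (!is.null(ssi_reference) && !is.null(ssi_test)) {
    vhi <- function(ds) vapply(ds, function(d)
      fit_inactivation_ssi(d$voltage, d$availability)$v_half, numeric(1))
    vi_ref <- vhi(ssi_reference); vi_test <- vhi(ssi_test)
    res$delta_v_half_inact <- mean(vi_test) - mean(vi_ref)
    if (length(vi_ref) >= 3 && length(vi_test) >= 3)
      p_values$v_half_inact <- pooled_t(vi_test, vi_ref)$p
  }
  res$p_values <- p_values
  structure(res, class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat(sprintf("<variant_comparison>  dV1/2(act) = %+.2f mV, peak reduction = %.1f%% at %g mV\n",
              x$delta_v_half_act, x$percent_peak_reduction, x$v_ref))
  if (is.finite(x$delta_v_half_inact))
    cat(sprintf("  dV1/2(inact) = %+.2f mV\n", x$delta_v_half_inact))
  if (length(x$p_values))
    cat("  p:", paste(names(x$p_values),
                      signif(unlist(x$p_values), 3), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
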