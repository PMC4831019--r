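#' Generate a synthetic gel-shift (EMSA) binding curve
#'
#' Bound fraction of a labelled RNA probe as a function of protein
#' concentration, following the Hill form
#' `y = minb + (maxb - minb) / (1 + (x / ic50)^(-hill))`,
#' with optional additive Gaussian noise. The noise-free value at
#' `x = ic50` is exactly `(minb + maxb) / 2`.
#'
#' @param ic50 half-maximal binding concentration, nM (> 0).
#' @param hill Hill slope (non-zero).
#' @param minb,maxb minimum and maximum bound fraction.
#' @param concentrations protein concentrations, nM (> 0); the default spans
#'   the 5-1,000 nM range used experimentally.
#' @param noise_sd additive Gaussian noise s.d. on the bound fraction.
#' @param seed integer seed (isolated RNG stream).
#' @return data.frame with `concentration` (nM) and `bound_fraction`.
#' @examples
#' gen_gelshift_curve(ic50 = 100, hill = 1.5)[1:3, ]
#' @export
gen_gelshift_curve <- function(ic50, hill, minb = 0, maxb = 1,
                               concentrations = c(5, 10, 25, 50, 100, 250, 500, 1000),
                               noise_sd = 0, seed = 1) {
  if (!is.finite(ic50) || ic50 <= 0) stop("ic50 must be > 0", call. = FALSE)
  if (!is.finite(hill) || hill == 0)
    stop("hill = 0 gives a degenerate (flat) curve", call. = FALSE)
  if (any(concentrations <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (minb > maxb) stop("minb must be <= maxb", call. = FALSE)
  y <- hill_curve(concentrations, minb, maxb, ic50, hill)
  if (noise_sd > 0)
    y <- y + with_local_seed(seed, rnorm(length(y), 0, noise_sd))
  data.frame(concentration = concentrations, bound_fraction = y)
}

# The Hill expression written with the negated exponent, the sigmoidal
# reading of the EMSA fitting equation.
hill_curve <- function(x, minb, maxb, ic50, hill) {
  minb + (maxb - minb) / (1 + (x / ic50)^(-hill))
}
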