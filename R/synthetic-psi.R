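# Synthetic RT-PCR band tables and amplicons for exon 6A/6B quantification.
#
# The BstBI site sits only in exon 6A, so after digestion a 6A amplicon runs
# as a doublet while the 6B amplicon stays intact. Band intensities follow
# mass staining: intensity = molar amount x fragment length, optionally with
# lognormal multiplicative noise.

# endogenous fragment sizes (bp): 6B intact, 6A doublet after digestion
FRAG_6B <- 240L
FRAG_6A_UPPER <- 125L
FRAG_6A_LOWER <- 115L

#' Generate synthetic gel band-intensity tables for exon 6A/6B
#'
#' Draws per-sample PSI (percent of transcripts including exon 6A) from
#' Gaussian group distributions clipped to \[0, 100\], converts molar isoform
#' amounts to band intensities by mass staining (intensity proportional to
#' molar amount times fragment length), and returns one row per sample.
#'
#' @param group_means per-group mean PSI, percent, in \[0, 100\].
#' @param group_sd common s.d. of per-sample PSI, percent.
#' @param n_per_group samples per group (>= 1).
#' @param group_labels optional labels (defaults to group1, group2, ...).
#' @param total_molar total molar amount per lane, arbitrary units.
#' @param intensity_sdlog lognormal noise sdlog applied per band (0 = none).
#' @param seed integer seed (isolated RNG stream).
#' @return an object of class `gel_band_table`: data.frame with columns
#'   `sample_id`, `group`, `psi_true`, `band_6B_intensity`,
#'   `band_6A_upper_intensity`, `band_6A_lower_intensity`, and fragment
#'   length columns `len_6B`, `len_6A_upper`, `len_6A_lower`.
#' @examples
#' gen_psi_tables(c(10, 40), group_sd = 5, n_per_group = 3, seed = 1)
#' @export
gen_psi_tables <- function(group_means, group_sd = 5, n_per_group = 10,
                           group_labels = NULL, total_molar = 1,
                           intensity_sdlog = 0, seed = 1) {
  if (any(group_means < 0 | group_means > 100))
    stop("group_means must lie in [0, 100]", call. = FALSE)
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  if (group_sd < 0) stop("group_sd must be >= 0", call. = FALSE)
  g <- length(group_means)
  labels <- group_labels %||% paste0("group", seq_len(g))
  stopifnot(length(labels) == g)
  with_local_seed(seed, {
    psi <- pmin(100, pmax(0, rnorm(g * n_per_group,
                                   rep(group_means, each = n_per_group),
                                   group_sd)))
    m6a <- total_molar * psi / 100
    m6b <- total_molar * (1 - psi / 100)
    noise <- function(n) if (intensity_sdlog > 0)
      rlnorm(n, -intensity_sdlog^2 / 2, intensity_sdlog) else rep(1, n)
    nsamp <- g * n_per_group
    tab <- data.frame(
      sample_id = sprintf("s%03d", seq_len(nsamp)),
      group = rep(labels, each = n_per_group),
      psi_true = psi,
      band_6B_intensity = m6b * FRAG_6B * noise(nsamp),
      band_6A_upper_intensity = m6a * FRAG_6A_UPPER * noise(nsamp),
      band_6A_lower_intensity = m6a * FRAG_6A_LOWER * noise(nsamp),
      len_6B = FRAG_6B, len_6A_upper = FRAG_6A_UPPER, len_6A_lower = FRAG_6A_LOWER,
      stringsAsFactors = FALSE)
    class(tab) <- c("gel_band_table", "data.frame")
    tab
  })
}

#' Toy amplicon sequences reproducing the printed digest fragment sizes
#'
#' Deterministically constructs named DNA amplicons for the minigene and
#' endogenous exon 6A/6B assays. The BstBI site (TTCGAA, cut after TT) is
#' placed so that digestion reproduces the expected fragment patterns:
#' minigene 6A -> 116 + 71 bp, minigene 6B -> 187 bp intact, endogenous 6A ->
#' 115 + 125 bp doublet, endogenous 6B -> 240 bp intact.
#'
#' @return named character vector of DNA sequences.
#' @examples
#' digest_amplicon(gen_amplicons()[["minigene_6A"]])$fragments  # 116 71
#' @export
gen_amplicons <- function() {
  site <- "TTCGAA"
  # site-free filler: repeat a 5-mer that cannot recreate TTCGAA at any joint
  filler <- function(n) {
    s <- strrep("ACGGT", ceiling(n / 5))
    substr(s, 1, n)
  }
  with_site <- function(total, cut_at) {
    # cut after `cut_at` bases => site starts at 0-based cut_at - 2
    paste0(filler(cut_at - 2), site, filler(total - (cut_at - 2) - nchar(site)))
  }
  c(minigene_6A = with_site(187L, 116L),
    minigene_6B = filler(187L),
    endogenous_6A = with_site(240L, 115L),
    endogenous_6B = filler(240L))
}

#' Generate a synthetic qPCR Ct table
#'
#' Target and reference (RPLP0-style standard) cycle-threshold values for two
#' groups whose true expression ratio is `fold_change`; quantification uses
#' the 2^-dCt rule downstream.
#'
#' @param n_per_group samples per group.
#' @param ct_reference mean reference-gene Ct.
#' @param dct_control mean (target - reference) Ct difference in controls.
#' @param fold_change true target fold change (group2 / group1).
#' @param ct_sd per-well Ct s.d.
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `group`, `ct_target`, `ct_reference`.
#' @export
gen_ct_table <- function(n_per_group = 5, ct_reference = 18, dct_control = 6,
                         fold_change = 1, ct_sd = 0.15, seed = 1) {
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  with_local_seed(seed, {
    n <- 2L * n_per_group
    grp <- rep(c("control", "case"), each = n_per_group)
    dct <- ifelse(grp == "control", dct_control,
                  dct_control - log2(fold_change))
    data.frame(sample_id = sprintf("q%03d", seq_len(n)), group = grp,
               ct_target = rnorm(n, ct_reference + dct, ct_sd),
               ct_reference = rnorm(n, ct_reference, ct_sd),
               stringsAsFactors = FALSE)
  })
}
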