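# Exon 6A/6B inclusion quantification: restriction-digest simulation, PSI
# from gel band intensities, 2^-dCt relative expression, group comparisons
# and PSI-ECG correlation.

#' Simulate a restriction digest of an amplicon
#'
#' Cuts after `cut_offset` bases within every occurrence of the recognition
#' sequence (BstBI: TT^CGAA), scanning left to right with overlapping
#' occurrences allowed. A sequence without the site returns a single
#' fragment.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param recognition recognition sequence (default BstBI).
#' @param cut_offset bases 5' of the cut within the site (default 2).
#' @return list with `fragments` (bp, 5' to 3') and `cut_positions`
#'   (0-based offsets).
#' @examples
#' digest_amplicon(gen_amplicons()[["endogenous_6A"]])$fragments  # 115 125
#' @export
digest_amplicon <- function(sequence, recognition = "TTCGAA", cut_offset = 2) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence))
    stop("sequence must be DNA over {A,C,G,T,N}", call. = FALSE)
  n <- nchar(sequence)
  hits <- Biostrings::matchPattern(recognition, Biostrings::DNAString(sequence))
  cuts <- sort(unique(Biostrings::start(hits) - 1L + cut_offset))
  cuts <- cuts[cuts > 0 & cuts < n]
  bounds <- c(0L, cuts, n)
  list(fragments = as.integer(diff(bounds)), cut_positions = as.integer(cuts))
}

#' Percent spliced-in (PSI) of exon 6A from gel band intensities
#'
#' With length correction on, band intensity is converted to a molar amount
#' by dividing by fragment length (ethidium staining scales with mass); the
#' 6A doublet's two fragments are averaged as one molar species. PSI is
#' `100 * 6A / (6A + 6B)`. All-zero lanes are flagged and excluded.
#'
#' @param table a `gel_band_table` (see [gen_psi_tables()]), or any
#'   data.frame with the same band and length columns.
#' @param length_correct divide intensities by fragment length first
#'   (default TRUE).
#' @return data.frame with `sample_id`, `group`, `psi_6a` (percent);
#'   excluded samples reported in attribute `excluded`.
#' @export
psi_from_bands <- function(table, length_correct = TRUE) {
  need <- c("band_6B_intensity", "band_6A_upper_intensity", "band_6A_lower_intensity")
  if (!all(need %in% names(table)))
    stop("band intensity columns missing", call. = FALSE)
  if (any(unlist(table[need]) < 0))
    stop("band intensities must be >= 0", call. = FALSE)
  zero <- rowSums(table[need]) == 0
  if (any(zero))
    message(sum(zero), " all-zero lane(s) flagged and excluded")
  tab <- table[!zero, , drop = FALSE]
  if (length_correct) {
    m6a <- (tab$band_6A_upper_intensity / tab$len_6A_upper +
              tab$band_6A_lower_intensity / tab$len_6A_lower) / 2
    m6b <- tab$band_6B_intensity / tab$len_6B
  } else {
    m6a <- (tab$band_6A_upper_intensity + tab$band_6A_lower_intensity) / 2
    m6b <- tab$band_6B_intensity
  }
  out <- data.frame(sample_id = tab$sample_id,
                    group = tab$group %||% NA_character_,
                    psi_6a = 100 * m6a / (m6a + m6b),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- table$sample_id[zero]
  attr(out, "length_correct") <- length_correct
  out
}

#' Relative expression by the 2^-dCt rule
#'
#' `2^-(Ct_target - Ct_reference)`, the single-reference quantification used
#' with an RPLP0-style standard.
#'
#' @param ct_target target-gene Ct values.
#' @param ct_reference reference-gene Ct values (recycled).
#' @return fold expression relative to the reference gene.
#' @examples
#' relative_expression(21, 20)  # 0.5
#' @export
relative_expression <- function(ct_target, ct_reference) {
  stop_if_not_finite(ct_target, "ct_target")
  stop_if_not_finite(ct_reference, "ct_reference")
  2^(-(ct_target - ct_reference))
}

#' Two-sample Student comparisons across groups
#'
#' Pairwise two-sided Student t-tests (pooled variance by default, Welch by
#' flag) on a measurement split by group, with significance stars at
#' 0.05 / 0.01 / 0.001. Two groups of zero variance and equal means give
#' p = 1 by convention (logged).
#'
#' @param values numeric measurements.
#' @param groups group labels (>= 2 groups, >= 2 samples each).
#' @param welch use the Welch correction instead of pooled variance.
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `t`, `df`, `p_value`, `stars`.
#' @export
group_compare <- function(values, groups, welch = FALSE) {
  groups <- as.character(groups)
  split_vals <- split(values, groups)
  if (length(split_vals) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(split_vals) < 2)) stop("need >= 2 samples per group", call. = FALSE)
  gn <- names(split_vals)
  pairs <- utils::combn(gn, 2)
  rows <- apply(pairs, 2, function(pr) {
    x <- split_vals[[pr[1]]]; y <- split_vals[[pr[2]]]
    if (var(x) == 0 && var(y) == 0) {
      if (mean(x) == mean(y)) {
        message("zero variance in both groups with equal means (", pr[1], " vs ",
                pr[2], "): p = 1 by convention")
        return(data.frame(group1 = pr[1], group2 = pr[2], t = 0,
                          df = length(x) + length(y) - 2, p_value = 1,
                          stringsAsFactors = FALSE))
      }
      return(data.frame(group1 = pr[1], group2 = pr[2], t = Inf,
                        df = length(x) + length(y) - 2, p_value = 0,
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(x, y, var.equal = !welch)
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- cut(out$p_value, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out$stars <- as.character(out$stars)
  out
}

#' Correlation between exon 6A inclusion and an ECG interval
#'
#' Ordinary least-squares R-squared of the interval on PSI (the published
#' check of whether splicing misregulation tracks conduction measurements).
#'
#' @param psi PSI values, percent.
#' @param interval paired ECG interval values, ms.
#' @return list with `r_squared`, `slope`, `intercept`, `n`.
#' @export
correlate_psi_ecg <- function(psi, interval) {
  if (length(psi) != length(interval)) stop("unpaired inputs", call. = FALSE)
  if (length(psi) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (var(psi) == 0)
    stop("zero-variance predictor: R^2 undefined", call. = FALSE)
  fit <- lm(interval ~ psi)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(psi))
}
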