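# Shared fixtures built in code.

# Tiny hand-checkable cohort: one plus-strand and one minus-strand exon on
# 30-nt contigs, controls from a fixed sequence.
toy_cohort <- function() {
  #            0123456789012345678901234567890
  plus_ctg <- "ACGTACGTACGGATCCGGAATTCCGGTTAA"   # exon [10, 16)
  minus_ctg <- "TTGGCCAATTCCGGAGCCTAGGCATGCATG"  # exon [12, 18) on minus
  ctl_ctg <- "AAAACCCCGGGGTTTTAAAACCCCGGGGTT"
  structure(list(
    records = data.frame(
      id = c("ex_plus", "ex_minus", "ex_ctl"),
      contig = c("c1", "c2", "c3"),
      start = c(10L, 12L, 8L), end = c(16L, 18L, 20L),
      strand = c("+", "-", "+"),
      direction = c("included_in_DM", "excluded_in_DM", "control"),
      stringsAsFactors = FALSE),
    sequences = c(c1 = plus_ctg, c2 = minus_ctg, c3 = ctl_ctg),
    flank_length = 5L, params = list()), class = "exon_cohort")
}

# adult noise-free current family under the standard protocol (memoised)
adult_family <- local({
  fam <- NULL
  function() {
    if (is.null(fam)) fam <<- gen_clamp_family(channel_preset("adult"),
                                               clamp_protocol(), noise_sd = 0)
    fam
  }
})

# reversal potential estimated from an extended-protocol adult family
estimated_erev <- local({
  er <- NULL
  function() {
    if (is.null(er)) {
      ext <- clamp_protocol(test_potentials = seq(-80, 80, 10))
      er <<- iv_and_reversal(gen_clamp_family(channel_preset("adult"), ext,
                                              noise_sd = 0))$erev
    }
    er
  }
})
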