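test_that("window extraction does strand-aware coordinate arithmetic", {
  coh <- toy_cohort()
  win <- extract_windows(coh, flank_length = 5)
  rc <- function(s) {  # independent reverse-complement oracle
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  to_rna <- function(s) chartr("T", "U", s)
  # plus strand: upstream = [5,10), within = [10,16), downstream = [16,21)
  p <- win[win$id == "ex_plus", ]
  expect_equal(p$upstream, unname(to_rna(substr(coh$sequences["c1"], 6, 10))))
  expect_equal(p$within, unname(to_rna(substr(coh$sequences["c1"], 11, 16))))
  expect_equal(p$downstream, unname(to_rna(substr(coh$sequences["c1"], 17, 21))))
  # minus strand: transcript upstream = revcomp of the genomic 3' flank
  m <- win[win$id == "ex_minus", ]
  expect_equal(m$upstream, unname(to_rna(rc(substr(coh$sequences["c2"], 19, 23)))))
  expect_equal(m$within, unname(to_rna(rc(substr(coh$sequences["c2"], 13, 18)))))
  expect_equal(m$downstream, unname(to_rna(rc(substr(coh$sequences["c2"], 8, 12)))))
})

test_that("window truncation at contig edges is flagged, bad records skipped", {
  coh <- toy_cohort()
  coh$records$start[1] <- 2L   # upstream flank of 5 no longer fits
  win <- extract_windows(coh, flank_length = 5)
  expect_equal(nchar(win$upstream[win$id == "ex_plus"]), 2L)
  expect_true(win$truncated[win$id == "ex_plus"])
  coh$records$end[3] <- 999L   # outside the contig
  expect_message(win2 <- extract_windows(coh, flank_length = 5), "skipped")
  expect_false("ex_ctl" %in% win2$id)
})

test_that("k-mer counting enumerates sliding windows and handles N", {
  c1 <- kmer_counts("ACGU", 4)
  expect_equal(unname(c1["ACGU"]), 1L)
  expect_equal(attr(c1, "total"), 1L)
  c2 <- kmer_counts("UGCUGC", 4)
  expect_equal(unname(c2[c("UGCU", "GCUG", "CUGC")]), c(1L, 1L, 1L))
  expect_equal(attr(c2, "total"), 3L)
  expect_equal(attr(kmer_counts(character(0), 4), "total"), 0L)
  expect_equal(attr(kmer_counts("", 4), "total"), 0L)
  # windows containing N contribute nothing
  expect_equal(attr(kmer_counts("ACGNUACG", 4), "total"), 1L)
  expect_error(kmer_counts("ACGU", 0), "k")
  # conservation under concatenation with an N spacer
  withr::with_seed(3, {
    for (i in 1:20) {
      s1 <- paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
      s2 <- paste(sample(c("A", "C", "G", "U"), 25, TRUE), collapse = "")
      joint <- kmer_counts(paste0(s1, "NNN", s2), 4)
      expect_equal(as.integer(joint),
                   as.integer(kmer_counts(s1, 4) + kmer_counts(s2, 4)))
    }
  })
})

test_that("binomial tail is exact against explicit pmf summation", {
  # oracle: sum the binomial pmf over the upper tail directly
  tail_sum <- function(k, n, p) sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
  expect_equal(binomial_motif_test(10, 20, 0.25), tail_sum(10, 20, 0.25),
               tolerance = 1e-12)
  for (cs in list(c(0, 7), c(3, 9), c(250, 1000))) {
    k <- cs[1]; n <- cs[2]
    expect_equal(binomial_motif_test(k, n, 0.31), tail_sum(k, n, 0.31),
                 tolerance = 1e-12)
  }
  # at n = 10,000 the choose() oracle overflows; sum the pmf directly
  expect_equal(binomial_motif_test(3200, 10000, 0.31),
               sum(dbinom(3200:10000, 10000, 0.31)), tolerance = 1e-12)
  expect_equal(binomial_motif_test(0, 50, 0.1), 1)
  # monotone non-increasing in the count
  p_seq <- binomial_motif_test(0:30, 30, 0.4)
  expect_true(all(diff(p_seq) <= 0))
  expect_error(binomial_motif_test(5, 4, 0.2), "exceeds")
  expect_error(binomial_motif_test(1, 4, 0), "bg_freq")
})

test_that("YGC classification matches the motif definition", {
  expect_true(contains_ygc("UGCA"))
  expect_false(contains_ygc("AUGU"))   # UGU is a CUGBP1-style motif, not YGC
  expect_true(contains_ygc("ACGC"))
  expect_equal(contains_ygc(c("GGGG", "CGCA", "UUGC")), c(FALSE, TRUE, TRUE))
  expect_error(contains_ygc("ACGT"), "RNA")
})

test_that("enrichment map detects planted structure and respects the null", {
  coh <- gen_exon_cohort(60, 60, 400, flank_length = 150, plant_motif = "UGCU",
                         plant_fold = 4, seed = 13)
  tab <- build_enrichment_map(coh, alpha = 1e-7)
  sig <- tab[tab$significant, ]
  expect_gt(nrow(sig), 0)
  # significant cells confined to the planted pattern: upstream of included,
  # downstream of excluded
  expect_true(all((sig$region == "upstream" & sig$direction == "included_in_DM") |
                    (sig$region == "downstream" & sig$direction == "excluded_in_DM")))
  # the planted motif ranks first in each planted cell, and most significant
  # motifs contain YGC
  for (cell in split(sig, paste(sig$region, sig$direction))) {
    expect_equal(cell$motif[which.min(cell$p_value)], "UGCU")
  }
  expect_gt(mean(sig$contains_ygc), 0.5)
  # identity background: foreground == background gives p >= 0.5 everywhere
  same <- gen_exon_cohort(40, 0, 40, flank_length = 100, plant_fold = 1, seed = 6)
  # make foreground and background literally identical sequences
  ctr <- same$records$direction == "control"
  same$sequences[same$records$contig[ctr]] <-
    same$sequences[same$records$contig[!ctr]]
  same$records[ctr, c("start", "end", "strand")] <-
    same$records[!ctr, c("start", "end", "strand")]
  tab2 <- build_enrichment_map(same, alpha = 1e-7)
  expect_true(all(tab2$p_value[tab2$fg_count > 0] >= 0.5))
})

test_that("enrichment table is invariant under reverse-complementing the cohort", {
  coh <- gen_exon_cohort(15, 15, 60, flank_length = 60, plant_motif = "UGCU",
                         plant_fold = 3, seed = 17)
  tab1 <- build_enrichment_map(coh)
  flipped <- coh
  flipped$sequences <- vapply(coh$sequences, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  L <- nchar(coh$sequences)[coh$records$contig]
  flipped$records$start <- L - coh$records$end
  flipped$records$end <- L - coh$records$start
  flipped$records$strand <- ifelse(coh$records$strand == "+", "-", "+")
  tab2 <- build_enrichment_map(flipped)
  ord <- function(t) t[order(t$motif, t$region, t$direction), ]
  expect_equal(ord(tab1)$fg_count, ord(tab2)$fg_count)
  expect_equal(ord(tab1)$p_value, ord(tab2)$p_value, tolerance = 1e-12)
})
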