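test_that("restriction digest cuts TT^CGAA and conserves length", {
  # two sites in a 30-mer, verified by hand: cuts after positions 6 and 19
  seq30 <- paste0("ACGG", "TTCGAA", "GGCATCAGG", "TTCGAA", "ACGGT")
  res <- digest_amplicon(seq30)
  expect_equal(res$cut_positions, c(6L, 21L))
  expect_equal(res$fragments, c(6L, 15L, 9L))
  expect_equal(sum(res$fragments), 30L)
  # no site: single fragment
  expect_equal(digest_amplicon("ACGGTACGGT")$fragments, 10L)
  expect_error(digest_amplicon("ACGX"), "DNA")
  # conservation + idempotence on every fragment without an internal site
  withr::with_seed(19, {
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
      r <- digest_amplicon(s)
      expect_equal(sum(r$fragments), nchar(s))
      off <- c(0L, cumsum(r$fragments))
      for (k in seq_along(r$fragments)) {
        frag <- substr(s, off[k] + 1, off[k + 1])
        r2 <- digest_amplicon(frag)
        # re-digesting splits only if the cut site spans a former boundary
        if (length(r2$fragments) == 1) expect_equal(r2$fragments, nchar(frag))
      }
    }
  })
})

test_that("PSI from bands follows the molar mixing model", {
  tab <- gen_psi_tables(c(0, 100), group_sd = 0, n_per_group = 2, seed = 1)
  psi <- psi_from_bands(tab)
  expect_equal(psi$psi_6a, c(0, 0, 100, 100))
  # equal molar amounts give PSI 50
  eq <- data.frame(sample_id = "s1", group = "g",
                   band_6B_intensity = 240, band_6A_upper_intensity = 125,
                   band_6A_lower_intensity = 115,
                   len_6B = 240, len_6A_upper = 125, len_6A_lower = 115)
  expect_equal(psi_from_bands(eq)$psi_6a, 50)
  # 30:70 mixture: exact with length correction, biased without
  mix <- gen_psi_tables(30, group_sd = 0, n_per_group = 1, seed = 1)
  expect_equal(psi_from_bands(mix)$psi_6a, 30)
  raw <- psi_from_bands(mix, length_correct = FALSE)$psi_6a
  bias_expected <- 100 * (0.3 * 120) / (0.3 * 120 + 0.7 * 240)
  expect_equal(raw, bias_expected)
  expect_false(isTRUE(all.equal(raw, 30)))
  # all-zero lanes are flagged and excluded
  z <- eq; z$band_6B_intensity <- 0; z$band_6A_upper_intensity <- 0
  z$band_6A_lower_intensity <- 0
  both <- rbind(eq, z); both$sample_id <- c("ok", "dead")
  expect_message(out <- psi_from_bands(both), "excluded")
  expect_equal(out$sample_id, "ok")
  expect_equal(attr(out, "excluded"), "dead")
})

test_that("PSI of the two mutually exclusive isoforms is complementary", {
  tab <- gen_psi_tables(c(20, 65), group_sd = 10, n_per_group = 5, seed = 4)
  psi_a <- psi_from_bands(tab)$psi_6a
  # recompute PSI(6B) by swapping the roles of the bands
  m6a <- (tab$band_6A_upper_intensity / tab$len_6A_upper +
            tab$band_6A_lower_intensity / tab$len_6A_lower) / 2
  m6b <- tab$band_6B_intensity / tab$len_6B
  psi_b <- 100 * m6b / (m6a + m6b)
  expect_equal(psi_a + psi_b, rep(100, length(psi_a)))
  expect_true(all(psi_a >= 0 & psi_a <= 100))
})

test_that("relative expression implements 2^-dCt", {
  expect_equal(relative_expression(20, 20), 1)
  expect_equal(relative_expression(21, 20), 0.5)
  expect_equal(relative_expression(18, 20), 4)
  # spreadsheet-style oracle on a 4-sample toy table
  ct_t <- c(24.1, 23.8, 25.0, 24.4); ct_r <- c(18.0, 17.9, 18.2, 18.1)
  rel <- relative_expression(ct_t, ct_r)
  expect_equal(exp(mean(log(rel))), 2^(-mean(ct_t - ct_r)), tolerance = 1e-12)
})

test_that("group comparison assigns stars and handles degenerate input", {
  withr::with_seed(2, {
    x <- rnorm(10, 10, 5); y <- rnorm(10, 40, 5)
  })
  cmp <- group_compare(c(x, y), rep(c("a", "b"), each = 10))
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$stars, "***")
  # pooled-variance textbook formula on a 3-vs-3 toy
  a <- c(1, 2, 3); b <- c(2.5, 3.5, 4.5)
  cmp2 <- group_compare(c(a, b), rep(c("g1", "g2"), each = 3))
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  expect_equal(cmp2$t, (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3)),
               tolerance = 1e-12)
  expect_message(z <- group_compare(c(1, 1, 1, 1), rep(c("a", "b"), each = 2)),
                 "convention")
  expect_equal(z$p_value, 1)
  expect_equal(z$stars, "")
  expect_error(group_compare(1:3, c("a", "a", "b")), "2 samples")
})

test_that("PSI-ECG correlation returns OLS R-squared", {
  # lm warns about the exact fit; the R^2 itself is what matters here
  expect_equal(suppressWarnings(correlate_psi_ecg(1:5, 2 * (1:5) + 3)$r_squared), 1)
  # closed-form oracle on a 4-pair toy table
  psi <- c(10, 20, 30, 40); qrs <- c(95, 100, 98, 110)
  r2 <- correlate_psi_ecg(psi, qrs)$r_squared
  r2_hand <- cor(psi, qrs)^2
  expect_equal(r2, r2_hand, tolerance = 1e-12)
  # independent pairs: near-zero R^2
  withr::with_seed(8, {
    expect_lt(correlate_psi_ecg(rnorm(1000), rnorm(1000))$r_squared, 0.01)
  })
  expect_error(correlate_psi_ecg(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(correlate_psi_ecg(1:2, 1:2), "n >= 3")
})
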