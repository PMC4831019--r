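# 4-mer motif enrichment around misregulated exons: strand-aware window
# extraction, k-mer counting, exact one-sided binomial test against a
# control-exon background, and YGC classification.

#' Extract strand-corrected region windows for every exon in a cohort
#'
#' For each record, returns the intronic upstream flank (5' of the exon in
#' transcript orientation), the exon itself, and the downstream intronic
#' flank, as RNA sequences. Minus-strand exons are reverse-complemented so
#' "upstream" always means 5' in transcript orientation. Windows truncated at
#' contig edges are flagged; records whose exon coordinates fall outside the
#' contig are skipped with a message.
#'
#' @param cohort an `exon_cohort`.
#' @param flank_length flank window length, nt (defaults to the cohort's).
#' @return data.frame with `id`, `direction`, `upstream`, `within`,
#'   `downstream` (RNA strings) and `truncated` flag.
#' @export
extract_windows <- function(cohort, flank_length = cohort$flank_length) {
  stopifnot(inherits(cohort, "exon_cohort"))
  r <- cohort$records
  seqs <- cohort$sequences
  clen <- nchar(seqs)[r$contig]
  bad <- is.na(clen) | r$start < 0 | r$end > clen | r$start >= r$end
  if (any(bad)) {
    message(sum(bad), " record(s) with coordinates outside their contig skipped")
    r <- r[!bad, , drop = FALSE]
    clen <- clen[!bad]
  }
  up_s <- pmax(0L, r$start - flank_length); up_e <- r$start
  dn_s <- r$end; dn_e <- pmin(clen, r$end + flank_length)
  contig_seq <- seqs[r$contig]
  sub0 <- function(s, from, to) {  # 0-based half-open substring; "" when empty
    out <- substr(s, from + 1L, to)
    out[to <= from] <- ""
    out
  }
  up <- sub0(contig_seq, up_s, up_e)
  wi <- sub0(contig_seq, r$start, r$end)
  dn <- sub0(contig_seq, dn_s, dn_e)
  minus <- r$strand == "-"
  if (any(minus)) {
    # genomic 3' flank becomes transcript upstream on the minus strand
    new_up <- revcomp(dn[minus])
    dn[minus] <- revcomp(up[minus])
    up[minus] <- new_up
    wi[minus] <- revcomp(wi[minus])
  }
  data.frame(id = r$id, direction = r$direction,
             upstream = unname(dna_to_rna(up)),
             within = unname(dna_to_rna(wi)),
             downstream = unname(dna_to_rna(dn)),
             truncated = unname(nchar(up) < flank_length | nchar(dn) < flank_length),
             stringsAsFactors = FALSE)
}

#' Count all k-mers over a set of RNA sequences
#'
#' Sliding-window counts (overlaps allowed) over the RNA alphabet; windows
#' containing `N` contribute nothing. Counts are summed over all sequences.
#'
#' @param sequences character vector of RNA (or DNA; T is mapped to U).
#' @param k k-mer length (>= 1).
#' @return named integer vector over all 4^k motifs (A/C/G/U alphabet), plus
#'   attribute `total` = total counted windows.
#' @export
kmer_counts <- function(sequences, k = 4) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  sequences <- dna_to_rna(toupper(sequences))
  sequences <- sequences[nchar(sequences) > 0]
  if (length(sequences) == 0) {
    motifs <- all_kmers(k)
    out <- setNames(integer(length(motifs)), motifs)
    attr(out, "total") <- 0L
    return(out)
  }
  rs <- Biostrings::RNAStringSet(sequences)
  m <- Biostrings::oligonucleotideFrequency(rs, width = k, step = 1)
  out <- as.integer(colSums(m))
  names(out) <- colnames(m)
  attr(out, "total") <- sum(out)
  out
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "U")), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

#' Exact one-sided binomial enrichment test
#'
#' Upper-tail probability `P(X >= fg_count)` for
#' `X ~ Binomial(fg_total, bg_freq)`.
#'
#' @param fg_count observed motif occurrences in the foreground.
#' @param fg_total occurrence opportunities in the foreground.
#' @param bg_freq background per-window motif probability, in (0, 1).
#' @return p-value in (0, 1].
#' @export
binomial_motif_test <- function(fg_count, fg_total, bg_freq) {
  if (any(bg_freq <= 0 | bg_freq >= 1))
    stop("bg_freq must lie in (0, 1)", call. = FALSE)
  if (any(fg_total < 1)) stop("fg_total must be >= 1", call. = FALSE)
  if (any(fg_count > fg_total)) stop("fg_count exceeds fg_total", call. = FALSE)
  pbinom(fg_count - 1, fg_total, bg_freq, lower.tail = FALSE)
}

#' Does a motif contain a YGC (CGC/UGC) element?
#'
#' MBNL proteins bind pyrimidine-G-C motifs; a 4-mer is flagged when CGC or
#' UGC occurs as a substring.
#'
#' @param motif character vector of RNA motifs.
#' @return logical vector.
#' @examples
#' contains_ygc(c("UGCA", "AUGU", "ACGC"))  # TRUE FALSE TRUE
#' @export
contains_ygc <- function(motif) {
  if (any(!grepl("^[ACGU]+$", motif)))
    stop("motifs must be RNA over {A,C,G,U}", call. = FALSE)
  grepl("CGC|UGC", motif)
}

#' Build the motif x region x direction enrichment map
#'
#' For each 4-mer, each region (upstream / within / downstream) and each
#' misregulation direction, counts occurrences in the misregulated-exon
#' windows and tests them against the empirical background frequency of the
#' same region in the control exons, with an exact one-sided binomial test.
#' Exons shorter than `k` are skipped for the "within" region (with a count
#' message); an empty background region is skipped with a warning.
#'
#' @param cohort an `exon_cohort`.
#' @param flank_length flank window length, nt.
#' @param k k-mer length.
#' @param alpha significance threshold carried in the output (the published
#'   map used 1e-7).
#' @return an object of class `motif_enrichment_table`: data.frame with
#'   columns `motif`, `region`, `direction`, `fg_count`, `fg_total`,
#'   `bg_freq`, `p_value`, `contains_ygc`, `significant`.
#' @export
build_enrichment_map <- function(cohort, flank_length = cohort$flank_length,
                                 k = 4, alpha = 1e-7) {
  win <- extract_windows(cohort, flank_length)
  if (!any(win$direction %in% c("included_in_DM", "excluded_in_DM")))
    stop("cohort has no misregulated exons", call. = FALSE)
  if (!any(win$direction == "control"))
    stop("cohort has no control exons", call. = FALSE)
  short <- nchar(win$within) < k
  if (any(short))
    message(sum(short), " exon(s) shorter than k skipped for the 'within' region")
  regions <- c("upstream", "within", "downstream")
  ctrl <- win[win$direction == "control", , drop = FALSE]
  bg <- lapply(regions, function(rg) {
    s <- ctrl[[rg]]
    if (rg == "within") s <- s[nchar(s) >= k]
    cnt <- kmer_counts(s, k)
    tot <- attr(cnt, "total")
    if (tot == 0) return(NULL)
    f <- cnt / tot
    # motifs unseen in the background get a half-count floor so they stay
    # testable with bg_freq in (0, 1); observed frequencies are untouched
    f[cnt == 0] <- 0.5 / tot
    f
  })
  names(bg) <- regions
  out <- list()
  for (dir in c("included_in_DM", "excluded_in_DM")) {
    fg <- win[win$direction == dir, , drop = FALSE]
    if (nrow(fg) == 0) next
    for (rg in regions) {
      if (is.null(bg[[rg]])) {
        warning("empty background for region '", rg, "'; skipped")
        next
      }
      s <- fg[[rg]]
      if (rg == "within") s <- s[nchar(s) >= k]
      cnt <- kmer_counts(s, k)
      tot <- attr(cnt, "total")
      if (tot == 0) next
      motifs <- names(cnt)
      p <- binomial_motif_test(as.numeric(cnt), tot, bg[[rg]][motifs])
      out[[paste(dir, rg)]] <- data.frame(
        motif = motifs, region = rg, direction = dir,
        fg_count = as.integer(cnt), fg_total = tot,
        bg_freq = as.numeric(bg[[rg]][motifs]),
        p_value = as.numeric(p),
        contains_ygc = contains_ygc(motifs),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab$significant <- tab$p_value < alpha
  attr(tab, "alpha") <- alpha
  attr(tab, "flank_length") <- flank_length
  attr(tab, "k") <- k
  class(tab) <- c("motif_enrichment_table", "data.frame")
  tab
}

#' Write an enrichment table as long-format TSV
#'
#' @param table a `motif_enrichment_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
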