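# Synthetic exon cohorts with intronic flanks and planted motifs.
#
# Each record lives on its own contig built as
#   pad | upstream flank | exon | downstream flank | pad
# in transcript orientation; minus-strand records store the reverse complement
# so that strand-aware window extraction is exercised. Background sequence is
# i.i.d. nucleotides with configurable composition. A 4-mer motif can be
# planted at `plant_fold` times its background frequency in the upstream flank
# of exons included in DM and the downstream flank of exons excluded in DM,
# mirroring the MBNL splicing map.

DNA_BASES <- c("A", "C", "G", "T")

rna_to_dna <- function(x) chartr("Uu", "Tt", x)
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a synthetic exon cohort (misregulated + control exons)
#'
#' @param n_included,n_excluded number of exons abnormally included/excluded
#'   in DM.
#' @param n_control number of control exons (2,000 mirrors the published
#'   control set size).
#' @param flank_length intronic flank length, nt (>= 4).
#' @param plant_motif RNA 4-mer (over ACGU) to plant, or `NULL` for none.
#' @param plant_fold target fold-enrichment of the planted motif over its
#'   background frequency (>= 1; 1 plants nothing).
#' @param exon_length_range min/max exon length, nt.
#' @param base_composition named probabilities for A, C, G, U.
#' @param pad extra contig padding beyond the flanks, nt.
#' @param seed integer seed (isolated RNG stream).
#' @return an object of class `exon_cohort`: list with `records` (data.frame:
#'   id, contig, start, end, strand, direction; 0-based half-open
#'   coordinates), `sequences` (named character, DNA), `flank_length`,
#'   `params`.
#' @examples
#' coh <- gen_exon_cohort(5, 5, 20, flank_length = 50, seed = 1)
#' table(coh$records$direction)
#' @export
gen_exon_cohort <- function(n_included = 200, n_excluded = 200, n_control = 2000,
                            flank_length = 250, plant_motif = "UGCU",
                            plant_fold = 1, exon_length_range = c(80, 200),
                            base_composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                            pad = 20, seed = 1) {
  if (flank_length < 4) stop("flank_length must be >= 4", call. = FALSE)
  if (plant_fold < 1) stop("plant_fold must be >= 1", call. = FALSE)
  if (!is.null(plant_motif)) {
    if (!grepl("^[ACGU]+$", plant_motif))
      stop("plant_motif must be an RNA motif over {A,C,G,U}", call. = FALSE)
  }
  comp <- base_composition / sum(base_composition)
  names(comp) <- toupper(names(comp))
  if (!setequal(names(comp), c("A", "C", "G", "U")))
    stop("base_composition must name A, C, G, U", call. = FALSE)
  comp <- comp[c("A", "C", "G", "U")]

  n <- n_included + n_excluded + n_control
  if (n < 1) stop("cohort must contain at least one record", call. = FALSE)
  direction <- rep(c("included_in_DM", "excluded_in_DM", "control"),
                   c(n_included, n_excluded, n_control))
  motif_dna <- if (is.null(plant_motif)) NULL else rna_to_dna(plant_motif)
  k <- if (is.null(motif_dna)) 0L else nchar(motif_dna)
  # background per-position probability of the motif under iid composition
  p_bg <- if (is.null(motif_dna)) 0 else
    prod(comp[match(strsplit(plant_motif, "")[[1]], c("A", "C", "G", "U"))])

  with_local_seed(seed, {
    exon_len <- sample(exon_length_range[1]:exon_length_range[2], n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    contig_len <- 2L * pad + 2L * flank_length + exon_len
    total <- sum(contig_len)
    bases <- sample(DNA_BASES, total, replace = TRUE, prob = comp)
    seqs <- vapply(split(bases, rep.int(seq_len(n), contig_len)),
                   paste0, character(1), collapse = "")
    names(seqs) <- NULL

    # plant extra motif copies in the designated flank (transcript orientation)
    if (!is.null(motif_dna) && plant_fold > 1) {
      opp <- flank_length - k + 1          # occurrence opportunities per flank
      extra_mean <- (plant_fold - 1) * opp * p_bg
      for (i in seq_len(n)) {
        if (direction[i] == "control") next
        n_extra <- floor(extra_mean) +
          (runif(1) < (extra_mean - floor(extra_mean)))
        if (n_extra < 1) next
        off <- if (direction[i] == "included_in_DM") pad else
          pad + flank_length + exon_len[i]          # upstream vs downstream
        pos <- off + sample.int(opp, min(n_extra, opp))
        for (p in pos) substr(seqs[i], p, p + k - 1L) <- motif_dna
      }
    }

    start <- ifelse(strand == "+", pad + flank_length,
                    contig_len - (pad + flank_length + exon_len))
    end <- start + exon_len
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    ids <- sprintf("exon_%05d", seq_len(n))
    contigs <- sprintf("contig_%05d", seq_len(n))
    names(seqs) <- contigs
    records <- data.frame(id = ids, contig = contigs,
                          start = as.integer(start), end = as.integer(end),
                          strand = strand, direction = direction,
                          stringsAsFactors = FALSE)
    structure(list(records = records, sequences = seqs,
                   flank_length = flank_length,
                   params = list(n_included = n_included, n_excluded = n_excluded,
                                 n_control = n_control, plant_motif = plant_motif,
                                 plant_fold = plant_fold, base_composition = comp,
                                 exon_length_range = exon_length_range,
                                 pad = pad, seed = seed, p_bg = p_bg)),
              class = "exon_cohort")
  })
}

#' @export
print.exon_cohort <- function(x, ...) {
  tab <- table(x$records$direction)
  cat(sprintf("<exon_cohort>  %d exons (%s), flank %d nt\n",
              nrow(x$records),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              x$flank_length))
  invisible(x)
}

#' Write an exon cohort to disk (FASTA + BED6 + direction TSV + JSON sidecar)
#'
#' @param cohort an `exon_cohort`.
#' @param dir output directory (created if absent).
#' @param prefix file name prefix.
#' @return named character vector of written paths, invisibly.
#' @export
write_exon_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "exon_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$sequences), fa)
  bed <- file.path(dir, paste0(prefix, ".bed"))
  r <- cohort$records
  write.table(data.frame(r$contig, r$start, r$end, r$id, 0L, r$strand),
              bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  dirs <- file.path(dir, paste0(prefix, "_directions.tsv"))
  write.table(r[, c("id", "direction")], dirs, sep = "\t", quote = FALSE,
              row.names = FALSE)
  side <- file.path(dir, paste0(prefix, ".json"))
  p <- cohort$params
  p$base_composition <- as.list(p$base_composition)
  jsonlite::write_json(c(p, list(flank_length = cohort$flank_length)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, bed = bed, directions = dirs, sidecar = side))
}

#' Read an exon cohort from FASTA + BED6 + direction TSV
#'
#' @param fasta FASTA of contigs.
#' @param bed BED6 exon records (0-based half-open; strand in column 6).
#' @param directions TSV with columns `id`, `direction`.
#' @param flank_length flank length to carry on the cohort, nt.
#' @return an `exon_cohort`.
#' @export
read_exon_cohort <- function(fasta, bed, directions, flank_length = 250) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  seqv <- as.character(seqs)
  names(seqv) <- sub("\\s.*$", "", names(seqs))
  b <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  d <- read.table(directions, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  records <- data.frame(id = b$V4, contig = b$V1, start = b$V2, end = b$V3,
                        strand = b$V6,
                        direction = d$direction[match(b$V4, d$id)],
                        stringsAsFactors = FALSE)
  structure(list(records = records, sequences = seqv,
                 flank_length = flank_length, params = list()),
            class = "exon_cohort")
}
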