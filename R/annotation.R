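tx_exon_granges <- function(transcripts) {
  ex <- transcripts |>
    dplyr::select("transcript_id", "chrom", "strand", "exons") |>
    tidyr::unnest("exons")
  GenomicRanges::GRanges(ex$chrom,
                         IRanges::IRanges(ex$start, ex$end),
                         strand = ex$strand,
                         transcript_id = ex$transcript_id)
}

tx_span_granges <- function(transcripts) {
  sp <- transcripts |>
    dplyr::mutate(start = vapply(.data$exons, function(e) min(e$start), numeric(1)),
                  end = vapply(.data$exons, function(e) max(e$end), numeric(1)))
  GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start, sp$end),
                         strand = sp$strand, transcript_id = sp$transcript_id)
}

#' Identify lncRNA candidates among assembled transcripts
#'
#' A transcript is retained as a lncRNA iff it is at least `min_length` nt
#' (default 200), has no same-strand exonic overlap with a known mRNA, and
#' has low coding potential: longest forward-frame ORF shorter than
#' `max_orf` nt (default 300). A precomputed coding-potential table can be
#' supplied instead of the ORF heuristic.
#'
#' @param transcripts Candidate transcript tibble with spliced `sequence`.
#' @param known_mrna Known mRNA transcript tibble (exon coordinates used).
#' @param min_length Minimum spliced length in nt.
#' @param max_orf ORF-length threshold in nt for the coding heuristic.
#' @param coding_scores Optional tibble (`transcript_id`, `coding`) of
#'   externally computed coding calls (TRUE = coding) overriding the ORF rule.
#' @return The candidate tibble with logical columns `too_short`,
#'   `overlaps_mrna`, `coding`, and `retained`.
#' @export
identify_lncrna <- function(transcripts, known_mrna, min_length = 200,
                            max_orf = 300, coding_scores = NULL) {
  if (is.null(transcripts$sequence) || anyNA(transcripts$sequence)) {
    stop("transcripts must carry spliced sequences")
  }
  q <- tx_exon_granges(transcripts)
  s <- tx_exon_granges(known_mrna)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s, ignore.strand = FALSE))
  overlapping_tx <- unique(S4Vectors::mcols(q)$transcript_id[S4Vectors::queryHits(hits)])

  out <- transcripts
  out$too_short <- nchar(out$sequence) < min_length
  out$overlaps_mrna <- out$transcript_id %in% overlapping_tx
  if (is.null(coding_scores)) {
    out$longest_orf <- vapply(out$sequence, longest_orf, integer(1), USE.NAMES = FALSE)
    out$coding <- out$longest_orf >= max_orf
  } else {
    out$coding <- coding_scores$coding[match(out$transcript_id,
                                             coding_scores$transcript_id)]
    if (anyNA(out$coding)) stop("coding_scores missing transcript(s)")
  }
  out$retained <- !out$too_short & !out$overlaps_mrna & !out$coding
  out
}

#' Classify circRNAs by locus type
#'
#' A circRNA is `exon` type if its circularized span overlaps at least one
#' exon of a same-strand transcript, `intron` type if it lies fully inside
#' an intron of a same-strand transcript, and `intergenic` otherwise.
#'
#' @param circs circRNA annotation tibble (`circ_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param gene_models Transcript tibble with exon structures.
#' @return The circRNA tibble with a `locus_type` column.
#' @export
classify_circrna <- function(circs, gene_models) {
  cg <- GenomicRanges::GRanges(circs$chrom, IRanges::IRanges(circs$start, circs$end),
                               strand = circs$strand)
  exons <- tx_exon_granges(gene_models)
  spans <- tx_span_granges(gene_models)
  hit_exon <- suppressWarnings(
    GenomicRanges::countOverlaps(cg, exons, ignore.strand = FALSE)) > 0
  within_span <- suppressWarnings(
    GenomicRanges::countOverlaps(cg, spans, type = "within",
                                 ignore.strand = FALSE)) > 0
  circs$locus_type <- ifelse(hit_exon, "exon",
                             ifelse(within_span, "intron", "intergenic"))
  circs
}

#' Assign cis-regulated coding targets to lncRNAs
#'
#' Emits a (lncRNA, gene) pair whenever the minimal genomic distance between
#' their spans is at most `window` nt (100 kb by default). Distance is the
#' gap width between the spans (overlapping or adjacent spans have distance
#' 0); both strands are considered. The signed distance is negative when the
#' lncRNA lies upstream of the gene in the gene's orientation.
#'
#' @param lncrnas lncRNA transcript tibble.
#' @param coding_genes Coding-gene transcript tibble.
#' @param window Maximum distance in nt (default 100000).
#' @return A tibble with `lncrna_id`, `gene_id`, `distance` (unsigned gap)
#'   and `signed_distance`.
#' @export
assign_cis_targets <- function(lncrnas, coding_genes, window = 100000) {
  lg <- tx_span_granges(lncrnas)
  gg <- tx_span_granges(coding_genes)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(lg, gg, maxgap = window, ignore.strand = TRUE))
  if (length(hits) == 0) {
    return(tibble::tibble(lncrna_id = character(), gene_id = character(),
                          distance = integer(), signed_distance = integer()))
  }
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(lg[qi], gg[si], ignore.strand = TRUE)
  ls <- GenomicRanges::start(lg)[qi]; le <- GenomicRanges::end(lg)[qi]
  gs <- GenomicRanges::start(gg)[si]; ge <- GenomicRanges::end(gg)[si]
  gstrand <- as.character(BiocGenerics::strand(gg))[si]
  upstream <- ifelse(gstrand == "-", ls > ge, le < gs)
  tibble::tibble(
    lncrna_id = S4Vectors::mcols(lg)$transcript_id[qi],
    gene_id = gene_of(coding_genes)[si],
    distance = as.integer(d),
    signed_distance = as.integer(ifelse(d == 0, 0L, ifelse(upstream, -d, d)))
  ) |> dplyr::distinct()
}

gene_of <- function(transcripts) {
  if ("gene_id" %in% names(transcripts)) transcripts$gene_id else transcripts$transcript_id
}

#' Stem-loop (hairpin) heuristic for miRNA precursors
#'
#' Scans all arm/loop/arm splits of a genomic window (loop length
#' `loop_range`, default 3-150 nt) and passes iff some split lets the
#' mature-containing arm pair with the opposite arm at >= `min_pairing` of
#' mature positions, counting Watson-Crick and G:U pairs along the fold's
#' antidiagonal. The default threshold (0.85) is calibrated so that random
#' windows pass in well under 5% of trials.
#'
#' @param window_sequence Genomic window around the mature (RNA or DNA).
#' @param mature_start 1-based start of the mature within the window.
#' @param mature_length Length of the mature miRNA in nt.
#' @param min_pairing Minimum paired fraction of mature positions.
#' @param loop_range Allowed loop lengths (nt), default `c(3, 150)`.
#' @return TRUE if any split passes; FALSE otherwise (including windows
#'   shorter than 2 x mature + minimum loop).
#' @export
hairpin_check <- function(window_sequence, mature_start, mature_length,
                          min_pairing = 0.85, loop_range = c(3, 150)) {
  w <- up_chars(dna_to_rna(window_sequence))
  n <- length(w)
  m1 <- mature_start
  m2 <- mature_start + mature_length - 1
  if (m1 < 1 || m2 > n) stop("mature lies outside the window")
  if (n < 2 * mature_length + loop_range[1]) return(FALSE)
  mat <- w[m1:m2]
  can_pair <- function(a, b) {
    (a == "A" & b == "U") | (a == "U" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G") |
      (a == "G" & b == "U") | (a == "U" & b == "G")
  }
  # In a fold with last left-arm base c and first right-arm base d, base i
  # pairs with s - i where s = c + d; the paired fraction depends on s only.
  frac_for_sum <- function(s) {
    partners <- s - (m1:m2)
    ok <- partners >= 1 & partners <= n
    if (!any(ok)) return(0)
    sum(can_pair(mat[ok], w[partners[ok]])) / mature_length
  }
  gmin <- loop_range[1]; gmax <- loop_range[2]
  # mature in the left arm: need c >= m2, d <= n, g = s - 2c - 1 in range
  s_lo <- 2 * m2 + gmin + 1; s_hi <- n + m1
  if (s_lo <= s_hi) {
    for (s in s_lo:s_hi) {
      c_lo <- max(m2, s - n, ceiling((s - gmax - 1) / 2))
      c_hi <- floor((s - gmin - 1) / 2)
      if (c_lo <= c_hi && frac_for_sum(s) >= min_pairing) return(TRUE)
    }
  }
  # mature in the right arm: need d <= m1, c >= 1
  s_lo <- m2 + 1; s_hi <- 2 * m1 - gmin - 1
  if (s_lo <= s_hi) {
    for (s in s_lo:s_hi) {
      c_lo <- max(1, s - m1, ceiling((s - gmax - 1) / 2))
      c_hi <- floor((s - gmin - 1) / 2)
      if (c_lo <= c_hi && frac_for_sum(s) >= min_pairing) return(TRUE)
    }
  }
  FALSE
}

#' Catalogue known and novel miRNAs from small RNA reads
#'
#' Reads are length-filtered to 18-25 nt. A read matching a same-length
#' reference mature with at most 3 mismatches (Hamming distance, no indels)
#' is `known`; otherwise, if the read maps exactly to the genome and the
#' 200-nt flanking window folds into a stem-loop ([hairpin_check()]), it is
#' `novel`; all other reads are `dropped`.
#'
#' @param reads Tibble with `read_id`, `sequence` and optional `count`.
#' @param reference_matures Tibble (`id`, `sequence`) of known matures.
#' @param genome Genome tibble ([read_fasta()]).
#' @param flank Flanking length for the precursor window (default 200).
#' @param ... Passed on to [hairpin_check()].
#' @return A tibble with `read_id`, `sequence`, `length`, `five_prime_nt`,
#'   `status` (`known`/`novel`/`dropped`), `n_mismatch`, `hairpin_pass`.
#'   The number of reads removed by the length filter is recorded in the
#'   `n_length_filtered` attribute.
#' @export
catalogue_mirna <- function(reads, reference_matures, genome, flank = 200, ...) {
  reads$sequence <- dna_to_rna(reads$sequence)
  len <- nchar(reads$sequence)
  dropped_len <- sum(len < 18 | len > 25)
  reads <- reads[len >= 18 & len <= 25, ]
  refs <- dna_to_rna(reference_matures$sequence)
  ref_len <- nchar(refs)

  genome_rna <- dna_to_rna(genome$sequence)
  genome_rc <- vapply(genome$sequence, revcomp, character(1), USE.NAMES = FALSE)

  res <- purrr::map(seq_len(nrow(reads)), function(i) {
    s <- reads$sequence[i]
    L <- nchar(s)
    mm <- NA_integer_
    same <- refs[ref_len == L]
    if (length(same)) {
      rc <- up_chars(s)
      mm <- min(vapply(same, function(r) sum(up_chars(r) != rc), integer(1)))
    }
    if (!is.na(mm) && mm <= 3) {
      return(list(status = "known", n_mismatch = mm, hairpin_pass = NA))
    }
    # locate exactly on the genome (either strand) and test the precursor fold
    for (ci in seq_along(genome_rna)) {
      for (strand_seq in list(genome_rna[ci], genome_rc[ci])) {
        at <- regexpr(s, strand_seq, fixed = TRUE)[1]
        if (at > 0) {
          wstart <- max(1, at - flank)
          wend <- min(nchar(strand_seq), at + L - 1 + flank)
          win <- substr(strand_seq, wstart, wend)
          hp <- hairpin_check(win, at - wstart + 1, L, ...)
          return(list(status = if (hp) "novel" else "dropped",
                      n_mismatch = mm, hairpin_pass = hp))
        }
      }
    }
    list(status = "dropped", n_mismatch = mm, hairpin_pass = NA)
  })
  out <- tibble::tibble(
    read_id = reads$read_id,
    sequence = reads$sequence,
    length = nchar(reads$sequence),
    five_prime_nt = substr(reads$sequence, 1, 1),
    status = vapply(res, `[[`, character(1), "status"),
    n_mismatch = vapply(res, function(x) as.integer(x$n_mismatch), integer(1)),
    hairpin_pass = vapply(res, function(x) as.logical(x$hairpin_pass), logical(1))
  )
  attr(out, "n_length_filtered") <- dropped_len
  out
}

#' Summary statistics for a miRNA catalogue
#'
#' @param catalogue A [catalogue_mirna()] result (dropped reads excluded).
#' @return A list with `length_distribution` (tibble `length`, `n`) and
#'   `first_nt_composition` (tibble `length`, `five_prime_nt`, `n`, `prop`).
#' @export
mirna_summary <- function(catalogue) {
  kept <- dplyr::filter(catalogue, .data$status != "dropped")
  list(
    length_distribution = dplyr::count(kept, .data$length, name = "n"),
    first_nt_composition = kept |>
      dplyr::count(.data$length, .data$five_prime_nt, name = "n") |>
      dplyr::group_by(.data$length) |>
      dplyr::mutate(prop = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  )
}
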