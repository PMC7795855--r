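#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased; `U` is preserved for RNA inputs. Record ids are
#' the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("FASTA format error: no records in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad)) stop("invalid characters in FASTA sequence(s): ",
                     paste(ids[bad], collapse = ", "))
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write a tibble of sequences as FASTA
#'
#' @param x A tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  lines <- unlist(purrr::map2(x$id, x$sequence, function(id, s) {
    c(paste0(">", id),
      substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3 or GTF
#'
#' Parses transcript structures (one row per transcript, exons as a nested
#' tibble of 1-based inclusive genomic intervals sorted by start). The
#' attribute dialect is auto-detected from the file unless given.
#'
#' @param path Path to a GFF3 or GTF file.
#' @param dialect `"auto"`, `"gff3"` or `"gtf"`.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `biotype`, `exons` (list of tibbles with `start`, `end`),
#'   `n_exons` and `length` (spliced length in nt).
#' @export
read_gene_models <- function(path, dialect = c("auto", "gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (dialect == "auto") {
    ln <- readLines(path, n = 200)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    if (length(ln) == 0) stop("no feature lines in ", path)
    attrs <- sub("^([^\t]*\t){8}", "", ln[1])
    # GTF attributes look like: key "value"; ... ; GFF3 like key=value;
    dialect <- if (grepl("=", attrs, fixed = TRUE) && !grepl("\"", attrs)) "gff3" else "gtf"
  }
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "gtf")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  is_exon <- type == "exon"
  if (!any(is_exon)) stop("no exon features in ", path)

  if (dialect == "gtf") {
    tx_of_exon <- as.character(mc$transcript_id)[is_exon]
    gene_of_exon <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)[is_exon] else tx_of_exon
    bio_map <- NULL
  } else {
    parent <- mc$Parent
    tx_of_exon <- vapply(seq_along(gr)[is_exon], function(i) {
      p <- parent[[i]]
      if (length(p) == 0) NA_character_ else as.character(p[1])
    }, character(1))
    # transcript-level features give gene parentage and biotype
    tx_rows <- which(!is_exon & !is.na(mc$ID) & type != "gene")
    bio_map <- tibble::tibble(
      transcript_id = as.character(mc$ID)[tx_rows],
      gene_id = vapply(tx_rows, function(i) {
        p <- parent[[i]]
        if (length(p) == 0) NA_character_ else as.character(p[1])
      }, character(1)),
      biotype = type[tx_rows]
    )
    gene_of_exon <- rep(NA_character_, sum(is_exon))
  }
  bad <- which(is.na(tx_of_exon) | tx_of_exon == "")
  if (length(bad)) {
    stop("exon feature without a parent transcript attribute (exon index ",
         bad[1], " of ", path, ")")
  }

  ex <- tibble::tibble(
    transcript_id = tx_of_exon,
    gene_id = gene_of_exon,
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    strand = as.character(BiocGenerics::strand(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon],
    end = GenomicRanges::end(gr)[is_exon]
  )
  ex <- dplyr::arrange(ex, .data$transcript_id, .data$start)
  tx <- purrr::map_dfr(split(ex, ex$transcript_id), function(g) {
    tibble::tibble(
      transcript_id = g$transcript_id[1], gene_id = g$gene_id[1],
      chrom = g$chrom[1], strand = g$strand[1],
      exons = list(tibble::tibble(start = g$start, end = g$end))
    )
  })
  if (!is.null(bio_map) && nrow(bio_map)) {
    tx <- tx |>
      dplyr::left_join(bio_map, by = "transcript_id") |>
      dplyr::mutate(gene_id = dplyr::coalesce(.data$gene_id.y, .data$gene_id.x,
                                              .data$transcript_id)) |>
      dplyr::select(-"gene_id.x", -"gene_id.y")
  } else {
    tx$biotype <- NA_character_
  }
  tx |>
    dplyr::mutate(
      gene_id = dplyr::coalesce(.data$gene_id, .data$transcript_id),
      biotype = normalize_biotype(.data$biotype),
      n_exons = vapply(.data$exons, nrow, integer(1)),
      length = vapply(.data$exons, function(e) sum(e$end - e$start + 1L), integer(1))
    ) |>
    dplyr::select("transcript_id", "gene_id", "chrom", "strand", "biotype",
                  "exons", "n_exons", "length")
}

normalize_biotype <- function(x) {
  dplyr::case_match(
    x,
    c("mRNA", "transcript") ~ "mRNA",
    c("lncRNA", "lnc_RNA") ~ "lncRNA",
    "circRNA" ~ "circRNA",
    c("precursor_miRNA", "miRNA_primary_transcript", "pre_miRNA") ~ "precursor_miRNA",
    .default = "unknown"
  )
}

#' Write gene models as GFF3
#'
#' Emits one transcript-level feature (typed by biotype) plus its exon
#' children per record; `read_gene_models()` round-trips the retained fields.
#'
#' @param transcripts A transcript tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(transcripts, path) {
  type_of <- c(mRNA = "mRNA", lncRNA = "lnc_RNA", circRNA = "circRNA",
               precursor_miRNA = "miRNA_primary_transcript", unknown = "transcript")
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    ex <- t$exons[[1]]
    ty <- type_of[[t$biotype %||% "unknown"]]
    lines <- c(
      lines,
      paste(t$chrom, "plantcerna", ty, min(ex$start), max(ex$end), ".",
            t$strand, ".", paste0("ID=", t$transcript_id, ";Parent=", t$gene_id),
            sep = "\t"),
      paste(t$chrom, "plantcerna", "exon", ex$start, ex$end, ".",
            t$strand, ".", paste0("ID=", t$transcript_id, ".exon", seq_len(nrow(ex)),
                                  ";Parent=", t$transcript_id),
            sep = "\t")
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract the spliced transcript sequence from a genome
#'
#' Exon sequences are concatenated 5' to 3' in transcript orientation
#' (reverse-complemented for minus-strand transcripts) and returned in RNA
#' space (T transliterated to U).
#'
#' @param genome A tibble with columns `id` and `sequence` ([read_fasta()]).
#' @param transcript A single transcript row ([read_gene_models()]).
#' @return The spliced RNA sequence as a single string.
#' @export
extract_spliced_sequence <- function(genome, transcript) {
  chrom_seq <- genome$sequence[match(transcript$chrom, genome$id)]
  if (is.na(chrom_seq)) stop("chromosome not in genome: ", transcript$chrom)
  ex <- transcript$exons[[1]]
  if (any(ex$start < 1) || any(ex$end > nchar(chrom_seq))) {
    stop("exon beyond chromosome bounds for ", transcript$transcript_id)
  }
  chunks <- substring(chrom_seq, ex$start, ex$end)
  s <- paste(chunks, collapse = "")
  if (transcript$strand == "-") s <- revcomp(s, out = "dna")
  dna_to_rna(s)
}

#' Add spliced sequences to a transcript table
#'
#' @inheritParams extract_spliced_sequence
#' @param transcripts A transcript tibble.
#' @return The tibble with a `sequence` column (RNA space).
#' @export
add_spliced_sequences <- function(transcripts, genome) {
  transcripts$sequence <- vapply(seq_len(nrow(transcripts)), function(i) {
    extract_spliced_sequence(genome, transcripts[i, ])
  }, character(1))
  transcripts
}

#' Read and write count tables
#'
#' Count tables are TSV with a `feature_id` column followed by one column per
#' sample, sample ids encoded as `<tissue>_<condition>_<replicate>` (e.g.
#' `leaf_ck_1`).
#'
#' @param path Path to a TSV file.
#' @return `read_count_table()`: a wide tibble; `sample_design()`: a tibble
#'   with `sample_id`, `tissue`, `condition`, `replicate`.
#' @export
read_count_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_count_table
#' @param x A wide count tibble.
#' @export
write_count_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname read_count_table
#' @param sample_ids Character vector of sample ids.
#' @export
sample_design <- function(sample_ids) {
  parts <- strsplit(sample_ids, "_", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) stop("sample id(s) not of the form tissue_condition_rep: ",
                     paste(sample_ids[bad], collapse = ", "))
  tibble::tibble(
    sample_id = sample_ids,
    tissue = vapply(parts, `[[`, character(1), 1),
    condition = vapply(parts, `[[`, character(1), 2),
    replicate = as.integer(vapply(parts, `[[`, character(1), 3))
  )
}

#' Read a circRNA back-splice annotation table
#'
#' Expected TSV columns, in order: `circ_id`, `chrom`, `start`, `end`,
#' `strand` (1-based inclusive coordinates of the circularized span).
#'
#' @param path Path to the TSV file.
#' @return A tibble with the five columns above.
#' @export
read_circ_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         circ_id = readr::col_character(),
                         chrom = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         strand = readr::col_character()
                       ))
  if (any(x$start > x$end)) stop("circRNA with start > end")
  x
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
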