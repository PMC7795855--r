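# Shared fixtures. Studies and pipeline runs are cached per seed so the
# recovery tests across files do not recompute them.
.fixture_cache <- new.env(parent = emptyenv())

get_study <- function(seed) {
  key <- paste0("study_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_cerna_study(seed = seed)
  }
  .fixture_cache[[key]]
}

get_pipeline <- function(seed) {
  key <- paste0("pipe_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- run_cerna_pipeline(get_study(seed))
  }
  .fixture_cache[[key]]
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

# minimal transcript tibble builder (1-based inclusive exons)
make_tx <- function(id, chrom, strand, exons, biotype = "mRNA",
                    sequence = NA_character_, gene_id = id) {
  tibble::tibble(transcript_id = id, gene_id = gene_id, chrom = chrom,
                 strand = strand, biotype = biotype,
                 exons = list(tibble::tibble(start = exons[, 1], end = exons[, 2])),
                 sequence = sequence)
}

empty_planted_de <- tibble::tibble(feature_id = character(), tissue = character(),
                                   direction = character(), log2FC = numeric())

# wide count tibble from a matrix with standard leaf/root sample names
counts_from_matrix <- function(m, tissue = "leaf") {
  samp <- paste(tissue, rep(c("ck", "st"), each = 3), 1:3, sep = "_")
  out <- tibble::tibble(feature_id = sprintf("f%03d", seq_len(nrow(m))))
  for (i in seq_len(ncol(m))) out[[samp[i]]] <- m[, i]
  out
}
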