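#' Run the full ceRNA inference pipeline on a study
#'
#' Orchestrates the stage functions end-to-end: FPKM/CPM normalization,
#' class-specific differential expression per tissue, target scanning in
#' cleavage and mimic modes, degradome validation, negative-pair tabulation
#' and per-tissue network assembly. Deterministic: no randomness is drawn
#' here, so the same study object always yields identical results.
#'
#' @param study A `cerna_study` ([simulate_cerna_study()]) or a list with
#'   the same components assembled from files.
#' @param alpha Raw p cutoff for DE calls (default 0.05).
#' @param relaxed_tissues Tissues whose gene-like DE sets are re-filtered at
#'   p < 0.1 ([relax_threshold_mode()]), as when a tissue yields no ceRNAs
#'   at the strict cutoff.
#' @param r_threshold Correlation threshold for network edges.
#' @param require_pair_positivity Apply the competing-pair condition.
#' @return A list: `fpkm`, `cpm`, `de_gene` and `de_mirna` (per-tissue
#'   lists), `sites`, `events`, `networks` (per tissue), `negative_pairs`.
#' @export
run_cerna_pipeline <- function(study, alpha = 0.05,
                               relaxed_tissues = character(),
                               r_threshold = 0.7,
                               require_pair_positivity = TRUE) {
  fpkm <- compute_fpkm(study$counts, study$feature_lengths)
  cpm <- normalize_mirna(study$mirna_counts)
  # correlation inputs use median-of-ratios normalization (robust to the
  # composition shifts a small feature set shows under strong DE)
  corr_gene <- normalize_counts(study$counts)
  corr_mirna <- normalize_counts(study$mirna_counts)
  scan_tbl <- dplyr::bind_rows(
    tibble::tibble(transcript_id = study$transcripts$transcript_id,
                   sequence = study$transcripts$sequence,
                   class = study$transcripts$biotype),
    tibble::tibble(transcript_id = study$circs$circ_id,
                   sequence = study$circs$sequence, class = "circRNA")
  )
  sites <- scan_all_targets(study$mirnas, scan_tbl)
  events <- validate_sites(sites, study$degradome, study$feature_lengths)

  tissues <- c("leaf", "root")
  de_gene <- list(); de_mirna <- list(); networks <- list(); np <- list()
  for (ts in tissues) {
    dg <- de_test(study$counts, ts, class = "gene_like", alpha = alpha)
    if (ts %in% relaxed_tissues) dg <- relax_threshold_mode(dg)
    dg$class <- unname(study$feature_classes[dg$feature_id])
    dm <- de_test(study$mirna_counts, ts, class = "mirna", alpha = alpha)
    de_gene[[ts]] <- dg
    de_mirna[[ts]] <- dm
    networks[[ts]] <- suppressWarnings(build_network(
      dg, dm, sites, corr_gene, corr_mirna, events, ts,
      r_threshold = r_threshold,
      require_pair_positivity = require_pair_positivity))
    np[[ts]] <- negative_pairs(
      dm, dg[dg$class == "mRNA", ], sites, events, ts)
  }
  list(fpkm = fpkm, cpm = cpm, de_gene = de_gene, de_mirna = de_mirna,
       sites = sites, events = events, networks = networks,
       negative_pairs = dplyr::bind_rows(np))
}
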