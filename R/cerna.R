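#' Pearson correlation between two expression series
#'
#' Computed on log2(normalized value + 1e-6) over the within-tissue samples
#' (3 control + 3 treated). Returns NA (flagged undefined) when either
#' series is constant; such pairs are excluded from correlation filtering.
#'
#' @param expr_a,expr_b Numeric vectors of normalized abundances over the
#'   same samples.
#' @param pseudo Pseudo-count before the log.
#' @return Pearson r in [-1, 1], or NA for a constant series.
#' @export
correlate <- function(expr_a, expr_b, pseudo = 1e-6) {
  if (length(expr_a) != length(expr_b)) stop("sample mismatch between series")
  a <- log2(expr_a + pseudo); b <- log2(expr_b + pseudo)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = "pearson")
}

# Within-tissue log-scale expression rows for a set of features, taken from
# a wide normalized table; returns a features x samples matrix.
tissue_expr_matrix <- function(norm, feature_ids, tissue, design = NULL) {
  samp <- setdiff(names(norm), "feature_id")
  design <- design %||% sample_design(samp)
  cols <- design$sample_id[design$tissue == tissue]
  m <- as.matrix(norm[match(feature_ids, norm$feature_id), cols, drop = FALSE])
  rownames(m) <- feature_ids
  m
}

#' Negative-regulation miRNA-mRNA pairs
#'
#' One record per (DE miRNA, DE mRNA) predicted target pair with opposite DE
#' directions in the given tissue; the degradome flag is `Y` iff a cleavage
#' event exists for the pair.
#'
#' @param de_mirna,de_mrna [de_test()] results for the tissue.
#' @param target_sites Site tibble ([scan_all_targets()]), cleavage mode.
#' @param degradome_events Event tibble ([validate_sites()]).
#' @param tissue Tissue label carried into the records.
#' @return A tibble: `mirna_id`, `mirna_direction`, `transcript_id`,
#'   `transcript_direction`, `tissue`, `degradome_flag` (`Y`/`N`).
#' @export
negative_pairs <- function(de_mirna, de_mrna, target_sites, degradome_events,
                           tissue) {
  mi <- de_mirna[de_mirna$direction != "ns", c("feature_id", "direction")]
  mr <- de_mrna[de_mrna$direction != "ns", c("feature_id", "direction")]
  pairs <- target_sites[target_sites$mode == "cleavage",
                        c("mirna_id", "target_id")] |> dplyr::distinct()
  verified <- dplyr::distinct(degradome_events[, c("mirna_id", "transcript_id")])
  pairs |>
    dplyr::inner_join(mi, by = c(mirna_id = "feature_id")) |>
    dplyr::rename(mirna_direction = "direction") |>
    dplyr::inner_join(mr, by = c(target_id = "feature_id")) |>
    dplyr::rename(transcript_direction = "direction",
                  transcript_id = "target_id") |>
    dplyr::filter(.data$mirna_direction != .data$transcript_direction) |>
    dplyr::mutate(
      tissue = tissue,
      degradome_flag = ifelse(
        paste(.data$mirna_id, .data$transcript_id) %in%
          paste(verified$mirna_id, verified$transcript_id), "Y", "N")
    ) |>
    dplyr::select("mirna_id", "mirna_direction", "transcript_id",
                  "transcript_direction", "tissue", "degradome_flag")
}

#' Assemble the miRNA-centric ceRNA network for one tissue
#'
#' Nodes are differentially expressed features only. An edge miRNA -> ceRNA
#' is retained iff (a) a predicted target site exists (either mode), (b) the
#' miRNA-ceRNA Pearson correlation on log2(normalized + 1e-6) over the six
#' within-tissue samples is <= -`r_threshold`, and, when
#' `require_pair_positivity`, (c) at least one other retained ceRNA of the
#' same miRNA correlates with it at >= +`r_threshold` (the competing-pair
#' condition). Degradome-verified edges are flagged.
#'
#' @param de_gene_like [de_test()] result for mRNA/lncRNA/circRNA features
#'   (a `class` column must name each feature's class).
#' @param de_mirna [de_test()] result for miRNAs.
#' @param target_sites Site tibble ([scan_all_targets()]).
#' @param norm_gene Wide normalized (FPKM) table for gene-like features.
#' @param norm_mirna Wide normalized (CPM) table for miRNAs.
#' @param degradome_events Event tibble ([validate_sites()]).
#' @param tissue Tissue to build.
#' @param r_threshold Correlation threshold (default 0.7).
#' @param require_pair_positivity Apply condition (c) (default TRUE).
#' @return A `cerna_network` object: list with `nodes`, `edges`, `tissue`
#'   and `params`. Nodes carry class and DE direction; edges carry the
#'   correlation, targeting mode and degradome flag.
#' @export
build_network <- function(de_gene_like, de_mirna, target_sites, norm_gene,
                          norm_mirna, degradome_events, tissue,
                          r_threshold = 0.7, require_pair_positivity = TRUE) {
  de_g <- de_gene_like[de_gene_like$direction != "ns", ]
  de_m <- de_mirna[de_mirna$direction != "ns", ]
  relaxed <- isTRUE(attr(de_gene_like, "relaxed")) || isTRUE(attr(de_mirna, "relaxed"))
  params <- list(r_threshold = r_threshold,
                 require_pair_positivity = require_pair_positivity,
                 alpha = attr(de_gene_like, "alpha"), relaxed = relaxed)
  empty <- function() {
    structure(list(nodes = tibble::tibble(id = character(), type = character(),
                                          class = character(), direction = character()),
                   edges = tibble::tibble(mirna_id = character(), cerna_id = character(),
                                          cerna_class = character(), tissue = character(),
                                          r = numeric(), mode = character(),
                                          degradome_verified = logical()),
                   tissue = tissue, params = params),
              class = "cerna_network")
  }
  if (nrow(de_g) == 0 || nrow(de_m) == 0) {
    warning("empty DE set(s) in tissue ", tissue, "; returning empty network")
    return(empty())
  }
  cand <- target_sites |>
    dplyr::filter(.data$mirna_id %in% de_m$feature_id,
                  .data$target_id %in% de_g$feature_id) |>
    dplyr::group_by(.data$mirna_id, .data$target_id, .data$target_class) |>
    dplyr::summarise(mode = paste(sort(unique(.data$mode)), collapse = "+"),
                     .groups = "drop")
  if (nrow(cand) == 0) return(empty())

  gm <- tissue_expr_matrix(norm_gene, unique(cand$target_id), tissue)
  mm <- tissue_expr_matrix(norm_mirna, unique(cand$mirna_id), tissue)
  cand$r <- vapply(seq_len(nrow(cand)), function(i) {
    correlate(mm[cand$mirna_id[i], ], gm[cand$target_id[i], ])
  }, numeric(1))
  edges <- cand[!is.na(cand$r) & cand$r <= -r_threshold, ]

  if (require_pair_positivity && nrow(edges)) {
    keep <- logical(nrow(edges))
    for (i in seq_len(nrow(edges))) {
      sib <- edges[edges$mirna_id == edges$mirna_id[i] &
                     edges$target_id != edges$target_id[i], ]
      if (nrow(sib) == 0) next
      r_ab <- vapply(sib$target_id, function(b) {
        correlate(gm[edges$target_id[i], ], gm[b, ])
      }, numeric(1))
      keep[i] <- any(!is.na(r_ab) & r_ab >= r_threshold)
    }
    edges <- edges[keep, ]
  }

  verified <- paste(degradome_events$mirna_id, degradome_events$transcript_id)
  edges <- edges |>
    dplyr::transmute(
      mirna_id = .data$mirna_id, cerna_id = .data$target_id,
      cerna_class = .data$target_class, tissue = tissue, r = .data$r,
      mode = .data$mode,
      degradome_verified = paste(.data$mirna_id, .data$target_id) %in% verified
    )
  node_ids <- unique(c(edges$mirna_id, edges$cerna_id))
  de_all <- dplyr::bind_rows(
    tibble::tibble(id = de_m$feature_id, type = "miRNA", class = "miRNA",
                   direction = de_m$direction),
    tibble::tibble(id = de_g$feature_id, type = "ceRNA",
                   class = de_g$class %||% rep("mRNA", nrow(de_g)),
                   direction = de_g$direction)
  )
  nodes <- de_all[de_all$id %in% node_ids, ]
  structure(list(nodes = nodes, edges = edges, tissue = tissue, params = params),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("cerna_network (", x$tissue, "): ", nrow(x$nodes), " DE nodes, ",
      nrow(x$edges), " edges (", sum(x$edges$degradome_verified),
      " degradome-verified)\n", sep = "")
  invisible(x)
}

#' Convert a ceRNA network to an igraph object
#'
#' @param net A `cerna_network`.
#' @return An igraph graph with node attributes `type`, `class`,
#'   `direction` and edge attributes `r`, `mode`, `degradome_verified`,
#'   `tissue`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = net$edges[, c("mirna_id", "cerna_id", "r", "mode",
                      "degradome_verified", "tissue")],
    directed = TRUE,
    vertices = net$nodes
  )
}

#' Export a ceRNA network to GraphML or TSV
#'
#' @param net A `cerna_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"tsv"` (edge list).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    readr::write_tsv(net$edges, path)
  }
  invisible(path)
}

#' Read the packaged negative-pair reference table
#'
#' Loads the packaged TSV of printed negative-regulation DEmiRNA-mRNA pairs
#' (columns: miR_name, up/down, Transcript, up/down, Tissue, Degradome
#' Detection) and renames the columns to the package's canonical names.
#'
#' @param path Path to the TSV; defaults to the packaged fixture.
#' @return A tibble: `mirna_id`, `mirna_direction`, `transcript_id`,
#'   `transcript_direction`, `tissue`, `degradome_flag`.
#' @export
read_negative_pair_table <- function(path = system.file(
  "extdata", "table2_negative_pairs.tsv", package = "plantcerna")) {
  x <- readr::read_tsv(path, show_col_types = FALSE, name_repair = "minimal")
  stats::setNames(
    x, c("mirna_id", "mirna_direction", "transcript_id",
         "transcript_direction", "tissue", "degradome_flag"))
}

#' Marginal counts of a negative-pair table
#'
#' @param pairs A negative-pair tibble ([negative_pairs()] or
#'   [read_negative_pair_table()]).
#' @return A tibble with one row: `n_leaf`, `n_root`,
#'   `n_degradome_confirmed`.
#' @export
negative_pair_marginals <- function(pairs) {
  tibble::tibble(
    n_leaf = sum(pairs$tissue == "leaf"),
    n_root = sum(pairs$tissue == "root"),
    n_degradome_confirmed = sum(pairs$degradome_flag == "Y")
  )
}
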