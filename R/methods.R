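#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ceRNA network into its edge table
#'
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return The edge tibble (`mirna_id`, `cerna_id`, `cerna_class`,
#'   `tissue`, `r`, `mode`, `degradome_verified`).
#' @export
tidy.cerna_network <- function(x, ...) x$edges

#' One-row summary of a ceRNA network
#'
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return A one-row tibble: tissue, node/edge counts by class, number of
#'   degradome-verified edges, and the filter parameters used.
#' @export
glance.cerna_network <- function(x, ...) {
  tibble::tibble(
    tissue = x$tissue,
    n_nodes = nrow(x$nodes),
    n_mirna = sum(x$nodes$type == "miRNA"),
    n_mrna = sum(x$nodes$class == "mRNA"),
    n_lncrna = sum(x$nodes$class == "lncRNA"),
    n_circrna = sum(x$nodes$class == "circRNA"),
    n_edges = nrow(x$edges),
    n_degradome_verified = sum(x$edges$degradome_verified),
    r_threshold = x$params$r_threshold,
    relaxed = isTRUE(x$params$relaxed)
  )
}

#' One-row summary of a synthetic study
#'
#' @param x A `cerna_study`.
#' @param ... Unused.
#' @return A one-row tibble of feature and planted-truth counts.
#' @export
glance.cerna_study <- function(x, ...) {
  tibble::tibble(
    n_mrna = sum(x$transcripts$biotype == "mRNA"),
    n_lncrna = sum(x$transcripts$biotype == "lncRNA"),
    n_circrna = nrow(x$circs),
    n_mirna = nrow(x$mirnas),
    n_planted_cleavage = nrow(x$truth$planted_cleavage),
    n_planted_mimic = nrow(x$truth$planted_mimic),
    n_planted_triplets = nrow(x$truth$planted_triplets),
    rng_seed = x$truth$rng_seed
  )
}

#' @export
print.cerna_study <- function(x, ...) {
  g <- glance(x)
  cat("cerna_study (seed ", g$rng_seed, "): ", g$n_mrna, " mRNA, ",
      g$n_lncrna, " lncRNA, ", g$n_circrna, " circRNA, ", g$n_mirna,
      " miRNA; ", g$n_planted_cleavage, " planted cleavage sites, ",
      g$n_planted_mimic, " mimic sites, ", g$n_planted_triplets,
      " ceRNA triplets\n", sep = "")
  invisible(x)
}

#' Plot a ceRNA network
#'
#' Bipartite layout with miRNA hubs; node colour encodes the DE direction
#' (up = red, down = green), node shape the feature class, and solid edges
#' mark degradome-verified regulation.
#'
#' @param object A `cerna_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_network <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "empty network") +
             ggplot2::theme_void())
  }
  g <- as_igraph(object)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
    class = igraph::V(g)$class, direction = igraph::V(g)$direction
  )
  edges <- tidy(object) |>
    dplyr::left_join(nodes[, c("id", "x", "y")], by = c(mirna_id = "id")) |>
    dplyr::left_join(nodes[, c("id", "x", "y")], by = c(cerna_id = "id"),
                     suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$degradome_verified),
      colour = "grey50") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$direction,
                   shape = .data$class), size = 3) +
    ggplot2::scale_colour_manual(values = c(up = "red3", down = "green4")) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                                   name = "degradome") +
    ggplot2::labs(title = paste0("ceRNA network (", object$tissue, ")")) +
    ggplot2::theme_void()
}

#' Volcano plot of a differential-expression result
#'
#' @param de A [de_test()] result.
#' @param ... Unused.
#' @return A ggplot object of log2FC versus -log10 p, coloured by call.
#' @export
plot_volcano <- function(de, ...) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2FC,
                                   y = -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "red3", down = "green4",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (st/ck)", y = "-log10 p") +
    ggplot2::theme_minimal()
}
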