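test_that("correlate handles exact, inverse and degenerate series", {
  x <- c(1, 2, 4, 8, 16, 32)
  expect_equal(correlate(x, x), 1)
  expect_equal(correlate(x, rev(x)), -1)
  expect_true(is.na(correlate(rep(3, 6), x)))
  expect_error(correlate(x, x[1:3]), "mismatch")
})

test_that("negative_pairs emits opposite-direction target pairs with degradome flags", {
  de_m <- tibble::tibble(feature_id = c("mirUP", "mirDN", "mirNS"),
                         direction = c("up", "down", "ns"))
  de_g <- tibble::tibble(feature_id = c("tDN", "tUP", "tUP2"),
                         direction = c("down", "up", "up"))
  sites <- tibble::tibble(
    mirna_id = c("mirUP", "mirUP", "mirDN", "mirNS"),
    target_id = c("tDN", "tUP", "tUP2", "tDN"),
    mode = "cleavage")
  events <- tibble::tibble(mirna_id = "mirUP", transcript_id = "tDN")
  np <- negative_pairs(de_m, de_g, sites, events, "root")
  expect_equal(nrow(np), 2)  # mirUP+tUP share direction; mirNS is not DE
  expect_equal(np$degradome_flag[np$mirna_id == "mirUP"], "Y")
  expect_equal(np$degradome_flag[np$mirna_id == "mirDN"], "N")
  expect_true(all(np$mirna_direction != np$transcript_direction))
})

test_that("the packaged negative-pair table reads with canonical columns", {
  t2 <- read_negative_pair_table()
  expect_equal(nrow(t2), 33)
  expect_named(t2, c("mirna_id", "mirna_direction", "transcript_id",
                     "transcript_direction", "tissue", "degradome_flag"))
  expect_true(all(t2$mirna_direction != t2$transcript_direction))
})

test_that("network edges only connect DE nodes and respect the r filter", {
  st <- get_study(1)
  res <- get_pipeline(1)
  for (ts in c("leaf", "root")) {
    net <- res$networks[[ts]]
    de_ids <- c(
      res$de_gene[[ts]]$feature_id[res$de_gene[[ts]]$direction != "ns"],
      res$de_mirna[[ts]]$feature_id[res$de_mirna[[ts]]$direction != "ns"])
    expect_true(all(net$edges$mirna_id %in% de_ids))
    expect_true(all(net$edges$cerna_id %in% de_ids))
    expect_true(all(net$edges$r <= -net$params$r_threshold))
    expect_true(all(net$nodes$id %in% de_ids))
  }
})

test_that("edge count is monotone non-increasing in the correlation threshold", {
  st <- get_study(1)
  res <- get_pipeline(1)
  ng <- normalize_counts(st$counts); nm <- normalize_counts(st$mirna_counts)
  dg <- res$de_gene$root; dm <- res$de_mirna$root
  n_edges <- vapply(c(0.5, 0.7, 0.9, 0.99), function(thr) {
    nrow(build_network(dg, dm, res$sites, ng, nm, res$events, "root",
                       r_threshold = thr)$edges)
  }, integer(1))
  expect_true(all(diff(n_edges) <= 0))
})

test_that("empty DE sets yield an empty network with a warning, not an error", {
  de0 <- tibble::tibble(feature_id = character(), direction = character(),
                        class = character())
  expect_warning(
    net <- build_network(de0, de0, tibble::tibble(), tibble::tibble(),
                         tibble::tibble(), tibble::tibble(), "leaf"),
    "empty")
  expect_s3_class(net, "cerna_network")
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$nodes), 0)
})

test_that("networks export to GraphML and TSV and round-trip attributes", {
  res <- get_pipeline(1)
  net <- res$networks$root
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$class, net$nodes$class)
  expect_equal(sort(igraph::E(g)$r), sort(net$edges$r), tolerance = 1e-9)

  ft <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, ft, "tsv")
  back <- readr::read_tsv(ft, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(net$edges))

  # an empty network still writes a parseable GraphML document
  empty <- suppressWarnings(build_network(
    tibble::tibble(feature_id = character(), direction = character(),
                   class = character()),
    tibble::tibble(feature_id = character(), direction = character()),
    tibble::tibble(), tibble::tibble(), tibble::tibble(), tibble::tibble(),
    "leaf"))
  fe <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, fe, "graphml")
  ge <- igraph::read_graph(fe, format = "graphml")
  expect_equal(igraph::gorder(ge), 0)
})

test_that("tidy, glance and autoplot summarize networks", {
  res <- get_pipeline(1)
  net <- res$networks$root
  expect_equal(tidy(net), net$edges)
  gl <- glance(net)
  expect_equal(gl$n_edges, nrow(net$edges))
  expect_equal(gl$tissue, "root")
  expect_s3_class(autoplot(net), "ggplot")
  expect_s3_class(plot_volcano(res$de_gene$root), "ggplot")
})

test_that("relaxed leaf mode propagates into network metadata", {
  st <- get_study(1)
  res <- run_cerna_pipeline(st, relaxed_tissues = "leaf")
  expect_true(res$networks$leaf$params$relaxed)
  expect_false(res$networks$root$params$relaxed)
  strict <- get_pipeline(1)
  n_strict <- nrow(strict$de_gene$leaf[strict$de_gene$leaf$direction != "ns", ])
  n_rel <- nrow(res$de_gene$leaf[res$de_gene$leaf$direction != "ns", ])
  expect_gte(n_rel, n_strict)
})
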