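test_that("reference generation is deterministic and honours feature contracts", {
  r1 <- generate_reference(5, 3, 3, seed = 1)
  r2 <- generate_reference(5, 3, 3, seed = 1)
  expect_identical(r1, r2)
  r3 <- generate_reference(5, 3, 3, seed = 2)
  expect_false(identical(r1$genome$sequence, r3$genome$sequence))

  lnc <- r1$transcripts[r1$transcripts$biotype == "lncRNA", ]
  expect_true(all(nchar(lnc$sequence) >= 200))
  expect_true(all(vapply(lnc$sequence, longest_orf, integer(1)) < 300))
  mr <- r1$transcripts[r1$transcripts$biotype == "mRNA", ]
  expect_true(all(vapply(mr$sequence, longest_orf, integer(1)) >= 300))
  expect_setequal(unique(r1$circs$locus_type_truth),
                  c("exon", "intron", "intergenic"))
  expect_error(plant_mirna_sites(r1, n_mirna = 50), "placement")
})

test_that("generator circRNA locus types agree with the annotation classifier", {
  r <- generate_reference(8, 4, 6, seed = 3)
  got <- classify_circrna(r$circs, r$transcripts[r$transcripts$biotype == "mRNA", ])
  expect_equal(got$locus_type, r$circs$locus_type_truth)
})

test_that("planted sites are recoverable and miRNA 5' composition is enforced", {
  st <- get_study(1)
  m <- st$mirnas
  expect_true(all(m$five_prime_nt[m$length == 21] == "U"))
  expect_true(all(m$five_prime_nt[m$length == 24] == "A"))
  expect_true(all(m$length >= 18 & m$length <= 25))

  # every planted cleavage site is found by the scanner at its position
  tr <- st$truth$planted_cleavage
  for (i in seq_len(nrow(tr))) {
    seq_i <- st$transcripts$sequence[st$transcripts$transcript_id ==
                                       tr$transcript_id[i]]
    hits <- scan_transcript(m$sequence[m$mirna_id == tr$mirna_id[i]], seq_i,
                            mode = "cleavage")
    expect_true(tr$cleavage_pos[i] %in% hits$cleavage_pos)
  }

  # every planted mimic is accepted by the rule checker at its window
  mi <- st$truth$planted_mimic
  for (i in seq_len(nrow(mi))) {
    host <- mi$ncrna_id[i]
    seq_i <- if (host %in% st$circs$circ_id) {
      st$circs$sequence[st$circs$circ_id == host]
    } else {
      st$transcripts$sequence[st$transcripts$transcript_id == host]
    }
    L <- m$length[m$mirna_id == mi$mirna_id[i]]
    win <- substr(seq_i, mi$site_start[i], mi$site_start[i] + L + mi$bulge_len[i] - 1)
    d <- align_duplex(m$sequence[m$mirna_id == mi$mirna_id[i]], win, "mimic")
    expect_true(check_mimic(d)$accept)
  }

  # planted coordinates lie within their transcripts
  lens <- st$feature_lengths
  expect_true(all(tr$cleavage_pos >= 1 &
                    tr$cleavage_pos <= lens[tr$transcript_id]))
})

test_that("simulated counts are Poisson in the zero-dispersion limit", {
  ids <- sprintf("f%03d", 1:300)
  cc <- simulate_counts(ids, empty_planted_de, dispersion = 0, seed = 8)
  m <- as.matrix(cc[, -1])
  # across 12 iid Poisson draws per feature, var/mean concentrates near 1
  ratio <- apply(m, 1, stats::var) / rowMeans(m)
  expect_lt(abs(mean(ratio) - 1), 0.1)
  expect_error(simulate_counts(ids, empty_planted_de, dispersion = -1),
               "dispersion")
})

test_that("planted triplets carry the constructed correlation sign structure", {
  st <- get_study(1)
  ng <- normalize_counts(st$counts)
  nm <- normalize_counts(st$mirna_counts)
  tt <- st$truth$planted_triplets
  for (i in seq_len(nrow(tt))) {
    samp <- paste(tt$tissue[i], rep(c("ck", "st"), each = 3), 1:3, sep = "_")
    a <- as.numeric(ng[ng$feature_id == tt$cerna_a[i], samp])
    b <- as.numeric(ng[ng$feature_id == tt$cerna_b[i], samp])
    mi <- as.numeric(nm[nm$feature_id == tt$mirna_id[i], samp])
    expect_gt(correlate(a, b), 0)
    expect_lt(correlate(mi, a), 0)
    expect_lt(correlate(mi, b), 0)
  }
})

test_that("degradome simulation plants peaks with the intended categories", {
  pc <- tibble::tibble(mirna_id = c("m1", "m2", "m3"),
                       transcript_id = c("t1", "t2", "t2"),
                       site_start = c(1L, 1L, 30L),
                       cleavage_pos = c(12L, 12L, 41L), n_mut = 0L)
  lens <- c(t1 = 100, t2 = 100)
  # isolated peak with no background: unique maximum, category 0
  d0 <- simulate_degradome(pc[1, ], lens["t1"], peak_reads = 50,
                           background_rate = 0, seed = 1)
  expect_equal(d0$truth$intended_category, 0L)
  expect_equal(d0$profile$count, 50)
  # single-read peak: category 4
  d4 <- simulate_degradome(pc[1, ], lens["t1"], peak_reads = 1,
                           background_rate = 0, seed = 1)
  expect_equal(d4$truth$intended_category, 4L)
  # two equal peaks on one transcript: shared maximum, both category 1
  d1 <- simulate_degradome(pc[2:3, ], lens["t2"], peak_reads = 50,
                           background_rate = 0, seed = 1)
  expect_equal(d1$truth$intended_category, c(1L, 1L))
  expect_error(simulate_degradome(pc, lens, peak_reads = 0), "peak_reads")
})

test_that("study simulation and on-disk serialization are deterministic", {
  s1 <- simulate_cerna_study(seed = 9, n_genes = 6, n_lncrna = 3, n_circrna = 3,
                             n_mirna = 4, n_triplets = 2)
  s2 <- simulate_cerna_study(seed = 9, n_genes = 6, n_lncrna = 3, n_circrna = 3,
                             n_mirna = 4, n_triplets = 2)
  expect_identical(s1[setdiff(names(s1), "truth")],
                   s2[setdiff(names(s2), "truth")])
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
  # the emitted formats read back through the io layer
  g <- read_fasta(file.path(d1, "genome.fa"))
  expect_equal(g$sequence, s1$genome$sequence)
  tx <- read_gene_models(file.path(d1, "transcripts.gff3"))
  expect_setequal(tx$transcript_id, s1$transcripts$transcript_id)
  cc <- read_count_table(file.path(d1, "counts_gene.tsv"))
  expect_equal(as.data.frame(cc), as.data.frame(s1$counts))
})
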