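test_that("lncRNA identification applies length, overlap and coding filters", {
  set.seed(9)
  known <- make_tx("m1", "chr1", "+", cbind(1000, 1500), "mRNA")
  cand <- dplyr::bind_rows(
    make_tx("short", "chr1", "+", cbind(5000, 5149),
            sequence = rand_rna(150)),
    make_tx("overlaps", "chr1", "+", cbind(1400, 1899),
            sequence = rand_rna(500)),
    make_tx("antisense", "chr1", "-", cbind(1400, 1899),
            sequence = rand_rna(500)),
    make_tx("good", "chr1", "+", cbind(7000, 7499),
            sequence = paste0(strrep("AC", 100),
                              "AUG", strrep("GCA", 29), "UAA",
                              strrep("CU", 100))),
    make_tx("coding", "chr1", "+", cbind(9000, 9499),
            sequence = paste0("AUG", strrep(paste0("GC", sample(c("A","C","G","U"),1)), 120), "UAA"))
  )
  res <- identify_lncrna(cand, known)
  keep <- res$transcript_id[res$retained]
  expect_false("short" %in% keep)       # < 200 nt
  expect_false("overlaps" %in% keep)    # same-strand exonic overlap
  expect_true("antisense" %in% keep)    # opposite strand overlap is retained
  expect_true("good" %in% keep)         # 500 nt, ORF 90 nt
  expect_false("coding" %in% keep)      # ORF >= 300 nt
  # invariants: retained set disjoint from mRNA ids, all >= 200 nt
  expect_length(intersect(keep, known$transcript_id), 0)
  expect_true(all(nchar(res$sequence[res$retained]) >= 200))
})

test_that("identify_lncrna honours precomputed coding calls", {
  cand <- make_tx("x", "chr1", "+", cbind(1, 500), sequence = rand_rna(500))
  known <- make_tx("m1", "chr2", "+", cbind(1, 100), "mRNA")
  res <- identify_lncrna(cand, known,
                         coding_scores = tibble::tibble(transcript_id = "x",
                                                        coding = TRUE))
  expect_false(res$retained)
})

test_that("circRNA locus types are exhaustive and exclusive", {
  gm <- make_tx("t1", "chr1", "+", cbind(c(100, 300), c(200, 400)), "mRNA")
  circs <- tibble::tibble(
    circ_id = c("exonic", "intronic", "intergenic", "antisense"),
    chrom = "chr1",
    start = c(150L, 210L, 5000L, 150L),
    end = c(180L, 290L, 5100L, 180L),
    strand = c("+", "+", "+", "-")
  )
  r <- classify_circrna(circs, gm)
  expect_equal(r$locus_type,
               c("exon", "intron", "intergenic", "intergenic"))
  expect_true(all(r$locus_type %in% c("exon", "intron", "intergenic")))
  expect_equal(sum(is.na(r$locus_type)), 0)
})

test_that("cis-target assignment honours the 100-kb window and overlap distance", {
  lnc <- make_tx("L", "chr1", "+", cbind(200000, 201000), "lncRNA")
  genes <- dplyr::bind_rows(
    make_tx("near.t1", "chr1", "+", cbind(150000, 151000), gene_id = "near"),
    make_tx("far.t1", "chr1", "+", cbind(10000, 11000), gene_id = "far"),
    make_tx("ov.t1", "chr1", "-", cbind(200500, 202000), gene_id = "ov")
  )
  cp <- assign_cis_targets(lnc, genes)
  expect_setequal(cp$gene_id, c("near", "ov"))
  expect_equal(cp$distance[cp$gene_id == "ov"], 0L)
  expect_true(all(abs(cp$signed_distance) <= 100000))
})

test_that("cis-target assignment agrees with an all-pairs brute-force scan", {
  set.seed(77)
  for (rep in 1:5) {
    n_l <- 10; n_g <- 15
    mk <- function(ids, prefix) {
      purrr::map_dfr(ids, function(i) {
        chrom <- sample(c("chr1", "chr2"), 1)
        st <- sample(1:400000, 1)
        make_tx(paste0(prefix, i), chrom, sample(c("+", "-"), 1),
                cbind(st, st + sample(200:2000, 1)))
      })
    }
    lncs <- mk(seq_len(n_l), "L"); genes <- mk(seq_len(n_g), "G")
    got <- assign_cis_targets(lncs, genes, window = 100000)
    # independent oracle: gap = max(0, max(starts) - min(ends) - 1)
    want <- list()
    for (i in seq_len(n_l)) for (j in seq_len(n_g)) {
      le <- lncs$exons[[i]]; ge <- genes$exons[[j]]
      if (lncs$chrom[i] != genes$chrom[j]) next
      gap <- max(0, max(min(le$start), min(ge$start)) -
                   min(max(le$end), max(ge$end)) - 1)
      if (gap <= 100000) {
        want[[length(want) + 1]] <- paste(lncs$transcript_id[i],
                                          genes$gene_id[j], gap)
      }
    }
    expect_setequal(paste(got$lncrna_id, got$gene_id, got$distance),
                    unlist(want))
  }
})

test_that("hairpin_check passes perfect stems and fails unfoldable windows", {
  set.seed(13)
  arm <- rand_rna(60)
  w <- paste0(arm, "GAAA", revcomp(arm, out = "rna"))
  expect_true(hairpin_check(w, 10, 21))
  expect_false(hairpin_check(strrep("A", 421), 201, 21))
  expect_false(hairpin_check(rand_rna(40), 5, 21))  # too short to fold
  # mature may sit on the 3' arm as well
  expect_true(hairpin_check(w, nchar(w) - 30, 21))
})

test_that("random windows rarely pass the hairpin heuristic", {
  set.seed(21)
  passes <- vapply(1:200, function(i) {
    hairpin_check(rand_rna(421), 201, 21)
  }, logical(1))
  expect_lt(mean(passes), 0.05)
})

test_that("catalogue_mirna partitions reads into known, novel and dropped", {
  set.seed(3)
  # genome carrying a perfect precursor: arm + loop + revcomp arm
  mature <- rand_rna(21)
  arm <- paste0(rand_rna(20), mature, rand_rna(20))
  precursor <- paste0(arm, "GUUUAC", revcomp(arm, out = "rna"))
  genome <- tibble::tibble(
    id = "chr1",
    sequence = paste0(rna_to_dna(paste0(rand_rna(300), precursor)),
                      paste(rep("ACGT", 75), collapse = "")))
  ref <- tibble::tibble(id = "ref-mir1", sequence = rand_rna(21))
  mm2 <- ref$sequence
  substr(mm2, 3, 3) <- setdiff(c("A", "C", "G", "U"), substr(mm2, 3, 3))[1]
  reads <- tibble::tibble(
    read_id = c("exact", "twomm", "novel", "lost", "tiny"),
    sequence = c(ref$sequence, mm2, mature, rand_rna(21), rand_rna(10)),
    count = 1
  )
  cat <- catalogue_mirna(reads, ref, genome)
  expect_equal(attr(cat, "n_length_filtered"), 1L)
  expect_equal(cat$status[cat$read_id == "exact"], "known")
  expect_equal(cat$n_mismatch[cat$read_id == "exact"], 0L)
  expect_equal(cat$status[cat$read_id == "twomm"], "known")
  expect_equal(cat$status[cat$read_id == "novel"], "novel")
  expect_true(cat$hairpin_pass[cat$read_id == "novel"])
  expect_equal(cat$status[cat$read_id == "lost"], "dropped")
  expect_true(all(cat$status %in% c("known", "novel", "dropped")))

  s <- mirna_summary(cat)
  expect_equal(sum(s$length_distribution$n), 3)
})
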