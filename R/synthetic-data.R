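rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# Random mRNA-like spliced sequence: 5' UTR + (ATG + non-stop codons + stop)
# + 3' UTR, so the longest forward ORF is at least 3 * (n_codons + 2) nt.
random_mrna_spliced <- function() {
  utr5 <- rand_dna(sample(30:90, 1))
  n_codons <- sample(100:180, 1)
  orf <- paste0("ATG", paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE),
                             collapse = ""), "TAA")
  utr3_len <- sample(80:160, 1)
  list(seq = paste0(utr5, orf, rand_dna(utr3_len)), utr3_len = utr3_len)
}

# Random lncRNA-like sequence: 200-1000 nt with longest ORF < 300 nt.
random_lncrna_spliced <- function() {
  repeat {
    s <- rand_dna(sample(200:1000, 1))
    if (longest_orf(s) < 300) return(s)
  }
}

# Append a transcript to a chromosome under construction. `spliced` is the
# transcript 5'->3' DNA; exons are laid left-to-right for '+' and
# right-to-left (reverse-complemented chunks) for '-'.
append_transcript <- function(chrom_chars, spliced, n_exons, strand,
                              last_block = NULL) {
  len <- nchar(spliced)
  cuts <- if (n_exons > 1) {
    hi <- if (is.null(last_block)) len - 10 else len - last_block - 10
    sort(sample(seq(30, max(31, hi)), n_exons - 1))
  } else integer()
  bounds <- c(0, cuts, len)
  chunks <- substring(spliced, bounds[-length(bounds)] + 1, bounds[-1])
  introns <- vapply(seq_len(n_exons - 1), function(i) rand_dna(sample(60:250, 1)),
                    character(1))
  genomic_chunks <- if (strand == "+") chunks else
    vapply(rev(chunks), revcomp, character(1), out = "dna", USE.NAMES = FALSE)
  pieces <- character(0)
  for (i in seq_len(n_exons)) {
    pieces <- c(pieces, genomic_chunks[i],
                if (i < n_exons) introns[i] else NULL)
  }
  cursor <- length(chrom_chars)
  ex_start <- integer(n_exons); ex_end <- integer(n_exons)
  pos <- cursor
  j <- 0
  for (i in seq_along(pieces)) {
    w <- nchar(pieces[i])
    if (i %% 2 == 1) { j <- j + 1; ex_start[j] <- pos + 1; ex_end[j] <- pos + w }
    pos <- pos + w
  }
  list(chrom_chars = c(chrom_chars, strsplit(paste(pieces, collapse = ""), "")[[1]]),
       exons = tibble::tibble(start = ex_start, end = ex_end))
}

#' Generate a synthetic reference (genome, gene models, circRNAs)
#'
#' Builds a random genome carrying mRNAs (forward ORFs >= 300 nt), lncRNAs
#' (200-1000 nt, longest ORF < 300 nt so the coding filter is exercised on
#' both sides) and circRNAs of all three locus types (exonic, intronic,
#' intergenic). Deterministic under `seed`.
#'
#' @param n_genes,n_lncrna,n_circrna Feature counts (n_genes >= 1;
#'   n_circrna >= 3 gives all three locus types).
#' @param seed RNG seed.
#' @return A list with `genome` (tibble `id`, `sequence`), `transcripts`
#'   (gene-model tibble with spliced `sequence` in RNA space and, for
#'   mRNAs, the 3' UTR length) and `circs` (tibble with coordinates,
#'   generator-assigned `locus_type_truth` and `sequence`).
#' @export
generate_reference <- function(n_genes = 30, n_lncrna = 15, n_circrna = 5,
                               seed = 1) {
  stopifnot(n_genes >= 1)
  with_seed(seed, {
    chroms <- list(chr1 = character(0), chr2 = character(0))
    tx <- list()
    add_feature <- function(kind, id, gene_id) {
      ci <- (length(tx) %% 2) + 1
      chroms[[ci]] <<- c(chroms[[ci]], strsplit(rand_dna(sample(1500:4000, 1)), "")[[1]])
      strand <- sample(c("+", "-"), 1)
      if (kind == "mRNA") {
        sp <- random_mrna_spliced()
        n_exons <- if (id == "mrna001.t1") 2L else sample(1:3, 1)
        placed <- append_transcript(chroms[[ci]], sp$seq, n_exons, strand,
                                    last_block = sp$utr3_len)
        utr3 <- sp$utr3_len
      } else {
        s <- random_lncrna_spliced()
        n_exons <- sample(1:2, 1)
        placed <- append_transcript(chroms[[ci]], s, n_exons, strand)
        utr3 <- NA_integer_
      }
      chroms[[ci]] <<- placed$chrom_chars
      tx[[length(tx) + 1]] <<- tibble::tibble(
        transcript_id = id, gene_id = gene_id, chrom = names(chroms)[ci],
        strand = strand, biotype = kind, exons = list(placed$exons),
        utr3_len = utr3
      )
    }
    for (i in seq_len(n_genes)) {
      add_feature("mRNA", sprintf("mrna%03d.t1", i), sprintf("gene%03d", i))
    }
    for (i in seq_len(n_lncrna)) {
      add_feature("lncRNA", sprintf("lnc%03d", i), sprintf("lncg%03d", i))
    }
    transcripts <- dplyr::bind_rows(tx)

    # circRNAs: cycle exon / intron / intergenic locus types
    circ <- list()
    types <- rep(c("exon", "intron", "intergenic"), length.out = n_circrna)
    mrna_tx <- transcripts[transcripts$biotype == "mRNA", ]
    multi <- mrna_tx[vapply(mrna_tx$exons, nrow, integer(1)) > 1, ]
    for (i in seq_len(n_circrna)) {
      ty <- types[i]
      if (ty == "exon") {
        h <- mrna_tx[sample(nrow(mrna_tx), 1), ]
        ex <- h$exons[[1]]
        e <- ex[which.max(ex$end - ex$start), ]
        w <- min(sample(80:200, 1), e$end - e$start + 1)
        st <- sample(seq(e$start, e$end - w + 1), 1)
        circ[[i]] <- tibble::tibble(circ_id = sprintf("circ%03d", i),
                                    chrom = h$chrom, start = st, end = st + w - 1,
                                    strand = h$strand, locus_type_truth = "exon")
      } else if (ty == "intron" && nrow(multi) > 0) {
        h <- multi[sample(nrow(multi), 1), ]
        ex <- h$exons[[1]]
        gap_start <- ex$end[1] + 1; gap_end <- ex$start[2] - 1
        w <- min(sample(50:150, 1), gap_end - gap_start + 1)
        st <- sample(seq(gap_start, gap_end - w + 1), 1)
        circ[[i]] <- tibble::tibble(circ_id = sprintf("circ%03d", i),
                                    chrom = h$chrom, start = st, end = st + w - 1,
                                    strand = h$strand, locus_type_truth = "intron")
      } else {
        ci <- (i %% 2) + 1
        w <- sample(120:300, 1)
        chroms[[ci]] <- c(chroms[[ci]], strsplit(rand_dna(5000 + w), "")[[1]])
        en <- length(chroms[[ci]]) - 100
        circ[[i]] <- tibble::tibble(circ_id = sprintf("circ%03d", i),
                                    chrom = names(chroms)[ci], start = en - w + 1,
                                    end = en, strand = sample(c("+", "-"), 1),
                                    locus_type_truth = "intergenic")
      }
    }
    circs <- dplyr::bind_rows(circ)
    # trailing intergenic tail so nothing abuts a chromosome end
    for (ci in seq_along(chroms)) {
      chroms[[ci]] <- c(chroms[[ci]], strsplit(rand_dna(1000), "")[[1]])
    }
    genome <- tibble::tibble(id = names(chroms),
                             sequence = unname(vapply(chroms, paste, character(1),
                                                      collapse = "")))
    transcripts <- add_spliced_sequences(transcripts, genome)
    transcripts$n_exons <- vapply(transcripts$exons, nrow, integer(1))
    transcripts$length <- nchar(transcripts$sequence)
    circs$sequence <- vapply(seq_len(nrow(circs)), function(i) {
      s <- substr(genome$sequence[match(circs$chrom[i], genome$id)],
                  circs$start[i], circs$end[i])
      if (circs$strand[i] == "-") s <- revcomp(s, out = "dna")
      dna_to_rna(s)
    }, character(1))
    list(genome = genome, transcripts = transcripts, circs = circs)
  })
}

# Genomic position of each transcript-space position (1-based, 5'->3').
tx_to_genome_pos <- function(transcript_row, tx_positions) {
  ex <- transcript_row$exons[[1]]
  if (transcript_row$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  lens <- ex$end - ex$start + 1L
  cum <- cumsum(lens)
  vapply(tx_positions, function(p) {
    i <- which(p <= cum)[1]
    off <- p - (if (i == 1) 0L else cum[i - 1]) - 1L
    if (transcript_row$strand == "+") ex$start[i] + off else ex$end[i] - off
  }, numeric(1))
}

# Write an RNA-space subsequence into the genome at the positions backing a
# transcript interval (complemented for minus-strand transcripts).
write_site_to_genome <- function(genome_chars, transcript_row, tx_start, site_rna) {
  dna <- up_chars(rna_to_dna(site_rna))
  gpos <- tx_to_genome_pos(transcript_row, tx_start + seq_along(dna) - 1L)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- transcript_row$chrom
  if (transcript_row$strand == "+") {
    genome_chars[[ch]][gpos] <- dna
  } else {
    genome_chars[[ch]][gpos] <- unname(comp[dna])
  }
  genome_chars
}

#' Plant miRNA cleavage and target-mimic sites into a synthetic reference
#'
#' Emits mature miRNAs (21-mers starting with U and 24-mers starting with A,
#' the two canonical DICER-LIKE product classes) and plants, for each, one
#' cleavage site in an mRNA 3' UTR (the exact reverse complement of the
#' miRNA with up to `max_mut` mismatches outside positions 10-11) and, for
#' the first `n_triplets` miRNAs, one target-mimic site (reverse complement
#' with a 1-4 nt bulge inserted between the bases paired to miRNA positions
#' 10-11) in a lncRNA or intergenic circRNA, forming planted ceRNA triplets.
#' Differential expression is planted so that each triplet's miRNA moves
#' opposite to its two ceRNAs under treatment, inducing the negative
#' miRNA-ceRNA and positive ceRNA-ceRNA correlations the network filter
#' expects.
#'
#' @param ref A [generate_reference()] result (modified in the returned copy).
#' @param n_mirna Number of miRNAs (at most the number of mRNAs).
#' @param seed RNG seed.
#' @param n_triplets Number of planted ceRNA triplets.
#' @param max_mut Maximum mismatches introduced into a cleavage site.
#' @param de_log2fc Magnitude of planted log2 fold changes.
#' @return A list: updated `ref`, `mirnas` tibble and `truth` (planted_de,
#'   planted_cleavage, planted_mimic, planted_triplets).
#' @export
plant_mirna_sites <- function(ref, n_mirna = 20, seed = 1, n_triplets = 8,
                              max_mut = 1, de_log2fc = 2, trip_log2fc = 4) {
  mrna <- ref$transcripts[ref$transcripts$biotype == "mRNA", ]
  lnc <- ref$transcripts[ref$transcripts$biotype == "lncRNA", ]
  if (n_mirna > nrow(mrna)) stop("placement error: need at least one mRNA per miRNA")
  with_seed(seed, {
    genome_chars <- lapply(stats::setNames(ref$genome$sequence, ref$genome$id),
                           function(s) up_chars(s))
    mirnas <- tibble::tibble(
      mirna_id = sprintf("mir%03d", seq_len(n_mirna)),
      length = rep(c(21L, 24L), length.out = n_mirna)
    )
    mirnas$sequence <- vapply(seq_len(n_mirna), function(i) {
      L <- mirnas$length[i]
      first <- if (L == 21L) "U" else "A"
      paste0(first, dna_to_rna(rand_dna(L - 1)))
    }, character(1))
    mirnas$five_prime_nt <- substr(mirnas$sequence, 1, 1)

    # --- cleavage sites: one per miRNA, inside an mRNA 3' UTR ---
    cleavage <- list()
    for (i in seq_len(n_mirna)) {
      t <- mrna[i, ]
      L <- mirnas$length[i]
      site <- revcomp(mirnas$sequence[i], out = "rna")
      n_mut <- sample(0:max_mut, 1)
      if (n_mut > 0) {
        # mutate target bases paired to non-scissile miRNA positions; setting
        # the target base equal to the miRNA base always yields a mismatch
        mpos <- sample(setdiff(seq_len(L), 10:11), n_mut)
        site_ch <- up_chars(site)
        m_ch <- up_chars(mirnas$sequence[i])
        site_ch[L - mpos + 1] <- m_ch[mpos]
        site <- paste(site_ch, collapse = "")
      }
      utr3_start <- t$length - t$utr3_len + 1L
      start <- sample(seq(utr3_start, t$length - L + 1L), 1)
      genome_chars <- write_site_to_genome(genome_chars, t, start, site)
      cleavage[[i]] <- tibble::tibble(
        mirna_id = mirnas$mirna_id[i], transcript_id = t$transcript_id,
        site_start = start, cleavage_pos = start + L - 10L, n_mut = n_mut
      )
    }
    planted_cleavage <- dplyr::bind_rows(cleavage)

    # --- mimic sites: one per triplet miRNA, in a lncRNA (or one circRNA) ---
    inter_circ <- ref$circs[ref$circs$locus_type_truth == "intergenic", ]
    mimic <- list()
    for (i in seq_len(n_triplets)) {
      L <- mirnas$length[i]
      b <- sample(1:4, 1)
      rc <- up_chars(revcomp(mirnas$sequence[i], out = "rna"))
      site <- paste(c(rc[1:(L - 10)], up_chars(dna_to_rna(rand_dna(b))),
                      rc[(L - 9):L]), collapse = "")
      use_circ <- i == n_triplets && nrow(inter_circ) > 0
      if (use_circ) {
        host <- inter_circ[1, ]
        host_id <- host$circ_id
        hlen <- host$end - host$start + 1L
        start <- sample(seq(1L, hlen - nchar(site) + 1L), 1)
        row <- tibble::tibble(chrom = host$chrom, strand = host$strand,
                              exons = list(tibble::tibble(start = host$start,
                                                          end = host$end)))
        genome_chars <- write_site_to_genome(genome_chars, row[1, ], start, site)
      } else {
        host <- lnc[((i - 1) %% nrow(lnc)) + 1, ]
        host_id <- host$transcript_id
        ex <- host$exons[[1]]
        # restrict to a single exon so the genomic footprint is contiguous
        exlen <- ex$end - ex$start + 1L
        ei <- which(exlen >= nchar(site) + 2L)[1]
        if (is.na(ei)) stop("placement error: lncRNA exon too short for mimic site")
        cum <- cumsum(exlen)
        if (host$strand == "-") {
          cum <- cumsum(rev(exlen)); ord <- rev(seq_len(nrow(ex)))
          ti <- which(ord == ei)
        } else ti <- ei
        tx_lo <- if (ti == 1) 1L else cum[ti - 1] + 1L
        tx_hi <- tx_lo + exlen[ei] - 1L
        start <- sample(seq(tx_lo, tx_hi - nchar(site) + 1L), 1)
        genome_chars <- write_site_to_genome(genome_chars, host, start, site)
      }
      mimic[[i]] <- tibble::tibble(
        mirna_id = mirnas$mirna_id[i], ncrna_id = host_id,
        site_start = start, bulge_len = b, insertion_after = 10L
      )
    }
    planted_mimic <- dplyr::bind_rows(mimic)

    # --- planted DE and ceRNA triplets ---
    # alternate tissue and direction out of phase so each tissue receives a
    # balanced mix of up- and down-planted features (library-size
    # normalization assumes most features are unchanged)
    tissues <- rep(c("leaf", "root"), length.out = n_mirna)
    mir_dir <- rep(c("down", "down", "up", "up"), length.out = n_mirna)
    opp <- c(down = "up", up = "down")
    de <- list()
    trip <- list()
    for (i in seq_len(n_mirna)) {
      ts <- tissues[i]
      fc <- if (i <= n_triplets) trip_log2fc else de_log2fc
      de[[length(de) + 1]] <- tibble::tibble(
        feature_id = mirnas$mirna_id[i], tissue = ts, direction = mir_dir[i],
        log2FC = ifelse(mir_dir[i] == "up", fc, -fc))
      de[[length(de) + 1]] <- tibble::tibble(
        feature_id = planted_cleavage$transcript_id[i], tissue = ts,
        direction = opp[[mir_dir[i]]],
        log2FC = ifelse(opp[[mir_dir[i]]] == "up", fc, -fc))
      if (i <= n_triplets) {
        de[[length(de) + 1]] <- tibble::tibble(
          feature_id = planted_mimic$ncrna_id[i], tissue = ts,
          direction = opp[[mir_dir[i]]],
          log2FC = ifelse(opp[[mir_dir[i]]] == "up", fc, -fc))
        trip[[i]] <- tibble::tibble(
          mirna_id = mirnas$mirna_id[i],
          cerna_a = planted_cleavage$transcript_id[i],
          cerna_b = planted_mimic$ncrna_id[i], tissue = ts)
      }
    }
    planted_de <- dplyr::distinct(dplyr::bind_rows(de),
                                  .data$feature_id, .data$tissue,
                                  .keep_all = TRUE)
    planted_triplets <- dplyr::bind_rows(trip)

    genome <- tibble::tibble(id = names(genome_chars),
                             sequence = unname(vapply(genome_chars, paste,
                                                      character(1), collapse = "")))
    ref$genome <- genome
    ref$transcripts <- add_spliced_sequences(ref$transcripts, genome)
    ref$circs$sequence <- vapply(seq_len(nrow(ref$circs)), function(i) {
      s <- substr(genome$sequence[match(ref$circs$chrom[i], genome$id)],
                  ref$circs$start[i], ref$circs$end[i])
      if (ref$circs$strand[i] == "-") s <- revcomp(s, out = "dna")
      dna_to_rna(s)
    }, character(1))
    list(ref = ref, mirnas = mirnas,
         truth = list(planted_de = planted_de,
                      planted_cleavage = planted_cleavage,
                      planted_mimic = planted_mimic,
                      planted_triplets = planted_triplets))
  })
}

#' Simulate replicated count matrices with planted effects
#'
#' Counts are negative-binomial around per-feature means (Poisson when
#' `dispersion` is 0) under a 2-tissue x 2-condition x 3-replicate design.
#' Planted DE features have treatment means shifted by the planted log2FC in
#' the planted tissue; because triplet members share this condition effect
#' with opposite signs for the miRNA, the two ceRNAs correlate positively
#' and the miRNA negatively across the six within-tissue samples.
#'
#' @param feature_ids Character vector of features.
#' @param planted_de Tibble (`feature_id`, `tissue`, `direction`, `log2FC`).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param lib_size Nominal library size; baseline means are expressed per
#'   1e6 and scaled by `lib_size / 1e6`.
#' @param seed RNG seed.
#' @param baseline Optional named vector of baseline means (per 1e6).
#' @param latent_shifts Optional tibble (`feature_id`, `sample_id`,
#'   `shift`) of per-sample log2 mean shifts carrying the shared latent
#'   factor that couples ceRNA-triplet members across replicates (see
#'   [simulate_cerna_study()]).
#' @return A wide count tibble (`feature_id` + 12 sample columns).
#' @export
simulate_counts <- function(feature_ids, planted_de, dispersion = 0.1,
                            lib_size = 1e6, seed = 1, baseline = NULL,
                            latent_shifts = NULL) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  with_seed(seed, {
    n <- length(feature_ids)
    if (is.null(baseline)) {
      baseline <- exp(stats::rnorm(n, log(200), 0.6))
      baseline <- pmin(pmax(baseline, 20), 2000)
      names(baseline) <- feature_ids
      planted <- unique(planted_de$feature_id)
      baseline[names(baseline) %in% planted] <-
        pmax(baseline[names(baseline) %in% planted], 150)
    }
    design <- tidyr::expand_grid(tissue = c("leaf", "root"),
                                 condition = c("ck", "st"), replicate = 1:3)
    design$sample_id <- paste(design$tissue, design$condition,
                              design$replicate, sep = "_")
    out <- tibble::tibble(feature_id = feature_ids)
    scale <- lib_size / 1e6
    for (j in seq_len(nrow(design))) {
      mu <- unname(baseline[feature_ids]) * scale
      if (design$condition[j] == "st") {
        pd <- planted_de[planted_de$tissue == design$tissue[j], ]
        idx <- match(pd$feature_id, feature_ids)
        ok <- !is.na(idx)
        mu[idx[ok]] <- mu[idx[ok]] * 2^pd$log2FC[ok]
      }
      if (!is.null(latent_shifts)) {
        ls <- latent_shifts[latent_shifts$sample_id == design$sample_id[j], ]
        idx <- match(ls$feature_id, feature_ids)
        ok <- !is.na(idx)
        mu[idx[ok]] <- mu[idx[ok]] * 2^ls$shift[ok]
      }
      out[[design$sample_id[j]]] <- if (dispersion == 0) {
        stats::rpois(n, mu)
      } else {
        stats::rnbinom(n, size = 1 / dispersion, mu = mu)
      }
    }
    out
  })
}

#' Simulate a degradome tag-abundance table with planted peaks
#'
#' Each planted cleavage site receives `peak_reads` tag 5' ends at the
#' target base paired to miRNA position 10; every other transcript position
#' receives Poisson(`background_rate`) background tags. The intended
#' category of each planted site given the realized profile is recorded.
#'
#' @param planted_cleavage Truth tibble ([plant_mirna_sites()]).
#' @param transcript_lengths Named vector of transcript lengths.
#' @param peak_reads Tag count planted at each cleavage position (>= 1).
#' @param background_rate Per-position Poisson background rate.
#' @param seed RNG seed.
#' @return A list: `profile` (tibble `transcript_id`, `position`, `count`)
#'   and `truth` (planted sites with `intended_category`).
#' @export
simulate_degradome <- function(planted_cleavage, transcript_lengths,
                               peak_reads = 50, background_rate = 0.01,
                               seed = 1) {
  if (peak_reads < 1) stop("peak_reads must be >= 1")
  if (background_rate < 0) stop("background_rate must be >= 0")
  with_seed(seed, {
    rows <- purrr::map_dfr(names(transcript_lengths), function(tid) {
      len <- transcript_lengths[[tid]]
      bg <- if (background_rate > 0) stats::rpois(len, background_rate) else
        integer(len)
      v <- as.numeric(bg)
      sites <- planted_cleavage[planted_cleavage$transcript_id == tid, ]
      if (nrow(sites)) v[sites$cleavage_pos] <- v[sites$cleavage_pos] + peak_reads
      pos <- which(v > 0)
      if (!length(pos)) return(NULL)
      tibble::tibble(transcript_id = tid, position = pos, count = v[pos])
    })
    truth <- planted_cleavage
    truth$intended_category <- vapply(seq_len(nrow(truth)), function(i) {
      v <- profile_vector(rows, truth$transcript_id[i],
                          transcript_lengths[[truth$transcript_id[i]]])
      classify_category(v, truth$cleavage_pos[i])
    }, integer(1))
    list(profile = rows, truth = truth)
  })
}

#' Simulate a complete synthetic ceRNA study
#'
#' One call builds the full input set the pipeline consumes: reference
#' genome and annotations, mature miRNAs with planted cleavage and mimic
#' sites, count matrices with planted differential expression and
#' correlation structure, a degradome profile with planted peaks, and the
#' machine-readable truth table. Defaults are the package's standard study
#' conditions (2 tissues x 2 conditions x 3 replicates, 20 miRNAs, 50
#' transcriptome features, |log2FC| = 2, NB dispersion 0.1, library size
#' 1e6, degradome peaks of 50 reads over 0.01 background).
#'
#' @param seed Master RNG seed; all stage seeds derive from it.
#' @inheritParams generate_reference
#' @inheritParams plant_mirna_sites
#' @inheritParams simulate_counts
#' @inheritParams simulate_degradome
#' @param latent_sd Standard deviation (log2 scale) of the per-sample shared
#'   latent factor coupling each planted triplet's members (ceRNAs load +1,
#'   the miRNA -1), the structural source of the within-condition
#'   correlations the network filter screens for.
#' @return A `cerna_study` list: `genome`, `transcripts`, `circs`,
#'   `mirnas`, `counts` (gene-like), `mirna_counts`, `feature_classes`,
#'   `feature_lengths`, `degradome`, `truth`.
#' @export
simulate_cerna_study <- function(seed = 1, n_genes = 30, n_lncrna = 15,
                                 n_circrna = 5, n_mirna = 20, n_triplets = 8,
                                 max_mut = 1, de_log2fc = 2, dispersion = 0.1,
                                 lib_size = 1e6, peak_reads = 50,
                                 background_rate = 0.01, trip_log2fc = 4, latent_sd = 0.25) {
  ref <- generate_reference(n_genes, n_lncrna, n_circrna, seed = seed)
  planted <- plant_mirna_sites(ref, n_mirna, seed = seed + 1000L,
                               n_triplets = n_triplets, max_mut = max_mut,
                               de_log2fc = de_log2fc,
                               trip_log2fc = trip_log2fc)
  ref <- planted$ref
  classes <- c(stats::setNames(ref$transcripts$biotype, ref$transcripts$transcript_id),
               stats::setNames(rep("circRNA", nrow(ref$circs)), ref$circs$circ_id))
  lengths <- c(stats::setNames(ref$transcripts$length, ref$transcripts$transcript_id),
               stats::setNames(nchar(ref$circs$sequence), ref$circs$circ_id))
  gene_ids <- names(classes)
  # shared latent factor per triplet and sample: each ceRNA loads +1 and the
  # miRNA -1, coupling the triplet's members across replicates within the
  # planted tissue (drawn once so both count matrices see the same factor)
  trip <- planted$truth$planted_triplets
  latent <- with_seed(seed + 5000L, {
    if (nrow(trip) == 0) NULL else purrr::map_dfr(seq_len(nrow(trip)), function(i) {
      ids <- paste(trip$tissue[i], rep(c("ck", "st"), each = 3), 1:3, sep = "_")
      l <- stats::rnorm(length(ids), 0, latent_sd)
      tibble::tibble(
        feature_id = rep(c(trip$cerna_a[i], trip$cerna_b[i], trip$mirna_id[i]),
                         each = length(ids)),
        sample_id = rep(ids, 3),
        shift = c(l, l, -l)
      )
    })
  })
  counts <- simulate_counts(gene_ids, planted$truth$planted_de,
                            dispersion = dispersion, lib_size = lib_size,
                            seed = seed + 2000L, latent_shifts = latent)
  mirna_counts <- simulate_counts(planted$mirnas$mirna_id,
                                  planted$truth$planted_de,
                                  dispersion = dispersion,
                                  lib_size = lib_size,
                                  seed = seed + 3000L, latent_shifts = latent)
  deg <- simulate_degradome(planted$truth$planted_cleavage, lengths,
                            peak_reads = peak_reads,
                            background_rate = background_rate,
                            seed = seed + 4000L)
  truth <- planted$truth
  truth$planted_cleavage <- deg$truth
  truth$rng_seed <- seed
  structure(list(genome = ref$genome, transcripts = ref$transcripts,
                 circs = ref$circs, mirnas = planted$mirnas, counts = counts,
                 mirna_counts = mirna_counts, feature_classes = classes,
                 feature_lengths = lengths, degradome = deg$profile,
                 truth = truth),
            class = "cerna_study")
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits genome FASTA, gene models GFF3, transcript and miRNA FASTA, count
#' TSVs, circRNA annotation TSV, degradome TSV and `truth.json`. Output is
#' byte-identical across runs for the same study object.
#'
#' @param study A `cerna_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(tibble::tibble(id = study$genome$id, sequence = study$genome$sequence),
              p("genome.fa"))
  write_gene_models(study$transcripts, p("transcripts.gff3"))
  write_fasta(tibble::tibble(id = study$transcripts$transcript_id,
                             sequence = study$transcripts$sequence),
              p("transcript_seqs.fa"))
  write_fasta(tibble::tibble(id = study$mirnas$mirna_id,
                             sequence = study$mirnas$sequence), p("mirna.fa"))
  write_count_table(study$counts, p("counts_gene.tsv"))
  write_count_table(study$mirna_counts, p("counts_mirna.tsv"))
  readr::write_tsv(study$circs[, c("circ_id", "chrom", "start", "end", "strand")],
                   p("circ_annotation.tsv"))
  readr::write_tsv(study$degradome, p("degradome.tsv"))
  jsonlite::write_json(study$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
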