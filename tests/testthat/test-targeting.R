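mir21 <- "UGGAGAAGCAGGGCACGUGCA"

test_that("align_duplex pairs exact complements and localizes substitutions", {
  w <- revcomp(mir21, out = "rna")
  d <- align_duplex(mir21, w, mode = "cleavage")
  expect_true(all(d$pair_states == "WC"))
  expect_equal(d$penalty, 0)

  # substitute the target base paired to miRNA position 3 (window index L-2)
  wc <- up_chars(w)
  wc[length(wc) - 2] <- "A"  # miRNA pos 3 is G; G:A is a mismatch
  d2 <- align_duplex(mir21, paste(wc, collapse = ""), mode = "cleavage")
  expect_equal(which(d2$pair_states == "MM"), 3L)

  # mimic: "CUA" inserted between the bases paired to miRNA nts 10-11
  rc <- up_chars(w)
  L <- length(rc)
  wm <- paste(c(rc[1:(L - 10)], "C", "U", "A", rc[(L - 9):L]), collapse = "")
  dm <- align_duplex(mir21, wm, mode = "mimic")
  expect_true(all(dm$pair_states == "WC"))
  expect_equal(dm$bulge$length, 3L)
  expect_equal(dm$bulge$after_mirna_pos, 10L)
  expect_equal(dm$bulge$side, "target")
})

test_that("align_duplex rejects invalid alphabets and inadmissible windows", {
  expect_error(align_duplex(mir21, "ACGT", mode = "cleavage"), "RNA")
  expect_null(align_duplex(mir21, rand_rna(20), mode = "cleavage"))
  expect_null(align_duplex(mir21, rand_rna(27), mode = "mimic"))  # bulge > 4
})

test_that("cleavage scoring applies the doubled core region and scissile rule", {
  w <- revcomp(mir21, out = "rna")
  d <- align_duplex(mir21, w, mode = "cleavage")
  s <- score_cleavage(d)
  expect_equal(s$score, 0)
  expect_true(s$accept)

  mm_at <- function(pos, base = NULL) {
    wc <- up_chars(w)
    i <- nchar(mir21) - pos + 1
    wc[i] <- base %||% up_chars(mir21)[pos]  # same base is always a mismatch
    align_duplex(mir21, paste(wc, collapse = ""), mode = "cleavage")
  }
  expect_equal(score_cleavage(mm_at(5))$score, 2)   # doubled region
  expect_equal(score_cleavage(mm_at(1))$score, 1)   # outside 2-13
  expect_false(score_cleavage(mm_at(10))$accept)    # scissile site must be WC
  expect_error(score_cleavage(align_duplex(mir21, rand_rna(24), "mimic") %||%
                                structure(list(mode = "mimic"),
                                          class = "duplex_alignment")),
               "cleavage")
})

test_that("score_cleavage is monotone in added mismatches", {
  set.seed(11)
  for (i in 1:20) {
    w <- up_chars(revcomp(mir21, out = "rna"))
    pos <- sample(setdiff(1:21, 10:11), 3)
    sc <- numeric(4)
    sc[1] <- score_cleavage(align_duplex(mir21, paste(w, collapse = ""),
                                         "cleavage"))$score
    for (k in 1:3) {
      w[21 - pos[k] + 1] <- up_chars(mir21)[pos[k]]
      sc[k + 1] <- score_cleavage(align_duplex(mir21, paste(w, collapse = ""),
                                               "cleavage"))$score
    }
    expect_true(all(diff(sc) >= 0))
  }
})

test_that("mimic rules I-III accept and reject as stated", {
  L <- nchar(mir21)
  rc <- up_chars(revcomp(mir21, out = "rna"))
  mk_mimic <- function(mm_positions = integer(), bulge = "CUA") {
    w <- rc
    for (p in mm_positions) w[L - p + 1] <- up_chars(mir21)[p]
    paste(c(w[1:(L - 10)], up_chars(bulge), w[(L - 9):L]), collapse = "")
  }
  ok <- check_mimic(align_duplex(mir21, mk_mimic(), "mimic"))
  expect_true(ok$accept)

  five <- check_mimic(align_duplex(mir21, mk_mimic(c(2, 4, 6, 15, 18)), "mimic"))
  expect_false(five$accept)
  expect_match(five$reasons, "II")

  run3 <- check_mimic(align_duplex(mir21, mk_mimic(4:6), "mimic"))
  expect_false(run3$accept)
  expect_match(run3$reasons, "II")

  # four scattered mismatches stay within the budget
  four <- check_mimic(align_duplex(mir21, mk_mimic(c(2, 5, 14, 18)), "mimic"))
  expect_true(four$accept)

  expect_error(check_mimic(align_duplex(mir21, revcomp(mir21, "rna"),
                                        "cleavage")), "mimic")
})

test_that("mimic acceptance is invariant under WC-preserving substitutions", {
  set.seed(23)
  L <- nchar(mir21)
  rc <- up_chars(revcomp(mir21, out = "rna"))
  base <- paste(c(rc[1:(L - 10)], "G", "G", rc[(L - 9):L]), collapse = "")
  for (i in 1:10) {
    m <- up_chars(mir21); w <- up_chars(base)
    p <- sample(setdiff(1:L, 1), 1)
    wc_pairs <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
    pick <- wc_pairs[[sample(4, 1)]]
    m[p] <- pick[1]
    wi <- if (p <= 10) (L + 2) - p + 1 else L - p + 1
    w[wi] <- pick[2]
    a0 <- check_mimic(align_duplex(mir21, base, "mimic"))
    a1 <- check_mimic(align_duplex(paste(m, collapse = ""),
                                   paste(w, collapse = ""), "mimic"))
    expect_equal(a1$accept, a0$accept)
  }
})

test_that("align_duplex equals exhaustive pairing enumeration on random windows", {
  set.seed(101)
  brute_force <- function(mirna, window, middle = c(9, 11)) {
    # enumerate every admissible pairing directly from the geometry
    m <- up_chars(mirna); L <- length(m)
    W <- nchar(window); w <- up_chars(window)
    b <- W - L
    states_for <- function(k) {
      idx <- vapply(seq_len(L), function(i) {
        if (i <= k || b == 0) W - i + 1 else W - i + 1 - b
      }, numeric(1))
      pair_states(m, w[idx])
    }
    if (b == 0) {
      st <- states_for(0)
      return(list(states = st, penalty = sum((st == "MM") + 0.5 * (st == "GU")),
                  k = NA))
    }
    if (b < 1 || b > 4) return(NULL)
    best <- NULL
    for (k in seq(middle[1], middle[2] - 1)) {
      st <- states_for(k)
      pen <- sum((st == "MM") + 0.5 * (st == "GU"))
      if (is.null(best) || pen < best$penalty) best <- list(states = st,
                                                            penalty = pen, k = k)
    }
    best
  }
  for (i in 1:100) {
    L <- sample(c(21, 24), 1)
    mirna <- rand_rna(L)
    b <- sample(0:4, 1)
    window <- rand_rna(L + b)
    mode <- if (b == 0) "cleavage" else "mimic"
    got <- align_duplex(mirna, window, mode)
    want <- brute_force(mirna, window)
    expect_equal(got$pair_states, want$states)
    expect_equal(got$penalty, want$penalty)
    if (b > 0) expect_equal(got$bulge$after_mirna_pos, want$k)
  }
})

test_that("scan_transcript recovers planted sites, including across back-splice junctions", {
  set.seed(55)
  mir <- rand_rna(21)
  site <- revcomp(mir, out = "rna")
  tx <- paste0(rand_rna(300), site, rand_rna(200))
  hits <- scan_transcript(mir, tx, mode = "cleavage")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 301L)
  expect_equal(hits$cleavage_pos, 301L + 21L - 10L)

  # circular transcript with the site straddling the junction
  circ <- paste0(substr(site, 12, 21), rand_rna(150), substr(site, 1, 11))
  expect_equal(nrow(scan_transcript(mir, circ, "cleavage", circular = FALSE)), 0)
  ch <- scan_transcript(mir, circ, "cleavage", circular = TRUE)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$start, 161L)
  expect_equal(ch$cleavage_pos, (161L + 21L - 10L - 1L) %% nchar(circ) + 1L)

  # mimic site recovered at the planted window
  rc <- up_chars(site)
  mim <- paste(c(rc[1:11], "GAU", rc[12:21]), collapse = "")
  tx2 <- paste0(rand_rna(100), mim, rand_rna(100))
  mh <- scan_transcript(mir, tx2, mode = "mimic")
  expect_true(101L %in% mh$start)
})

test_that("random transcripts essentially never yield accepted cleavage sites", {
  set.seed(77)
  n_hits <- vapply(1:200, function(i) {
    nrow(scan_transcript(rand_rna(21), rand_rna(2000), mode = "cleavage"))
  }, integer(1))
  expect_lt(mean(n_hits), 0.05)
})
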