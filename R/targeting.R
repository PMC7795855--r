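# Integer codes for RNA bases; anything else (N) codes 5 and never pairs.
rna_code <- function(chars) {
  code <- match(chars, c("A", "C", "G", "U"))
  code[is.na(code)] <- 5L
  code
}

# 5x5 pair-state lookup (miRNA base x target base): 0 = MM, 1 = GU, 2 = WC.
pair_lut <- local({
  p <- matrix(0L, 5, 5)
  p[1, 4] <- 2L; p[4, 1] <- 2L; p[3, 2] <- 2L; p[2, 3] <- 2L
  p[3, 4] <- 1L; p[4, 3] <- 1L
  p
})

state_label <- c("MM", "GU", "WC")

# Target-window index paired to miRNA position i (both 5'->3') for an
# antiparallel duplex over a window of length W with a target-side bulge of
# length b inserted between the bases paired to miRNA positions k and k+1
# (b = 0, k ignored for a bulge-free duplex).
duplex_partner_idx <- function(L, W, b = 0L, k = 0L) {
  i <- seq_len(L)
  ifelse(i <= k | b == 0L, W - i + 1L, W - i + 1L - b)
}

#' Align a miRNA against a candidate target window
#'
#' Returns the minimal-penalty antiparallel pairing of the window (target,
#' 5'->3') against the miRNA (5'->3'). Cleavage mode admits no bulges, so
#' the window must equal the miRNA length. Mimic mode admits exactly one
#' target-side bulge of 1-4 nt inserted at a middle insertion point
#' (between the bases paired to miRNA positions 9-10 or 10-11 by default);
#' ties break to the leftmost insertion point. Penalty counts MM as 1 and
#' G:U as 0.5 over all positions.
#'
#' @param mirna miRNA sequence, RNA space, 5'->3'.
#' @param window Target window sequence, RNA space, 5'->3'.
#' @param mode `"cleavage"` or `"mimic"`.
#' @param middle Middle positions of the miRNA, default `c(9, 11)`.
#' @param bulge_range Allowed mimic bulge lengths, default `c(1, 4)`.
#' @return A `duplex_alignment` object (list with `mirna`, `window`, `mode`,
#'   `pair_states`, `bulge`, `penalty`), or `NULL` if the window length
#'   admits no pairing under the mode's rules.
#' @export
align_duplex <- function(mirna, window, mode = c("cleavage", "mimic"),
                         middle = c(9, 11), bulge_range = c(1, 4)) {
  mode <- match.arg(mode)
  if (grepl("[^ACGUN]", toupper(mirna)) || grepl("[^ACGUN]", toupper(window))) {
    stop("sequences must be RNA (A/C/G/U/N)")
  }
  m <- rna_code(up_chars(mirna))
  w <- rna_code(up_chars(window))
  L <- length(m); W <- length(w)
  mk_aln <- function(states, bulge) {
    structure(list(mirna = toupper(mirna), window = toupper(window),
                   mode = mode, pair_states = state_label[states + 1L],
                   bulge = bulge,
                   penalty = sum((states == 0L) * 1 + (states == 1L) * 0.5)),
              class = "duplex_alignment")
  }
  if (mode == "cleavage") {
    if (W != L) return(NULL)
    states <- pair_lut[cbind(m, w[duplex_partner_idx(L, W)])]
    return(mk_aln(states, NULL))
  }
  b <- W - L
  if (b < bulge_range[1] || b > bulge_range[2]) return(NULL)
  ks <- seq(middle[1], middle[2] - 1)
  best <- NULL
  for (k in ks) {
    states <- pair_lut[cbind(m, w[duplex_partner_idx(L, W, b, k)])]
    pen <- sum((states == 0L) * 1 + (states == 1L) * 0.5)
    if (is.null(best) || pen < best$penalty) {
      best <- mk_aln(states, tibble::tibble(after_mirna_pos = k,
                                            side = "target", length = b))
      best$penalty <- pen
    }
  }
  best
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("duplex_alignment (", x$mode, ")\n", sep = "")
  cat("miRNA:  5'-", x$mirna, "-3'\n", sep = "")
  cat("states: ", paste(substr(x$pair_states, 1, 1), collapse = ""), "\n", sep = "")
  if (!is.null(x$bulge)) {
    cat("target bulge of ", x$bulge$length, " nt after miRNA position ",
        x$bulge$after_mirna_pos, "\n", sep = "")
  }
  cat("penalty: ", x$penalty, "\n", sep = "")
  invisible(x)
}

#' Score a cleavage-mode duplex
#'
#' Penalties: mismatch 1, G:U wobble 0.5, doubled at miRNA positions 2-13.
#' Accept iff score <= `max_score` (default 4.0) and positions 10-11 are
#' Watson-Crick (the scissile site must be paired).
#'
#' @param d A cleavage-mode `duplex_alignment`.
#' @param max_score Acceptance threshold.
#' @param double_region Positions with doubled penalties, default `c(2, 13)`.
#' @return A list with `score` and `accept`.
#' @export
score_cleavage <- function(d, max_score = 4, double_region = c(2, 13)) {
  if (d$mode != "cleavage") stop("score_cleavage requires a cleavage-mode alignment")
  st <- d$pair_states
  L <- length(st)
  wgt <- ifelse(seq_len(L) >= double_region[1] & seq_len(L) <= double_region[2], 2, 1)
  score <- sum(((st == "MM") * 1 + (st == "GU") * 0.5) * wgt)
  accept <- score <= max_score && all(st[10:11] == "WC")
  list(score = score, accept = accept)
}

#' Validate a mimic-mode duplex against the target-mimicry rules
#'
#' Rule I: exactly one bulge, on the target (ncRNA) side, at a middle
#' insertion point. Rule II: over non-middle miRNA positions, the mismatch
#' budget (MM = 1, G:U = 0.5) is at most `max_budget` and no more than
#' `max_run` consecutive mismatches (G:U pairs break a run and do not count
#' toward it). Rule III: no bulge anywhere else.
#'
#' @param d A mimic-mode `duplex_alignment`.
#' @param middle Middle positions of the miRNA, default `c(9, 11)`.
#' @param max_budget Rule-II mismatch budget, default 4.
#' @param max_run Longest allowed consecutive-mismatch run, default 2.
#' @return A list with `accept` and `reasons` (violated rules, if any).
#' @export
check_mimic <- function(d, middle = c(9, 11), max_budget = 4, max_run = 2) {
  if (d$mode != "mimic") stop("check_mimic requires a mimic-mode alignment")
  reasons <- character()
  if (is.null(d$bulge) || nrow(d$bulge) != 1 || d$bulge$side != "target" ||
      d$bulge$after_mirna_pos < middle[1] ||
      d$bulge$after_mirna_pos >= middle[2]) {
    reasons <- c(reasons, "I: need exactly one target-side bulge at a middle insertion point")
  }
  st <- d$pair_states
  is_mid <- seq_along(st) >= middle[1] & seq_along(st) <= middle[2]
  budget <- sum((st == "MM" & !is_mid) * 1 + (st == "GU" & !is_mid) * 0.5)
  run <- max_mm_run(st, is_mid)
  if (budget > max_budget || run > max_run) {
    reasons <- c(reasons, "II: mismatch budget or consecutive-mismatch run exceeded")
  }
  list(accept = length(reasons) == 0, reasons = reasons)
}

max_mm_run <- function(states, is_mid) {
  mm <- states == "MM" & !is_mid
  if (!any(mm)) return(0L)
  r <- rle(mm)
  max(r$lengths[r$values])
}

#' Scan a transcript for miRNA target sites
#'
#' Slides all admissible windows along the transcript, aligns each against
#' the miRNA and applies the mode's acceptance rules ([score_cleavage()] /
#' [check_mimic()]). For circular transcripts the sequence is treated as a
#' circle: windows may span the back-splice junction and duplicate hits are
#' deduplicated by modular position. Overlapping cleavage windows are
#' deduplicated keeping the best score per predicted cleavage position.
#'
#' @param mirna miRNA sequence (RNA space, 5'->3').
#' @param transcript Transcript sequence (RNA space).
#' @param mode `"cleavage"` or `"mimic"`.
#' @param circular Treat the transcript as circular (circRNA).
#' @param middle,bulge_range,max_score,double_region Rule parameters, see
#'   [align_duplex()] and [score_cleavage()].
#' @param max_budget,max_run Mimic rule-II parameters, see [check_mimic()].
#' @return A tibble of accepted sites: `start`, `end` (transcript window,
#'   1-based), `score`, `cleavage_pos` (cleavage mode; the target base
#'   paired to miRNA position 10), `bulge_len`, `insertion_k` (mimic mode),
#'   `mode`; sorted by (score, position).
#' @export
scan_transcript <- function(mirna, transcript, mode = c("cleavage", "mimic"),
                            circular = FALSE, middle = c(9, 11),
                            bulge_range = c(1, 4), max_score = 4,
                            double_region = c(2, 13), max_budget = 4,
                            max_run = 2) {
  mode <- match.arg(mode)
  mirna <- dna_to_rna(mirna)
  transcript <- dna_to_rna(transcript)
  n0 <- nchar(transcript)
  L <- nchar(mirna)
  if (n0 < L) return(empty_sites(mode))
  seqs <- if (circular) paste0(transcript, substr(transcript, 1, L + bulge_range[2])) else transcript
  m <- rna_code(up_chars(mirna))
  t_code <- rna_code(up_chars(seqs))
  n <- length(t_code)

  if (mode == "cleavage") {
    W <- L
    n_win <- n - W + 1
    if (circular) n_win <- min(n_win, n0)  # starts 1..n0 cover all junctions
    if (n_win < 1) return(empty_sites(mode))
    starts <- seq_len(n_win)
    idx <- duplex_partner_idx(L, W)
    wgt <- ifelse(seq_len(L) >= double_region[1] & seq_len(L) <= double_region[2], 2, 1)
    score <- numeric(n_win)
    ok_scissile <- rep(TRUE, n_win)
    for (i in seq_len(L)) {
      st <- pair_lut[cbind(m[i], t_code[starts + idx[i] - 1L])]
      score <- score + ((st == 0L) * 1 + (st == 1L) * 0.5) * wgt[i]
      if (i %in% 10:11) ok_scissile <- ok_scissile & st == 2L
    }
    acc <- score <= max_score & ok_scissile
    out <- tibble::tibble(
      start = starts[acc], end = starts[acc] + W - 1L, score = score[acc],
      cleavage_pos = starts[acc] + (W - 10L), bulge_len = NA_integer_,
      insertion_k = NA_integer_, mode = "cleavage"
    )
    if (circular && nrow(out)) {
      out$cleavage_pos <- (out$cleavage_pos - 1L) %% n0 + 1L
      out$start <- (out$start - 1L) %% n0 + 1L
      out$end <- (out$end - 1L) %% n0 + 1L
    }
    out <- out |>
      dplyr::arrange(.data$score, .data$start) |>
      dplyr::distinct(.data$cleavage_pos, .keep_all = TRUE) |>
      dplyr::arrange(.data$score, .data$start)
    return(out)
  }

  ks <- seq(middle[1], middle[2] - 1)
  mid <- seq_len(L) >= middle[1] & seq_len(L) <= middle[2]
  res <- list()
  for (b in seq(bulge_range[1], bulge_range[2])) {
    W <- L + b
    n_win <- n - W + 1
    if (circular) n_win <- min(n_win, n0)
    if (n_win < 1) next
    starts <- seq_len(n_win)
    for (k in ks) {
      idx <- duplex_partner_idx(L, W, b, k)
      budget <- numeric(n_win)
      pen <- numeric(n_win)
      run <- integer(n_win); max_run_v <- integer(n_win)
      for (i in seq_len(L)) {
        st <- pair_lut[cbind(m[i], t_code[starts + idx[i] - 1L])]
        pen <- pen + (st == 0L) * 1 + (st == 1L) * 0.5
        if (!mid[i]) {
          budget <- budget + (st == 0L) * 1 + (st == 1L) * 0.5
          run <- ifelse(st == 0L, run + 1L, 0L)
        } else {
          run <- 0L
        }
        max_run_v <- pmax(max_run_v, run)
      }
      acc <- budget <= max_budget & max_run_v <= max_run
      if (any(acc)) {
        res[[length(res) + 1]] <- tibble::tibble(
          start = starts[acc], end = starts[acc] + W - 1L, score = budget[acc],
          penalty = pen[acc], cleavage_pos = NA_integer_,
          bulge_len = b, insertion_k = k, mode = "mimic"
        )
      }
    }
  }
  if (!length(res)) return(empty_sites(mode))
  out <- dplyr::bind_rows(res)
  if (circular) {
    out$start <- (out$start - 1L) %% n0 + 1L
    out$end <- (out$end - 1L) %% n0 + 1L
  }
  # one record per window: minimal penalty, leftmost insertion point
  out |>
    dplyr::arrange(.data$penalty, .data$insertion_k) |>
    dplyr::distinct(.data$start, .data$bulge_len, .keep_all = TRUE) |>
    dplyr::select(-"penalty") |>
    dplyr::arrange(.data$score, .data$start)
}

empty_sites <- function(mode) {
  tibble::tibble(start = integer(), end = integer(), score = numeric(),
                 cleavage_pos = integer(), bulge_len = integer(),
                 insertion_k = integer(), mode = character())
}

#' Scan many miRNAs against many transcripts
#'
#' Convenience wrapper over [scan_transcript()]: mRNAs are scanned in
#' cleavage mode, non-coding classes in both cleavage and mimic mode.
#'
#' @param mirnas Tibble (`mirna_id`, `sequence`).
#' @param transcripts Tibble (`transcript_id`, `sequence`, `class`) where
#'   `class` is `mRNA`, `lncRNA` or `circRNA`.
#' @param ... Rule parameters passed to [scan_transcript()].
#' @return A tibble of sites with `mirna_id`, `target_id`, `target_class`
#'   and the [scan_transcript()] columns.
#' @export
scan_all_targets <- function(mirnas, transcripts, ...) {
  grid <- tidyr::expand_grid(mi = seq_len(nrow(mirnas)),
                             tx = seq_len(nrow(transcripts)))
  purrr::pmap_dfr(grid, function(mi, tx) {
    cls <- transcripts$class[tx]
    circ <- cls == "circRNA"
    modes <- if (cls == "mRNA") "cleavage" else c("cleavage", "mimic")
    purrr::map_dfr(modes, function(md) {
      s <- scan_transcript(mirnas$sequence[mi], transcripts$sequence[tx],
                           mode = md, circular = circ, ...)
      if (nrow(s) == 0) return(s)
      tibble::tibble(mirna_id = mirnas$mirna_id[mi],
                     target_id = transcripts$transcript_id[tx],
                     target_class = cls, s)
    })
  })
}
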