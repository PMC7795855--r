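#' Map degradome tags onto transcript positions
#'
#' Each tag's 5' end is placed at every exact-match position of its prefix
#' (first `prefix` nt, default 20, or the full tag if shorter) on the sense
#' strand of the transcripts. Tags matching k positions contribute weight
#' count/k to each. Unmatched tags contribute nothing (their count is
#' reported in the `n_unmatched` attribute).
#'
#' @param tags Tibble with `sequence` and `count` (tag 5'-end abundances).
#' @param transcripts Tibble (`transcript_id`, `sequence`).
#' @param prefix Prefix length used for matching.
#' @return A degradome profile tibble: `transcript_id`, `position`,
#'   `count` (possibly fractional), one row per covered position.
#' @export
map_tags <- function(tags, transcripts, prefix = 20) {
  if (nrow(transcripts) == 0) stop("empty transcript set")
  tx_seq <- dna_to_rna(transcripts$sequence)
  hits <- purrr::map_dfr(seq_len(nrow(tags)), function(i) {
    q <- dna_to_rna(tags$sequence[i])
    q <- substr(q, 1, min(prefix, nchar(q)))
    m <- purrr::map_dfr(seq_along(tx_seq), function(j) {
      at <- gregexpr(q, tx_seq[j], fixed = TRUE)[[1]]
      if (at[1] == -1) return(tibble::tibble(transcript_id = character(),
                                             position = integer()))
      tibble::tibble(transcript_id = transcripts$transcript_id[j],
                     position = as.integer(at))
    })
    if (nrow(m) == 0) return(tibble::tibble(transcript_id = character(),
                                            position = integer(), count = numeric()))
    m$count <- tags$count[i] / nrow(m)
    m
  })
  n_unmatched <- sum(tags$count) - sum(hits$count)
  out <- hits |>
    dplyr::group_by(.data$transcript_id, .data$position) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  attr(out, "n_unmatched") <- n_unmatched
  out
}

# Dense abundance vector for one transcript from a profile table.
profile_vector <- function(profile, transcript_id, length) {
  v <- numeric(length)
  p <- profile[profile$transcript_id == transcript_id, ]
  v[p$position] <- p$count
  v
}

#' Classify a degradome position into cleavage categories 0-4
#'
#' Category 0: abundance > 1, equal to the transcript maximum, and the
#' maximum is unique. Category 1: > 1, equal to a shared maximum.
#' Category 2: > 1, below the maximum but above the median. Category 3:
#' > 1 and at most the median. Category 4: abundance <= 1. The median is
#' taken over positions with at least one tag.
#'
#' @param abundance Dense per-position abundance vector for one transcript.
#' @param position 1-based position to classify (abundance must be > 0).
#' @return Integer category in 0:4.
#' @export
classify_category <- function(abundance, position) {
  x <- abundance[position]
  if (is.na(x) || x <= 0) stop("no degradome signal at position ", position)
  if (x <= 1) return(4L)
  mx <- max(abundance)
  if (x == mx) {
    if (sum(abundance == mx) == 1) return(0L) else return(1L)
  }
  med <- stats::median(abundance[abundance >= 1])
  if (x > med) 2L else 3L
}

#' Validate predicted cleavage sites against degradome profiles
#'
#' A predicted site becomes a cleavage event iff the degradome abundance at
#' its predicted position (the target base paired to miRNA position 10) is
#' positive. Events carry the category classification and a reference-only
#' binomial enrichment p-value (probability of >= the observed count at one
#' position given the transcript's total tags and a uniform null); the
#' p-value is not used for screening.
#'
#' @param sites Cleavage-mode site tibble ([scan_all_targets()]), with
#'   `mirna_id`, `target_id`, `cleavage_pos`.
#' @param profile Degradome profile tibble ([map_tags()]).
#' @param transcript_lengths Named vector of transcript lengths.
#' @return A tibble of events: `mirna_id`, `transcript_id`, `position`,
#'   `tag_count`, `category`, `p_enrich`.
#' @export
validate_sites <- function(sites, profile, transcript_lengths) {
  sites <- sites[sites$mode == "cleavage", ]
  if (nrow(sites) == 0) {
    return(tibble::tibble(mirna_id = character(), transcript_id = character(),
                          position = integer(), tag_count = numeric(),
                          category = integer(), p_enrich = numeric()))
  }
  unknown <- setdiff(sites$target_id, names(transcript_lengths))
  if (length(unknown)) stop("site references unknown transcript(s): ",
                            paste(unknown, collapse = ", "))
  purrr::map_dfr(unique(sites$target_id), function(tid) {
    v <- profile_vector(profile, tid, transcript_lengths[[tid]])
    s <- sites[sites$target_id == tid, ]
    s <- s[s$cleavage_pos >= 1 & s$cleavage_pos <= length(v), ]
    cnt <- v[s$cleavage_pos]
    keep <- cnt > 0
    if (!any(keep)) return(NULL)
    s <- s[keep, ]; cnt <- cnt[keep]
    total <- round(sum(v))
    tibble::tibble(
      mirna_id = s$mirna_id,
      transcript_id = tid,
      position = s$cleavage_pos,
      tag_count = cnt,
      category = vapply(s$cleavage_pos, function(p) classify_category(v, p), integer(1)),
      p_enrich = stats::pbinom(pmax(0, ceiling(cnt) - 1), total,
                               1 / length(v), lower.tail = FALSE)
    )
  })
}

#' Build a T-plot table for one transcript
#'
#' Dense per-position degradome abundances with validated cleavage sites
#' flagged; one row per transcript position, ready for plotting.
#'
#' @param profile Degradome profile tibble.
#' @param events Cleavage event tibble ([validate_sites()]).
#' @param transcript_id Transcript to tabulate.
#' @param length Transcript length in nt.
#' @return A tibble with `position`, `abundance`, `is_cleavage_site`.
#' @export
tplot_table <- function(profile, events, transcript_id, length) {
  v <- profile_vector(profile, transcript_id, length)
  flagged <- events$position[events$transcript_id == transcript_id]
  tibble::tibble(position = seq_len(length), abundance = v,
                 is_cleavage_site = seq_len(length) %in% flagged)
}

#' Plot a degradome T-plot
#'
#' @param tplot A [tplot_table()] result.
#' @param title Optional plot title (e.g. the transcript id).
#' @return A ggplot object: per-position tag abundance with cleavage sites
#'   highlighted.
#' @export
plot_tplot <- function(tplot, title = NULL) {
  ggplot2::ggplot(tplot, ggplot2::aes(x = .data$position, y = .data$abundance)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          colour = "grey40") +
    ggplot2::geom_point(data = dplyr::filter(tplot, .data$is_cleavage_site),
                        colour = "red", shape = 17, size = 2.5) +
    ggplot2::labs(x = "transcript position (nt)", y = "degradome tag abundance",
                  title = title) +
    ggplot2::theme_minimal()
}
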