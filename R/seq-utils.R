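up_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

#' Reverse-complement a nucleotide string
#'
#' Works in either DNA or RNA space; the output alphabet follows `out`.
#'
#' @param x A single nucleotide string (A/C/G/T/U/N).
#' @param out Output alphabet, `"rna"` or `"dna"`.
#' @return The reverse complement as a single string.
#' @export
revcomp <- function(x, out = c("rna", "dna")) {
  out <- match.arg(out)
  comp <- c(A = ifelse(out == "rna", "U", "T"), C = "G", G = "C",
            T = "A", U = "A", N = "N")
  ch <- rev(up_chars(x))
  bad <- !ch %in% names(comp)
  if (any(bad)) stop("invalid nucleotide(s): ", paste(unique(ch[bad]), collapse = ","))
  paste(unname(comp[ch]), collapse = "")
}

#' Convert between DNA and RNA alphabets
#'
#' @param x Nucleotide string(s).
#' @return `dna_to_rna()` replaces T with U; `rna_to_dna()` the reverse.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

# Pair-state classification between a miRNA base and a target base, both in
# RNA space and both read 5'->3' on their own strands. WC = Watson-Crick,
# GU = G:U wobble, MM = anything else (including N).
pair_states <- function(mirna_chars, target_chars) {
  stopifnot(length(mirna_chars) == length(target_chars))
  m <- mirna_chars; t <- target_chars
  wc <- (m == "A" & t == "U") | (m == "U" & t == "A") |
        (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "U") | (m == "U" & t == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "MM"))
}

# Longest open reading frame (AUG..stop, length in nt including the stop
# codon) over the three forward frames of an RNA string. An AUG with no
# in-frame stop is counted to the last complete codon.
longest_orf <- function(rna) {
  s <- up_chars(dna_to_rna(rna))
  n <- length(s)
  best <- 0L
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0) next
    codons <- paste0(s[starts], s[starts + 1L], s[starts + 2L])
    is_start <- codons == "AUG"
    is_stop <- codons %in% c("UAA", "UAG", "UGA")
    open_from <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_from) && is_start[i]) open_from <- i
      if (!is.na(open_from) && is_stop[i]) {
        best <- max(best, (i - open_from + 1L) * 3L)
        open_from <- NA_integer_
      }
    }
    if (!is.na(open_from)) best <- max(best, (length(codons) - open_from + 1L) * 3L)
  }
  best
}

# Deterministic RNG scope: runs `expr` under `seed` and restores the caller's
# RNG state afterwards, so generators are reproducible without clobbering
# the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
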