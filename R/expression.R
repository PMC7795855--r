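#' FPKM normalization
#'
#' FPKM = count x 10^9 / (feature length in nt x total fragments in the
#' sample). Zero FPKM values are kept as zero; the 1e-6 pseudo-count used to
#' avoid log(0) is applied only where logs are taken (see [log2_pseudo()]).
#'
#' @param counts Wide count tibble: `feature_id` plus one column per sample.
#' @param lengths Named numeric vector or tibble (`feature_id`, `length`)
#'   of feature lengths in nt.
#' @return A tibble of the same shape holding FPKM values.
#' @export
compute_fpkm <- function(counts, lengths) {
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length, lengths$feature_id)
  }
  len <- lengths[counts$feature_id]
  if (anyNA(len)) stop("missing length for feature(s): ",
                       paste(counts$feature_id[is.na(len)], collapse = ", "))
  if (any(len <= 0)) stop("feature lengths must be > 0")
  out <- counts
  samp <- setdiff(names(counts), "feature_id")
  for (s in samp) {
    tot <- sum(counts[[s]])
    if (tot <= 0) stop("zero library size in sample ", s)
    out[[s]] <- counts[[s]] * 1e9 / (as.numeric(len) * tot)
  }
  out
}

#' Counts-per-million normalization for miRNA libraries
#'
#' Global normalization: cpm = count x 10^6 / per-sample total.
#'
#' @inheritParams compute_fpkm
#' @return A tibble of the same shape holding CPM values.
#' @export
normalize_mirna <- function(counts) {
  out <- counts
  for (s in setdiff(names(counts), "feature_id")) {
    tot <- sum(counts[[s]])
    if (tot <= 0) stop("zero library size in sample ", s)
    out[[s]] <- counts[[s]] * 1e6 / tot
  }
  out
}

#' Median-of-ratios normalization of a count table
#'
#' Divides each sample by its median-of-ratios size factor (the estimator
#' [de_test()] uses), which is robust to composition shifts that distort
#' total-count scaling when many features change or the feature set is
#' small. Used for the correlation inputs of the network stage.
#'
#' @inheritParams compute_fpkm
#' @return A tibble of the same shape holding normalized counts.
#' @export
normalize_counts <- function(counts) {
  samp <- setdiff(names(counts), "feature_id")
  m <- as.matrix(counts[, samp])
  sf <- estimate_size_factors(m)
  out <- counts
  for (i in seq_along(samp)) out[[samp[i]]] <- counts[[samp[i]]] / sf[i]
  out
}

#' log2 with the pipeline's pseudo-count
#'
#' @param x Non-negative values.
#' @param pseudo Pseudo-count added before the log (default 1e-6).
#' @return log2(x + pseudo).
#' @export
log2_pseudo <- function(x, pseudo = 1e-6) log2(x + pseudo)

# Two-sided exact test for equal means of two negative-binomial group sums,
# conditioning on the total. Each group sum is the sum of n_rep iid NB counts
# with common dispersion phi (variance mu + phi*mu^2), so the group sum has
# size n_rep/phi. In the phi -> 0 limit this is the conditional binomial
# test with p = 1/2 (the "sum of small probabilities" two-sided rule, as in
# stats::binom.test).
nb_exact_pvalue <- function(s1, s2, phi, n_rep = 3) {
  n <- s1 + s2
  if (n == 0) return(1)
  k <- 0:n
  if (phi < 1e-12) {
    logp <- stats::dbinom(k, n, 0.5, log = TRUE)
  } else {
    size <- n_rep / phi
    mu <- n / 2
    logp <- stats::dnbinom(k, size = size, mu = mu, log = TRUE) +
      stats::dnbinom(n - k, size = size, mu = mu, log = TRUE)
    logp <- logp - matrixStats_logsumexp(logp)
  }
  p_obs <- logp[s1 + 1]
  min(1, sum(exp(logp[logp <= p_obs + 1e-7])))
}

matrixStats_logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Median-of-ratios size factors (ratios of each sample to the row-wise
# geometric-mean reference, median over features expressed in all samples),
# rescaled to geometric mean 1. Robust to composition shifts when most
# features are unchanged; falls back to total-count scaling when too few
# features are all-positive.
estimate_size_factors <- function(m) {
  pos <- rowSums(m > 0) == ncol(m)
  if (sum(pos) >= 5) {
    logref <- rowMeans(log(m[pos, , drop = FALSE]))
    sf <- apply(m[pos, , drop = FALSE], 2, function(col) {
      exp(stats::median(log(col) - logref))
    })
  } else {
    lib <- colSums(m)
    sf <- lib / mean(lib)
  }
  sf / exp(mean(log(sf)))
}

#' Class-specific differential-expression test
#'
#' Negative-binomial exact test on per-group summed library-size-normalized
#' counts (3 vs 3 replicates within a tissue; median-of-ratios size
#' factors). Per-feature dispersion is estimated by the method of moments
#' and shrunk 50/50 toward the across-feature median. Calls use the class-specific cutoffs: `gene_like`
#' requires |log2FC| > `fc_cutoff` (default 1); `mirna` requires fold change
#' >= 1.5 in either direction (|log2FC| >= log2 1.5). Both require
#' p < `alpha` (strict).
#'
#' @param counts Wide count tibble (`feature_id` + samples).
#' @param tissue Tissue to test (samples of other tissues are ignored).
#' @param class `"gene_like"` or `"mirna"`.
#' @param alpha Raw p-value cutoff (default 0.05; 0.1 is the relaxed mode).
#' @param fc_cutoff log2 fold-change cutoff for `gene_like` (default 1).
#' @param dispersion Optional fixed dispersion overriding estimation
#'   (0 gives the Poisson/binomial limit).
#' @param design Optional design tibble; derived from sample ids by default.
#' @return A tibble with `feature_id`, `tissue`, `mean_ck`, `mean_st`,
#'   `log2FC`, `p_value`, `direction` (`up`/`down`/`ns`); the thresholds are
#'   recorded as attributes `class`, `alpha` and `fc_cutoff`.
#' @export
de_test <- function(counts, tissue, class = c("gene_like", "mirna"),
                    alpha = 0.05, fc_cutoff = 1, dispersion = NULL,
                    design = NULL) {
  class <- match.arg(class)
  samp <- setdiff(names(counts), "feature_id")
  design <- design %||% sample_design(samp)
  design <- design[design$tissue == tissue, ]
  ck <- design$sample_id[design$condition == "ck"]
  st <- design$sample_id[design$condition == "st"]
  if (length(ck) != 3 || length(st) != 3) {
    stop("design error: need 3 ck and 3 st replicates in tissue ", tissue,
         " (found ", length(ck), " ck, ", length(st), " st)")
  }
  m <- as.matrix(counts[, c(ck, st)])
  if (any(colSums(m) <= 0)) stop("zero library size")
  norm <- sweep(m, 2, estimate_size_factors(m), `/`)
  ck_i <- seq_along(ck); st_i <- length(ck) + seq_along(st)

  mean_ck <- rowMeans(norm[, ck_i, drop = FALSE])
  mean_st <- rowMeans(norm[, st_i, drop = FALSE])
  log2fc <- log2_pseudo(mean_st) - log2_pseudo(mean_ck)

  if (is.null(dispersion)) {
    mom <- function(idx) {
      k <- length(idx)
      mu <- rowMeans(norm[, idx, drop = FALSE])
      v <- apply(norm[, idx, drop = FALSE], 1, stats::var)
      # m^2 - v/k debiases the squared-mean denominator (E[m^2] = mu^2 +
      # var/k), which matters at 3 replicates
      den <- pmax(mu^2 - v / k, mu^2 * 0.25)
      ifelse(mu > 0, (v - mu) / den, NA_real_)
    }
    phi_raw <- pmax(0, rowMeans(cbind(mom(ck_i), mom(st_i)), na.rm = TRUE))
    phi_raw[is.nan(phi_raw)] <- NA_real_
    med <- stats::median(phi_raw, na.rm = TRUE)
    if (is.na(med)) med <- 0
    phi <- 0.5 * ifelse(is.na(phi_raw), med, phi_raw) + 0.5 * med
  } else {
    if (dispersion < 0) stop("dispersion must be >= 0")
    phi <- rep(dispersion, nrow(m))
  }

  s1 <- round(rowSums(norm[, ck_i, drop = FALSE]))
  s2 <- round(rowSums(norm[, st_i, drop = FALSE]))
  p <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_pvalue(s1[i], s2[i], phi[i], n_rep = length(ck))
  }, numeric(1))

  res <- tibble::tibble(
    feature_id = counts$feature_id,
    tissue = tissue,
    mean_ck = mean_ck,
    mean_st = mean_st,
    log2FC = log2fc,
    p_value = p
  )
  res$direction <- de_direction(res$log2FC, res$p_value, class, alpha, fc_cutoff)
  attr(res, "class_tested") <- class
  attr(res, "alpha") <- alpha
  attr(res, "fc_cutoff") <- fc_cutoff
  res
}

de_direction <- function(log2fc, p, class, alpha, fc_cutoff) {
  sig <- p < alpha
  if (class == "gene_like") {
    pass <- abs(log2fc) > fc_cutoff
  } else {
    pass <- abs(log2fc) >= log2(1.5)
  }
  ifelse(sig & pass & log2fc > 0, "up",
         ifelse(sig & pass & log2fc < 0, "down", "ns"))
}

#' Re-filter DE results at a relaxed p threshold
#'
#' Re-assigns directions from the stored raw p-values without recomputation;
#' the relaxed mode is flagged in the result (`relaxed` attribute) and
#' propagated by downstream network builders.
#'
#' @param results A [de_test()] result.
#' @param alpha Relaxed p cutoff (default 0.1).
#' @return The result tibble with updated `direction` and attributes.
#' @export
relax_threshold_mode <- function(results, alpha = 0.1) {
  class <- attr(results, "class_tested") %||% "gene_like"
  fc <- attr(results, "fc_cutoff") %||% 1
  results$direction <- de_direction(results$log2FC, results$p_value, class, alpha, fc)
  attr(results, "alpha") <- alpha
  attr(results, "relaxed") <- TRUE
  results
}

#' Relative expression by the comparative 2^-ddCt method
#'
#' @param ct_target_st,ct_ref_st Target and reference-gene Ct in treatment.
#' @param ct_target_ck,ct_ref_ck Target and reference-gene Ct in control.
#' @return 2^-((ct_target_st - ct_ref_st) - (ct_target_ck - ct_ref_ck)).
#' @export
delta_delta_ct <- function(ct_target_st, ct_ref_st, ct_target_ck, ct_ref_ck) {
  stopifnot(is.finite(ct_target_st), is.finite(ct_ref_st),
            is.finite(ct_target_ck), is.finite(ct_ref_ck))
  2^-((ct_target_st - ct_ref_st) - (ct_target_ck - ct_ref_ck))
}
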