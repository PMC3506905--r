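#' Per-tissue summaries of quantitative maps
#'
#' Mean, SD and voxel count of each quantitative parameter over each ROI
#' mask (ROI masks are expected to be disjoint, with validity/banding
#' exclusions and cortical-mask erosion already applied by the caller —
#' [run_pipeline()] does this). Empty ROIs are reported as rows with
#' `n = 0`, never silently dropped; single-voxel ROIs report `sd = 0` with
#' an `n = 1` flag.
#'
#' @param qmaps Named list of numeric 3D arrays (e.g. `t1`, `t2`, `m0`,
#'   `mtr`, `myelin`).
#' @param roi_masks Named list of logical 3D arrays.
#' @return Data frame with columns `tissue`, `parameter`, `mean`, `sd`, `n`.
#' @export
roi_summaries <- function(qmaps, roi_masks) {
  rows <- list()
  for (tis in names(roi_masks)) {
    m <- roi_masks[[tis]]
    for (p in names(qmaps)) {
      v <- qmaps[[p]][m]
      v <- v[is.finite(v)]
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tis, parameter = p,
        mean = if (n > 0) mean(v) else NA_real_,
        sd = if (n > 1) sd(v) else if (n == 1) 0 else NA_real_,
        n = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Two-sample group comparison with Bonferroni correction
#'
#' Two-sided two-sample t-test (Student's pooled-variance test by default,
#' matching the study design; Welch available because group variances can
#' differ severely), with the raw p-value multiplied by the number of
#' comparisons in the family and capped at 1. Identical constant groups
#' yield t = 0, p = 1 by convention.
#'
#' @param values_a,values_b Numeric vectors, n >= 2 each.
#' @param alpha Significance level (default 0.05).
#' @param n_comparisons Bonferroni family size (default 5: T1, T2, M0, MTR,
#'   myelin).
#' @param var_equal Pooled-variance Student test if `TRUE` (default), Welch
#'   otherwise.
#' @return List with `t`, `df`, `p_raw`, `p_corrected`, `significant`.
#' @export
group_compare <- function(values_a, values_b, alpha = 0.05,
                          n_comparisons = 5, var_equal = TRUE) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 finite values")
  near_const <- function(x) sd(x) < 1e-10 * (abs(mean(x)) + 1)
  if (near_const(values_a) && near_const(values_b)) {
    if (isTRUE(all.equal(mean(values_a), mean(values_b), tolerance = 1e-9))) {
      tt <- list(statistic = 0, parameter = length(values_a) +
                   length(values_b) - 2, p.value = 1)
    } else {
      tt <- list(statistic = Inf * sign(mean(values_a) - mean(values_b)),
                 parameter = length(values_a) + length(values_b) - 2,
                 p.value = 0)
    }
  } else {
    ht <- t.test(values_a, values_b, var.equal = var_equal,
                 alternative = "two.sided")
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  p_corr <- min(1, tt$p.value * n_comparisons)
  list(t = tt$statistic, df = tt$parameter, p_raw = tt$p.value,
       p_corrected = p_corr, significant = p_corr < alpha)
}

#' Pearson and Spearman correlation of a qMR parameter with myelin content
#'
#' Product-moment and rank correlation (tie-aware average ranks) with
#' p-values. Zero-variance input is reported as undefined, not an error.
#'
#' @param qvalues,myelin_values Paired numeric vectors (non-finite pairs
#'   dropped), n >= 3.
#' @return List with `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n`, `defined`.
#' @export
correlate <- function(qvalues, myelin_values) {
  ok <- is.finite(qvalues) & is.finite(myelin_values)
  x <- qvalues[ok]; y <- myelin_values[ok]
  if (length(x) < 3) stop("at least 3 paired finite values are required")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                n = length(x), defined = FALSE))
  pe <- suppressWarnings(cor.test(x, y, method = "pearson"))
  sp <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x), defined = TRUE)
}

#' Normalized histogram with flagged overflow bins
#'
#' Counts divided by the total number of values; values below the first or
#' above the last edge are counted in explicit underflow/overflow bins so
#' the frequencies always sum to 1.
#'
#' @param values Numeric vector with at least one finite value.
#' @param bin_edges Strictly increasing numeric vector of edges.
#' @return List with `bin_edges`, `frequencies` (length
#'   `length(bin_edges) - 1`), `underflow`, `overflow`, `n`.
#' @export
normalized_histogram <- function(values, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1) stop("at least one finite value is required")
  under <- sum(values < bin_edges[1])
  over <- sum(values >= bin_edges[length(bin_edges)])
  inside <- values[values >= bin_edges[1] &
                     values < bin_edges[length(bin_edges)]]
  idx <- findInterval(inside, bin_edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1)
  list(bin_edges = bin_edges, frequencies = counts / n,
       underflow = under / n, overflow = over / n, n = n)
}

#' Default histogram bin edges: uniform bins over a percentile range
#' @param values Pooled values.
#' @param n_bins Number of bins (default 64).
#' @param probs Percentile range (default 1st-99th).
#' @return Numeric vector of edges.
#' @export
histogram_edges <- function(values, n_bins = 64, probs = c(0.01, 0.99)) {
  rng <- quantile(values[is.finite(values)], probs, names = FALSE)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = n_bins + 1)
}

#' Overlap coefficient of two normalized histograms
#' @param h1,h2 Outputs of [normalized_histogram()] on shared edges.
#' @return Sum of pairwise bin minima (1 = identical, 0 = disjoint).
#' @export
histogram_overlap <- function(h1, h2) {
  stopifnot(identical(h1$bin_edges, h2$bin_edges))
  sum(pmin(h1$frequencies, h2$frequencies))
}
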