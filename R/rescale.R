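#' Select the extreme-coverage (artifact) outlier bins
#'
#' Picks the `k` bins with the highest coverage in the untreated track.
#' In ChIP-seq data these extreme bins are dominated by alignment artifacts:
#' they appear with very similar profiles in IP and input libraries, so the
#' ratio of their coverage between two libraries reflects sequencing depth
#' alone, not biology. Ties are broken by ascending genomic index so the
#' selection is deterministic.
#'
#' @param untreated Coverage tibble of the untreated (reference) track.
#' @param k Number of outlier bins (default 150).
#' @return A tibble of `k` rows with the grid columns plus `value`
#'   (the untreated coverage at the selected bins), ordered by bin index.
#' @export
select_outlier_bins <- function(untreated, k = 150) {
  n <- nrow(untreated)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k)) {
    abort("`k` must be a single integer >= 1")
  }
  if (k > n) abort(sprintf("k = %d exceeds the number of bins (%d)", k, n))
  if (sum(untreated$value > 0) < k) {
    abort(sprintf("fewer than k = %d bins with positive coverage", k))
  }
  ord <- order(-untreated$value, untreated$bin)
  sel <- sort(untreated$bin[ord[seq_len(k)]])
  out <- untreated[match(sel, untreated$bin), , drop = FALSE]
  as_tibble(out)
}

#' Fold-change distribution at outlier bins
#'
#' Per-bin treated/untreated coverage ratios at a set of outlier bins.
#' Bins where either track is zero are excluded from the ratio set and
#' counted as dropped (no pseudocounts: a pseudocount would bias ratios at
#' exactly the extreme-value bins the method relies on).
#'
#' @param treated,untreated Coverage tibbles on a shared grid.
#' @param outliers Outlier-bin tibble from [select_outlier_bins()].
#' @return A tibble with one row per retained bin: `bin`, `chrom`, `start`,
#'   `end`, `value_untreated`, `value_treated`, `fc`. Attributes `n_used`
#'   and `n_dropped` record the zero-coverage exclusions.
#' @export
fold_change_distribution <- function(treated, untreated, outliers) {
  check_same_grid(treated, untreated)
  idx <- match(outliers$bin, untreated$bin)
  if (anyNA(idx)) abort("outlier bins do not belong to the tracks' grid")
  u <- untreated$value[idx]
  t_ <- treated$value[idx]
  keep <- u > 0 & t_ > 0
  if (!any(keep)) abort("all outlier bins have zero coverage in one of the tracks")
  out <- tibble(
    bin = outliers$bin[keep],
    chrom = outliers$chrom[keep],
    start = outliers$start[keep],
    end = outliers$end[keep],
    value_untreated = u[keep],
    value_treated = t_[keep],
    fc = t_[keep] / u[keep]
  )
  attr(out, "n_used") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Estimate the between-condition depth-rescaling factor
#'
#' The central estimator: the median treated/untreated fold change over the
#' `k` highest-coverage bins of the untreated track estimates the ratio of
#' effective sequencing depths, and its reciprocal is the factor by which
#' the treated track must be multiplied so that artifact-bin signal matches
#' between conditions. After rescaling, any remaining genome-wide shift in
#' signal is attributable to biology (e.g. a global loss of the mark), not
#' depth.
#'
#' @param treated,untreated Coverage tibbles on a shared grid. `untreated`
#'   is the reference in which outliers are ranked; the returned factor
#'   multiplies `treated`.
#' @param k Number of outlier bins (default 150).
#' @return An object of class `scaling_fit`: a list with elements
#'   `fold_changes` (the per-bin tibble from [fold_change_distribution()]),
#'   `factor` (`1 / median_fc`), `median_fc`, `mean_fc` (diagnostic only),
#'   `k`, `n_used`, `n_dropped`, and `direction` (`"treated"`). Use
#'   [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' sim <- simulate_chip(sim_config(seed = 1), libraries = "ip")
#' fit <- estimate_scaling(sim$coverage$ip_treated, sim$coverage$ip_untreated)
#' glance(fit)
#' @export
estimate_scaling <- function(treated, untreated, k = 150) {
  outliers <- select_outlier_bins(untreated, k = k)
  fcs <- fold_change_distribution(treated, untreated, outliers)
  med <- median(fcs$fc)
  structure(
    list(
      fold_changes = fcs,
      factor = 1 / med,
      median_fc = med,
      mean_fc = mean(fcs$fc),
      k = k,
      n_used = attr(fcs, "n_used"),
      n_dropped = attr(fcs, "n_dropped"),
      direction = "treated"
    ),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("Depth-rescaling fit (outlier-bin method)\n")
  cat(sprintf("  k = %d outlier bins (%d used, %d dropped for zero coverage)\n",
              x$k, x$n_used, x$n_dropped))
  cat(sprintf("  median fold change (treated/untreated): %.4f\n", x$median_fc))
  cat(sprintf("  scaling factor for the %s track:        %.4f\n",
              x$direction, x$factor))
  invisible(x)
}

#' @rdname estimate_scaling
#' @param x A `scaling_fit` object.
#' @param ... Unused.
#' @export
tidy.scaling_fit <- function(x, ...) {
  as_tibble(x$fold_changes)
}

#' @rdname estimate_scaling
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble(
    factor = x$factor,
    median_fc = x$median_fc,
    mean_fc = x$mean_fc,
    k = x$k,
    n_used = x$n_used,
    n_dropped = x$n_dropped,
    direction = x$direction
  )
}

#' Input-library consistency check for the outlier-bin factor
#'
#' For input (whole-chromatin control) libraries no biological signal
#' change is expected, so the fold change of the total genomic coverage
#' between conditions should agree with the median fold change at the
#' outlier bins; a large gap would indicate the outlier bins do not track
#' depth. For the IP libraries of a mark undergoing global loss, the same
#' two quantities disagree — that gap is exactly the evidence that
#' rescaling is needed.
#'
#' The outlier bins passed in should be the ones selected from the
#' untreated IP track: artifact loci are shared between IP and input, and
#' using one set of loci makes the IP and input reports comparable.
#'
#' @param treated,untreated Coverage tibbles (typically the input
#'   libraries) on a shared grid.
#' @param outliers Outlier bins from [select_outlier_bins()] on the
#'   untreated IP track.
#' @param log2_tol Consistency tolerance on the |log2| gap (default 0.1).
#' @return A one-row tibble: `total_fc`, `outlier_median_fc`,
#'   `abs_log2_gap`, `consistent`, `log2_tol`, `n_used`, `n_dropped`.
#' @export
check_input_consistency <- function(treated, untreated, outliers, log2_tol = 0.1) {
  check_same_grid(treated, untreated)
  tot_t <- coverage_total_bases(treated)
  tot_u <- coverage_total_bases(untreated)
  if (tot_t <= 0 || tot_u <= 0) abort("zero total coverage in one of the tracks")
  fcs <- fold_change_distribution(treated, untreated, outliers)
  total_fc <- tot_t / tot_u
  med <- median(fcs$fc)
  gap <- abs(log2(total_fc) - log2(med))
  tibble(
    total_fc = total_fc,
    outlier_median_fc = med,
    abs_log2_gap = gap,
    consistent = gap <= log2_tol,
    log2_tol = log2_tol,
    n_used = attr(fcs, "n_used"),
    n_dropped = attr(fcs, "n_dropped")
  )
}

#' Sensitivity of the scaling factor to the outlier threshold
#'
#' Re-estimates the factor for several values of `k` and summarises the
#' spread. A small relative spread supports the claim that the estimate
#' does not hinge on the exact number of outlier bins considered.
#'
#' @param treated,untreated Coverage tibbles on a shared grid.
#' @param k_values Integer vector of outlier counts
#'   (default `c(50, 100, 150, 300, 500)`).
#' @return A tibble of class `k_sweep` with one row per `k`: `k`, `factor`,
#'   `median_fc`, `n_used`, `n_dropped`. `glance()` gives the relative
#'   spread `(max - min) / median` of the factors.
#' @export
sweep_outlier_k <- function(treated, untreated, k_values = c(50, 100, 150, 300, 500)) {
  if (length(k_values) < 1L) abort("`k_values` must be non-empty")
  rows <- purrr::map(k_values, function(k) {
    fit <- estimate_scaling(treated, untreated, k = k)
    tibble(k = k, factor = fit$factor, median_fc = fit$median_fc,
           n_used = fit$n_used, n_dropped = fit$n_dropped)
  })
  out <- bind_rows(rows)
  class(out) <- c("k_sweep", class(out))
  out
}

#' @rdname sweep_outlier_k
#' @param x A `k_sweep` tibble.
#' @param ... Unused.
#' @export
glance.k_sweep <- function(x, ...) {
  tibble(
    n_k = nrow(x),
    factor_min = min(x$factor),
    factor_max = max(x$factor),
    relative_spread = (max(x$factor) - min(x$factor)) / median(x$factor)
  )
}
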