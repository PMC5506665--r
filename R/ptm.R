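#' Read and validate a histone-PTM relative-abundance table
#'
#' The table holds, per residue site (e.g. `H3K9`), modification state
#' (`me0`, `me1`, `me2`, `me3`, `ac`, ...), condition and replicate, the
#' relative abundance of that state as a fraction of the site's peptide
#' pool. Within each (site, condition, replicate) the state fractions must
#' sum to 1 within `tol` — enforced on load, since downstream ratios are
#' meaningless otherwise.
#'
#' @param path CSV file with columns `site`, `state`, `condition`,
#'   `replicate`, `abundance`.
#' @param table A data frame with those columns (for `validate_ptm_table`).
#' @param tol Tolerance on the per-(site, condition, replicate) abundance
#'   sum (default 0.01).
#' @return A validated tibble.
#' @export
read_ptm_table <- function(path, tol = 0.01) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_ptm_table(tab, tol = tol)
}

#' @rdname read_ptm_table
#' @export
validate_ptm_table <- function(table, tol = 0.01) {
  need <- c("site", "state", "condition", "replicate", "abundance")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L) {
    abort(sprintf("PTM table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(table$abundance < 0)) abort("negative abundance in PTM table")
  sums <- table |>
    group_by(.data$site, .data$condition, .data$replicate) |>
    summarise(total = sum(.data$abundance), .groups = "drop")
  bad <- sums[abs(sums$total - 1) > tol, , drop = FALSE]
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "state abundances do not sum to 1 (tol %.3g) for %s / %s / replicate %s (sum %.4f)",
      tol, bad$site[1L], bad$condition[1L], as.character(bad$replicate[1L]), bad$total[1L]))
  }
  as_tibble(table)
}

#' Replicate-level fractions of one modification state
#'
#' @param table Validated PTM table.
#' @param site Residue site, e.g. `"H3K9"`.
#' @param state Modification state, e.g. `"me0"`.
#' @return A list with `replicates` (tibble `condition`, `replicate`,
#'   `percent`) and `means` (tibble `condition`, `mean_percent`), both as
#'   percentages of the site's peptide pool.
#' @export
ptm_fractions <- function(table, site, state) {
  sel <- table[table$site == site & table$state == state, , drop = FALSE]
  if (nrow(sel) == 0L) {
    abort(sprintf("no rows for site '%s', state '%s'", site, state))
  }
  reps <- tibble(
    condition = sel$condition,
    replicate = sel$replicate,
    percent = 100 * sel$abundance
  )
  means <- reps |>
    group_by(.data$condition) |>
    summarise(mean_percent = mean(.data$percent), .groups = "drop")
  list(replicates = reps, means = means)
}

#' Compare PTM abundances between two conditions
#'
#' Per (site, state): condition means, the log2 ratio of means
#' (treated/untreated), the mean of per-replicate log2 ratios as a
#' secondary summary, and a two-sided Welch t-test across replicates.
#' Results are ranked by |log2 ratio|. No multiple-testing correction is
#' applied to `p_value` (per-mark tests are reported as-is); a
#' Benjamini-Hochberg column `p_adj` is added for transparency.
#'
#' @param table Validated PTM table with exactly the two conditions named.
#' @param treated,untreated Condition labels (defaults `"treated"`,
#'   `"untreated"`).
#' @return A tibble of class `ptm_comparison`, sorted by decreasing
#'   `abs(log2_ratio)`: `site`, `state`, `mean_untreated`, `mean_treated`,
#'   `log2_ratio`, `mean_rep_log2_ratio`, `p_value`, `p_adj`, `rank`.
#'   With fewer than 2 replicates per condition, p-values are `NA` with a
#'   warning; ratios are still reported.
#' @export
compare_ptm <- function(table, treated = "treated", untreated = "untreated") {
  for (cond in c(treated, untreated)) {
    if (!cond %in% table$condition) {
      abort(sprintf("condition '%s' not present in the PTM table", cond))
    }
  }
  cells <- table |>
    filter(.data$condition %in% c(treated, untreated)) |>
    group_by(.data$site, .data$state) |>
    tidyr::nest() |>
    ungroup()
  warned <- FALSE
  rows <- purrr::pmap(list(cells$site, cells$state, cells$data), function(si, st, d) {
    u <- d$abundance[d$condition == untreated]
    t_ <- d$abundance[d$condition == treated]
    mu <- mean(u); mt <- mean(t_)
    lr <- if (mu > 0 && mt > 0) log2(mt / mu) else NA_real_
    rep_lr <- if (length(u) == length(t_) && all(u > 0) && all(t_ > 0)) {
      mean(log2(t_ / u))
    } else NA_real_
    p <- NA_real_
    if (length(u) >= 2L && length(t_) >= 2L) {
      p <- tryCatch(t.test(t_, u, var.equal = FALSE)$p.value, error = function(e) NA_real_)
    } else {
      warned <<- TRUE
    }
    tibble(site = si, state = st, mean_untreated = mu, mean_treated = mt,
           log2_ratio = lr, mean_rep_log2_ratio = rep_lr, p_value = p)
  })
  out <- bind_rows(rows)
  if (warned) warn("fewer than 2 replicates in a condition: p-values omitted for affected states")
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out <- arrange(out, desc(abs(.data$log2_ratio)))
  out$rank <- seq_len(nrow(out))
  attr(out, "test") <- "Welch two-sample t-test, two-sided"
  attr(out, "treated") <- treated
  attr(out, "untreated") <- untreated
  class(out) <- c("ptm_comparison", class(out))
  out
}

#' @rdname compare_ptm
#' @param x A `ptm_comparison` tibble.
#' @param ... Unused.
#' @export
glance.ptm_comparison <- function(x, ...) {
  top <- x[1L, , drop = FALSE]
  tibble(
    n_states = nrow(x),
    top_site = top$site,
    top_state = top$state,
    top_log2_ratio = top$log2_ratio,
    top_p_value = top$p_value,
    n_significant = sum(x$p_value < 0.05, na.rm = TRUE),
    test = attr(x, "test")
  )
}
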