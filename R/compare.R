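#' Genome-wide Pearson correlation between two coverage tracks
#'
#' Correlates per-bin values over the bins that are nonzero in at least one
#' track (all-zero bins are uninformative padding). Pearson correlation is
#' invariant to positive rescaling of either track, so it measures whether
#' the *distribution* of the mark is preserved, independently of a global
#' level change.
#'
#' @param a,b Coverage tibbles on a shared grid.
#' @param transform `"raw"` (default) or `"log2p1"` (log2(x + 1)).
#' @return A one-row tibble: `r`, `n_bins_used`, `transform`.
#' @export
coverage_cor <- function(a, b, transform = c("raw", "log2p1")) {
  transform <- match.arg(transform)
  check_same_grid(a, b)
  keep <- a$value > 0 | b$value > 0
  x <- a$value[keep]
  y <- b$value[keep]
  if (transform == "log2p1") {
    x <- log2(x + 1)
    y <- log2(y + 1)
  }
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("cannot compute a correlation: fewer than 2 informative bins or zero variance")
  }
  tibble(r = cor(x, y, method = "pearson"), n_bins_used = length(x), transform = transform)
}

#' Per-bin fold-change track
#'
#' Treated/untreated ratio in every bin with positive untreated coverage;
#' bins where the ratio is undefined are kept and flagged (`defined =
#' FALSE`, `fc = NA`), never silently dropped.
#'
#' @param treated,untreated Coverage tibbles on a shared grid (the treated
#'   track normally rescaled first, see [scale_coverage()]).
#' @return The grid tibble with `value_untreated`, `value_treated`, `fc`,
#'   `defined`.
#' @export
bin_fold_change <- function(treated, untreated) {
  check_same_grid(treated, untreated)
  defined <- untreated$value > 0
  fc <- ifelse(defined, treated$value / untreated$value, NA_real_)
  tibble(
    bin = untreated$bin,
    chrom = untreated$chrom,
    start = untreated$start,
    end = untreated$end,
    value_untreated = untreated$value,
    value_treated = treated$value,
    fc = fc,
    defined = defined
  )
}

#' Read gene annotation from BED6
#'
#' @param path BED6 file (chrom, start, end, gene_id, score, strand).
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  tibble(
    gene_id = if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene_", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = strand
  )
}

#' Promoter windows around transcription start sites
#'
#' One symmetric window per gene, `[tss - flank, tss + flank)`, clipped to
#' the sequence bounds. The TSS follows the BED convention: interval start
#' for `+`-strand genes, interval end for `-`-strand genes; strand is used
#' only to locate the TSS.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`),
#'   e.g. from [read_genes_bed()].
#' @param layout Genome layout tibble (for clipping).
#' @param flank Half-width of the window in bp (default 2000, i.e.
#'   TSS +/- 2 kb).
#' @return A tibble with `gene_id`, `chrom`, `tss`, `strand`, `start`,
#'   `end` (the window, 0-based half-open).
#' @export
promoter_windows <- function(genes, layout, flank = 2000) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  unknown <- setdiff(unique(genes$chrom), layout$chrom)
  if (length(unknown) > 0L) {
    abort(sprintf("gene(s) on sequence(s) absent from the layout: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  chrom_len <- setNames(layout$length, layout$chrom)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    tss = tss,
    strand = genes$strand,
    start = pmax(tss - flank, 0),
    end = pmin(tss + flank, chrom_len[genes$chrom])
  )
}

#' Mean signal per feature window
#'
#' Mean per-base signal over each window, computed from the binned track
#' with bins weighted by their overlap length (each base inherits its bin's
#' mean value).
#'
#' @param cov Coverage tibble.
#' @param windows Window tibble from [promoter_windows()] (needs `gene_id`,
#'   `chrom`, `start`, `end`).
#' @return A tibble `gene_id`, `chrom`, `start`, `end`, `mean_signal`;
#'   windows empty after clipping get `NA` and are flagged via `empty`.
#' @export
window_signal <- function(cov, windows) {
  layout <- grid_layout(cov)
  unknown <- setdiff(unique(windows$chrom), layout$chrom)
  if (length(unknown) > 0L) {
    abort(sprintf("window(s) on sequence(s) absent from the layout: %s",
                  paste(unknown, collapse = ", ")))
  }
  res <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    wsel <- which(windows$chrom == ch)
    bsel <- cov$chrom == ch
    # per-base track where each base carries its bin's mean value
    rle <- S4Vectors::Rle(cov$value[bsel], cov$end[bsel] - cov$start[bsel])
    st <- pmax(windows$start[wsel], 0)
    en <- pmin(windows$end[wsel], length(rle))
    ok <- st < en
    if (any(ok)) {
      v <- IRanges::Views(rle, start = st[ok] + 1, end = en[ok])
      res[wsel[ok]] <- IRanges::viewMeans(v)
    }
  }
  tibble(
    gene_id = windows$gene_id,
    chrom = windows$chrom,
    start = windows$start,
    end = windows$end,
    mean_signal = res,
    empty = is.na(res)
  )
}

#' Ranked promoter fold changes between conditions
#'
#' Computes the mean signal per promoter window in each condition (on the
#' window means, not on averaged per-bin ratios), forms the
#' treated/untreated fold change, and sorts promoters by decreasing fold
#' change — the classic "sorted fold change" display for a global loss:
#' when the mark is lost genome-wide, nearly the whole curve sits below 1.
#'
#' @param treated,untreated Coverage tibbles on a shared grid; pass the
#'   depth-rescaled treated track.
#' @param windows Promoter windows from [promoter_windows()].
#' @return A tibble of class `promoter_fc`, sorted by decreasing `fc`:
#'   `gene_id`, `mean_untreated`, `mean_treated`, `fc`, `log2_fc`,
#'   `defined`. `glance()` reports the fraction of defined promoters with
#'   `fc < 1`.
#' @export
promoter_fold_change <- function(treated, untreated, windows) {
  check_same_grid(treated, untreated)
  mu <- window_signal(untreated, windows)
  mt <- window_signal(treated, windows)
  defined <- !mu$empty & !mt$empty & mu$mean_signal > 0
  fc <- ifelse(defined, mt$mean_signal / mu$mean_signal, NA_real_)
  if (!any(defined)) abort("no promoter has a defined fold change")
  out <- tibble(
    gene_id = mu$gene_id,
    mean_untreated = mu$mean_signal,
    mean_treated = mt$mean_signal,
    fc = fc,
    log2_fc = log2(fc),
    defined = defined
  )
  out <- arrange(out, desc(.data$fc))
  class(out) <- c("promoter_fc", class(out))
  out
}

#' @rdname promoter_fold_change
#' @param x A `promoter_fc` tibble.
#' @param ... Unused.
#' @export
glance.promoter_fc <- function(x, ...) {
  def <- x[x$defined, , drop = FALSE]
  tibble(
    n_promoters = nrow(x),
    n_defined = nrow(def),
    frac_reduced = mean(def$fc < 1),
    median_fc = median(def$fc)
  )
}
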