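#' Read aligned DNA fragments from BED or BEDPE
#'
#' One record is one sequenced DNA fragment (the span of a properly paired
#' read pair). BED3+ files are taken as the fragment interval directly;
#' BEDPE records are collapsed to the fragment span
#' `[min(start1, start2), max(end1, end2))`, and must have both ends on the
#' same sequence.
#'
#' @param path Path to a BED3(+) or BEDPE file (uncompressed text).
#' @param format `"auto"` (by extension: `.bedpe` vs anything else),
#'   `"bed"`, or `"bedpe"`.
#' @return A fragment tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
read_fragments <- function(path, format = c("auto", "bed", "bedpe")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bedpe$", path, ignore.case = TRUE)) "bedpe" else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    frags <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = as.numeric(GenomicRanges::end(gr))
    )
  } else {
    tab <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (ncol(tab) < 6L) abort("BEDPE file needs at least 6 columns")
    if (any(tab[[1]] != tab[[4]])) {
      abort("BEDPE record with mates on different sequences cannot form a fragment")
    }
    s1 <- as.numeric(tab[[2]]); s2 <- as.numeric(tab[[5]])
    e1 <- as.numeric(tab[[3]]); e2 <- as.numeric(tab[[6]])
    frags <- tibble(chrom = tab[[1]], start = pmin(s1, s2), end = pmax(e1, e2))
  }
  if (any(frags$start >= frags$end)) abort("fragment with start >= end")
  frags
}

#' Mean fragment coverage in genome bins
#'
#' Computes, for every bin of a grid, the mean per-base depth of the given
#' fragments: total fragment bases overlapping the bin divided by the bin
#' length. The sum of `value * (end - start)` over all bins equals the total
#' number of fragment bases (after clipping), which makes the computation
#' checkable against a per-base accumulation.
#'
#' Fragments extending past the end of their sequence are clipped to the
#' sequence bounds with a warning; fragments on sequences absent from the
#' grid are an error.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`), e.g. from
#'   [read_fragments()] or [simulate_chip()].
#' @param bins Bin grid from [bin_genome()].
#' @return The grid tibble with an added `value` column (mean per-base
#'   depth per bin).
#' @examples
#' grid <- bin_genome(genome_layout("chrA", 1000), 500)
#' bin_coverage(tibble::tibble(chrom = "chrA", start = 250, end = 750), grid)
#' @export
bin_coverage <- function(fragments, bins) {
  stopifnot(is.data.frame(fragments), all(c("chrom", "start", "end") %in% names(fragments)))
  layout <- grid_layout(bins)
  unknown <- setdiff(unique(fragments$chrom), layout$chrom)
  if (length(unknown) > 0L) {
    abort(sprintf("fragments on sequence(s) absent from the genome layout: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (nrow(fragments) > 0L && any(fragments$start >= fragments$end)) {
    abort("fragment with start >= end")
  }
  chrom_len <- setNames(layout$length, layout$chrom)
  values <- numeric(nrow(bins))
  clipped <- FALSE
  for (ch in layout$chrom) {
    sel <- bins$chrom == ch
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(fr) == 0L) next
    len <- chrom_len[[ch]]
    st <- pmax(fr$start, 0)
    en <- fr$end
    if (any(en > len) || any(fr$start < 0)) {
      clipped <- TRUE
      en <- pmin(en, len)
    }
    keep <- st < en
    st <- st[keep]; en <- en[keep]
    cov <- IRanges::coverage(IRanges::IRanges(start = st + 1, end = en), width = len)
    v <- IRanges::Views(cov, start = bins$start[sel] + 1, end = bins$end[sel])
    values[sel] <- IRanges::viewMeans(v)
  }
  if (clipped) warn("fragments extending beyond sequence bounds were clipped")
  out <- bins
  out$value <- values
  attr(out, "bin_size") <- attr(bins, "bin_size")
  attr(out, "layout") <- layout
  out
}

#' Total fragment bases represented by a coverage track
#'
#' @param cov Coverage tibble (grid columns plus `value`).
#' @return `sum(value * (end - start))`.
#' @export
coverage_total_bases <- function(cov) {
  sum(cov$value * (cov$end - cov$start))
}

#' Multiply a coverage track by a scaling factor
#'
#' Used to apply an estimated depth-rescaling factor (see
#' [estimate_scaling()]) to the treated track before downstream comparisons.
#'
#' @param cov Coverage tibble.
#' @param factor Positive multiplier.
#' @return The track with every bin value (and hence its total bases)
#'   multiplied by `factor`.
#' @export
scale_coverage <- function(cov, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    abort("`factor` must be a single positive number")
  }
  cov$value <- cov$value * factor
  cov
}

#' Write / read a binned coverage track as bedGraph
#'
#' `write_bedgraph()` writes one record per bin; bins with value 0 are
#' omitted (zero-suppressed, as is conventional). `read_bedgraph()` reads a
#' track back onto a given grid: every record must coincide exactly with one
#' grid bin, and bins without a record are restored as 0.
#'
#' @param cov Coverage tibble.
#' @param path Output / input file path.
#' @param bins Bin grid the records must align to.
#' @return `read_bedgraph()` returns a coverage tibble on `bins`;
#'   `write_bedgraph()` returns `path` invisibly.
#' @export
write_bedgraph <- function(cov, path) {
  keep <- cov$value != 0
  gr <- GenomicRanges::GRanges(
    seqnames = cov$chrom[keep],
    ranges = IRanges::IRanges(start = cov$start[keep] + 1, end = cov$end[keep]),
    score = cov$value[keep]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, bins) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  rec <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    value = as.numeric(gr$score)
  )
  key <- paste(bins$chrom, bins$start, bins$end)
  idx <- match(paste(rec$chrom, rec$start, rec$end), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    abort(sprintf("bedGraph record %s:%d-%d does not match a grid bin",
                  rec$chrom[bad], rec$start[bad], rec$end[bad]))
  }
  out <- bins
  out$value <- 0
  out$value[idx] <- rec$value
  out
}
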