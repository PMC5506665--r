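#' Call broad enriched domains from binned IP and input coverage
#'
#' A deliberately simple threshold-and-merge caller suited to broad,
#' domain-forming histone marks: bins whose IP/input ratio reaches
#' `min_ratio` are marked, marked runs separated by gaps of at most
#' `merge_gap` bp are merged, and merged runs shorter than `min_len` bp are
#' dropped. Bins with zero input are given the genome-wide mean input value
#' as denominator, which avoids infinite ratios while leaving artifact bins
#' (high in IP *and* input) callable on their true ratio.
#'
#' @param ip,input Coverage tibbles on a shared grid.
#' @param min_ratio Minimum IP/input ratio for a bin to be marked
#'   (default 1.5; must be > 1).
#' @param min_len Minimum region length in bp after merging (default 2000).
#' @param merge_gap Maximum gap in bp bridged between marked runs
#'   (default 1000).
#' @return A region tibble (`chrom`, `start`, `end`), sorted in layout
#'   order, non-overlapping and non-abutting, with attribute
#'   `n_zero_input_bins` flagging how many bins used the fallback
#'   denominator.
#' @export
call_domains <- function(ip, input, min_ratio = 1.5, min_len = 2000, merge_gap = 1000) {
  check_same_grid(ip, input)
  if (!is.numeric(min_ratio) || min_ratio <= 1) abort("`min_ratio` must be > 1")
  denom <- input$value
  zero_in <- denom <= 0
  mean_input <- mean(input$value)
  if (mean_input <= 0) abort("input track has zero coverage everywhere")
  denom[zero_in] <- mean_input
  marked <- ip$value / denom >= min_ratio
  layout <- grid_layout(ip)
  regions <- purrr::map(layout$chrom, function(ch) {
    sel <- ip$chrom == ch & marked
    if (!any(sel)) return(NULL)
    ir <- IRanges::reduce(
      IRanges::IRanges(start = ip$start[sel] + 1, end = ip$end[sel]),
      min.gapwidth = merge_gap + 1
    )
    ir <- ir[IRanges::width(ir) >= min_len]
    if (length(ir) == 0L) return(NULL)
    tibble(chrom = ch, start = IRanges::start(ir) - 1, end = as.numeric(IRanges::end(ir)))
  })
  out <- bind_rows(regions)
  if (nrow(out) == 0L) out <- tibble(chrom = character(), start = numeric(), end = numeric())
  attr(out, "n_zero_input_bins") <- sum(zero_in)
  attr(out, "layout") <- layout
  out
}

# region tibble -> per-chrom reduced IRanges list (1-based closed internally)
regions_to_irl <- function(regions, chroms) {
  setNames(lapply(chroms, function(ch) {
    sel <- regions$chrom == ch
    IRanges::reduce(IRanges::IRanges(start = regions$start[sel] + 1,
                                     end = regions$end[sel]))
  }), chroms)
}

#' Base-pair overlap between two region sets
#'
#' Three-way base-pair partition (A-only, B-only, shared) plus the Jaccard
#' index, and region-count summaries (how many regions of each set touch
#' the other) — the two usual ways of drawing the Venn diagram for
#' enriched-region overlap between conditions.
#'
#' @param a,b Region tibbles (`chrom`, `start`, `end`), e.g. from
#'   [call_domains()]. Overlapping records within a set are merged first.
#' @return A one-row tibble: `bp_a_only`, `bp_b_only`, `bp_shared`,
#'   `jaccard`, `n_a`, `n_b`, `n_a_hit_b`, `n_b_hit_a`.
#' @export
region_overlap <- function(a, b) {
  chroms <- union(unique(a$chrom), unique(b$chrom))
  irl_a <- regions_to_irl(a, chroms)
  irl_b <- regions_to_irl(b, chroms)
  bp_a <- bp_b <- bp_shared <- 0
  n_a_hit <- n_b_hit <- 0
  for (ch in chroms) {
    ia <- irl_a[[ch]]; ib <- irl_b[[ch]]
    inter <- IRanges::intersect(ia, ib)
    bp_shared <- bp_shared + sum(IRanges::width(inter))
    bp_a <- bp_a + sum(IRanges::width(ia))
    bp_b <- bp_b + sum(IRanges::width(ib))
    n_a_hit <- n_a_hit + sum(IRanges::overlapsAny(ia, ib))
    n_b_hit <- n_b_hit + sum(IRanges::overlapsAny(ib, ia))
  }
  union_bp <- bp_a + bp_b - bp_shared
  tibble(
    bp_a_only = bp_a - bp_shared,
    bp_b_only = bp_b - bp_shared,
    bp_shared = bp_shared,
    jaccard = if (union_bp > 0) bp_shared / union_bp else 0,
    n_a = sum(vapply(irl_a, length, integer(1L))),
    n_b = sum(vapply(irl_b, length, integer(1L))),
    n_a_hit_b = n_a_hit,
    n_b_hit_a = n_b_hit
  )
}

#' Read / write region sets as BED3
#'
#' @param path BED file path.
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @return `read_regions_bed()` returns a region tibble;
#'   `write_regions_bed()` returns `path` invisibly.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' @rdname read_regions_bed
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end)
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
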