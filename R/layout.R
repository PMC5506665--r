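#' Genome layout: an ordered table of sequence lengths
#'
#' A genome layout is a tibble with columns `chrom` (character) and `length`
#' (positive integer bp). Row order is the canonical sequence order and is
#' preserved by every structure derived from it (bin grids, coverage tracks,
#' region sets).
#'
#' @param chrom Character vector of sequence names (unique).
#' @param length Integer vector of sequence lengths in bp (positive).
#' @return A tibble with columns `chrom`, `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(5e6, 5e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) {
    abort("genome layout must contain at least one sequence")
  }
  if (anyDuplicated(chrom)) {
    dup <- chrom[duplicated(chrom)][1L]
    abort(sprintf("duplicate sequence name in genome layout: '%s'", dup))
  }
  if (any(!is.finite(length) | length <= 0 | length != floor(length))) {
    bad <- which(!is.finite(length) | length <= 0 | length != floor(length))[1L]
    abort(sprintf("sequence '%s' has non-positive or non-integer length", chrom[bad]))
  }
  tibble(chrom = chrom, length = length)
}

#' Read a chrom.sizes file
#'
#' Parses the UCSC-style two-column TSV of sequence name and length.
#'
#' @param path Path to a `name<TAB>length` text file.
#' @return A genome layout tibble (see [genome_layout()]), in file order.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("chrom.sizes file '%s' is empty", path))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L || is.na(suppressWarnings(as.numeric(p[2L])))) {
      abort(sprintf("malformed chrom.sizes line %d: '%s'", i, lines[i]))
    }
  }
  chrom <- vapply(parts, `[`, character(1L), 1L)
  len <- as.numeric(vapply(parts, `[`, character(1L), 2L))
  for (i in seq_along(chrom)) {
    if (len[i] <= 0) abort(sprintf("non-positive length on chrom.sizes line %d: '%s'", i, lines[i]))
    if (chrom[i] %in% chrom[seq_len(i - 1L)]) {
      abort(sprintf("duplicate sequence name on chrom.sizes line %d: '%s'", i, chrom[i]))
    }
  }
  genome_layout(chrom, len)
}

#' Tile a genome into fixed-width bins
#'
#' Each sequence is tiled left-to-right with half-open, 0-based bins of
#' `bin_size` bp; the final bin of a sequence keeps its true (possibly
#' shorter) length, so a sequence of length L yields `ceiling(L / bin_size)`
#' bins. The default 500 bp matches the resolution commonly used for broad
#' histone marks.
#'
#' @param layout A genome layout tibble from [genome_layout()].
#' @param bin_size Bin width in bp (default 500).
#' @return A tibble with columns `bin` (1-based index over the whole
#'   genome, in layout order), `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' bin_genome(genome_layout("chrA", 1250), bin_size = 500)
#' @export
bin_genome <- function(layout, bin_size = 500) {
  stopifnot(is.data.frame(layout), all(c("chrom", "length") %in% names(layout)))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size < 1 ||
      bin_size != floor(bin_size)) {
    abort("`bin_size` must be a single integer >= 1")
  }
  per_chrom <- purrr::map2(layout$chrom, layout$length, function(ch, len) {
    starts <- seq(0, len - 1, by = bin_size)
    tibble(chrom = ch, start = starts, end = pmin(starts + bin_size, len))
  })
  grid <- bind_rows(per_chrom)
  grid <- tibble(bin = seq_len(nrow(grid)), grid)
  attr(grid, "bin_size") <- bin_size
  attr(grid, "layout") <- layout
  grid
}

# Layout recovered from a grid/coverage tibble (attribute if present,
# otherwise reconstructed from the bin boundaries).
grid_layout <- function(bins) {
  lay <- attr(bins, "layout")
  if (!is.null(lay)) return(lay)
  bins |>
    group_by(.data$chrom) |>
    summarise(length = max(.data$end), .groups = "drop") |>
    (\(d) genome_layout(d$chrom, d$length))()
}

# Two tracks/grids share a grid iff chrom/start/end agree row by row.
check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(as.character(a$chrom), as.character(b$chrom)) ||
      !identical(as.numeric(a$start), as.numeric(b$start)) ||
      !identical(as.numeric(a$end), as.numeric(b$end))) {
    abort("coverage tracks are not on the same bin grid")
  }
  invisible(TRUE)
}
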