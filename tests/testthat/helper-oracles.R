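# Brute-force oracles, independent of the package's IRanges-based code
# paths: everything here works on explicit per-base vectors.

# Per-base depth accumulation, then per-bin mean.
oracle_bin_coverage <- function(fragments, layout, bin_size) {
  out <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]
    len <- layout$length[i]
    depth <- numeric(len)
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(fr) > 0) {
      for (j in seq_len(nrow(fr))) {
        s <- max(fr$start[j], 0) + 1
        e <- min(fr$end[j], len)
        if (s <= e) depth[s:e] <- depth[s:e] + 1
      }
    }
    starts <- seq(0, len - 1, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    vals <- vapply(seq_along(starts),
                   function(k) mean(depth[(starts[k] + 1):ends[k]]), numeric(1))
    out[[i]] <- tibble::tibble(chrom = ch, start = starts, end = ends, value = vals)
  }
  dplyr::bind_rows(out)
}

# Per-base membership partition of two region sets.
oracle_overlap <- function(a, b, chrom_lens) {
  bp_a_only <- bp_b_only <- bp_shared <- 0
  for (ch in names(chrom_lens)) {
    in_a <- logical(chrom_lens[[ch]])
    in_b <- logical(chrom_lens[[ch]])
    ra <- a[a$chrom == ch, , drop = FALSE]
    rb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(ra) > 0) for (j in seq_len(nrow(ra))) in_a[(ra$start[j] + 1):ra$end[j]] <- TRUE
    if (nrow(rb) > 0) for (j in seq_len(nrow(rb))) in_b[(rb$start[j] + 1):rb$end[j]] <- TRUE
    bp_a_only <- bp_a_only + sum(in_a & !in_b)
    bp_b_only <- bp_b_only + sum(!in_a & in_b)
    bp_shared <- bp_shared + sum(in_a & in_b)
  }
  list(bp_a_only = bp_a_only, bp_b_only = bp_b_only, bp_shared = bp_shared,
       jaccard = if (bp_a_only + bp_b_only + bp_shared > 0)
         bp_shared / (bp_a_only + bp_b_only + bp_shared) else 0)
}

# Textbook Pearson correlation from sums, independent of stats::cor.
oracle_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Welch two-sample two-sided t-test p-value from the formulas.
oracle_welch_p <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(tt), df)
}

# Single-sequence coverage track with full-width bins and given values.
make_cov <- function(values, bin_size = 500, chrom = "chrA") {
  layout <- chipscale::genome_layout(chrom, length(values) * bin_size)
  grid <- chipscale::bin_genome(layout, bin_size)
  grid$value <- as.numeric(values)
  grid
}

# Random fragment set on a given layout; fragments may straddle bins and
# occasionally touch the sequence end.
random_fragments <- function(layout, n) {
  ch_idx <- sample.int(nrow(layout), n, replace = TRUE)
  len <- layout$length[ch_idx]
  start <- floor(runif(n) * (len - 1))
  width <- pmax(1, floor(runif(n) * 600))
  tibble::tibble(chrom = layout$chrom[ch_idx], start = start,
                 end = pmin(start + width, len))
}

# Random merged region set on chroms given as a named length vector.
random_regions <- function(chrom_lens, n) {
  ch <- sample(names(chrom_lens), n, replace = TRUE)
  len <- unname(chrom_lens[ch])
  start <- floor(runif(n) * (len - 1))
  width <- pmax(1, floor(runif(n) * (len / 4)))
  tibble::tibble(chrom = ch, start = start, end = pmin(start + width, len))
}
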