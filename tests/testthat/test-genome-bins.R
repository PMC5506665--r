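test_that("chrom.sizes parsing keeps order and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".chrom.sizes")
  writeLines(c("chrA\t1000", "chrB\t700"), path)
  lay <- read_chrom_sizes(path)
  expect_equal(lay$chrom, c("chrA", "chrB"))
  expect_equal(lay$length, c(1000, 700))
  expect_equal(sum(lay$length), 1700)

  writeLines(c("chrA\t1000", "chrA\t500"), path)
  expect_error(read_chrom_sizes(path), "duplicate")
  writeLines(c("chrA\t-5"), path)
  expect_error(read_chrom_sizes(path), "non-positive")
  writeLines(character(), path)
  expect_error(read_chrom_sizes(path), "empty")
  expect_error(genome_layout(c("a", "a"), c(1, 2)), "duplicate")
})

test_that("bin grid tiles each sequence with a true-length terminal bin", {
  g1 <- bin_genome(genome_layout("chrA", 1500), 500)
  expect_equal(nrow(g1), 3)
  expect_true(all(g1$end - g1$start == 500))

  g2 <- bin_genome(genome_layout("chrA", 1250), 500)
  expect_equal(nrow(g2), 3)
  expect_equal(g2$start[3], 1000)
  expect_equal(g2$end[3], 1250)

  g3 <- bin_genome(genome_layout(c("chrA", "chrB"), c(1000, 700)), 500)
  expect_equal(nrow(g3), 4)
  # gapless, non-overlapping tiling per sequence
  for (ch in c("chrA", "chrB")) {
    sub <- g3[g3$chrom == ch, ]
    expect_equal(sub$start, c(0, 500))
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])
  }
  expect_error(bin_genome(genome_layout("chrA", 1000), 0), "bin_size")
})

test_that("bin grids are deterministic and sized ceil(length / bin_size)", {
  set.seed(11)
  for (i in 1:20) {
    lens <- sample(100:5000, sample(1:4, 1))
    bs <- sample(c(100, 250, 500, 333), 1)
    lay <- genome_layout(paste0("c", seq_along(lens)), lens)
    g <- bin_genome(lay, bs)
    expect_identical(g, bin_genome(lay, bs))
    per <- table(factor(g$chrom, levels = lay$chrom))
    expect_equal(as.numeric(per), ceiling(lens / bs))
  }
})

test_that("fragment coverage matches its definition on hand cases", {
  grid <- bin_genome(genome_layout("chrA", 1500), 500)
  cov1 <- bin_coverage(tibble::tibble(chrom = "chrA", start = 0, end = 500), grid)
  expect_equal(cov1$value, c(1, 0, 0))

  cov2 <- bin_coverage(tibble::tibble(chrom = "chrA", start = 250, end = 750), grid)
  expect_equal(cov2$value, c(0.5, 0.5, 0))

  expect_error(
    bin_coverage(tibble::tibble(chrom = "chrZ", start = 0, end = 10), grid),
    "chrZ"
  )
  expect_warning(
    bin_coverage(tibble::tibble(chrom = "chrA", start = 1400, end = 1600), grid),
    "clipped"
  )
})

test_that("fragment coverage equals the per-base brute-force oracle and conserves bases", {
  set.seed(42)
  for (i in 1:10) {
    lens <- sample(500:10000, sample(1:3, 1))
    lay <- genome_layout(paste0("chr", seq_along(lens)), lens)
    bs <- sample(c(100, 250, 500), 1)
    grid <- bin_genome(lay, bs)
    frags <- random_fragments(lay, 200)
    cov <- suppressWarnings(bin_coverage(frags, grid))
    oracle <- oracle_bin_coverage(frags, lay, bs)
    expect_equal(cov$value, oracle$value, tolerance = 1e-12)
    # conservation: sum(value * width) == clipped fragment bases
    clipped <- pmin(frags$end, lay$length[match(frags$chrom, lay$chrom)]) -
      pmax(frags$start, 0)
    expect_equal(coverage_total_bases(cov), sum(clipped), tolerance = 1e-6)
  }
})

test_that("bedGraph round-trips coverage, restores suppressed zeros, rejects straddlers", {
  grid <- bin_genome(genome_layout(c("chrA", "chrB"), c(2000, 1000)), 500)
  cov <- grid
  cov$value <- c(1.25, 0, 3.5, 0.001, 0, 2)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(cov, path)
  back <- read_bedgraph(path, grid)
  expect_equal(back$value, cov$value, tolerance = 1e-9)
  # zero bins are suppressed on disk
  expect_equal(length(readLines(path)), sum(cov$value != 0))

  zero <- grid
  zero$value <- rep(0, nrow(grid))
  write_bedgraph(zero, path)
  expect_equal(read_bedgraph(path, grid)$value, zero$value)

  writeLines("chrA\t250\t750\t1.0", path)
  expect_error(read_bedgraph(path, grid), "does not match")
})

test_that("fragments load from BED and BEDPE as fragment spans", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t0\t500", "chrA\t250\t750"), bed)
  fr <- read_fragments(bed)
  expect_equal(fr$start, c(0, 250))
  expect_equal(fr$end, c(500, 750))

  bedpe <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chrA\t100\t150\tchrA\t400\t460\tfrag1\t0\t+\t-", bedpe)
  fp <- read_fragments(bedpe)
  expect_equal(fp$start, 100)
  expect_equal(fp$end, 460)

  writeLines("chrA\t100\t150\tchrB\t400\t460\tfrag1\t0\t+\t-", bedpe)
  expect_error(read_fragments(bedpe), "different sequences")
})
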