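# Small, fast configuration used throughout: 2 x 200 kb, 400 bins.
small_cfg <- function(...) {
  sim_config(chrom_lengths = c(2e5, 2e5), n_artifact_bins = 40,
             n_domains = 4, domain_len_range = c(1e4, 3e4),
             n_promoters = 20, ...)
}

test_that("the simulator is bit-reproducible from its seed and varies across seeds", {
  a <- simulate_chip(small_cfg(seed = 3))
  b <- simulate_chip(small_cfg(seed = 3))
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$truth$artifact_bins, b$truth$artifact_bins)
  c_ <- simulate_chip(small_cfg(seed = 4))
  expect_false(identical(a$fragments$ip_untreated, c_$fragments$ip_untreated))
})

test_that("with noise disabled, realized coverage equals the configured expectation", {
  sim <- simulate_chip(small_cfg(noise = "none", seed = 5))
  for (lib in names(sim$coverage)) {
    expect_equal(sim$coverage[[lib]]$value, expected_coverage(sim, lib)$value,
                 tolerance = 1e-12)
  }
})

test_that("the null case gives identical treated and untreated IP tracks", {
  cfg <- small_cfg(noise = "none", r = 1, d_treated = 1, d_untreated = 1, seed = 6)
  sim <- simulate_chip(cfg, libraries = "ip")
  expect_equal(sim$coverage$ip_treated$value, sim$coverage$ip_untreated$value)
  fit <- estimate_scaling(sim$coverage$ip_treated, sim$coverage$ip_untreated, k = 40)
  expect_equal(fit$factor, 1)
})

test_that("artifact-bin coverage ratios concentrate on the depth ratio, independent of r", {
  for (r_ in c(0.3, 1)) {
    sim <- simulate_chip(small_cfg(artifact_shape = Inf, artifact_fold = 100,
                                   r = r_, seed = 7))
    tr <- sim$truth
    for (pair in list(c("ip_treated", "ip_untreated"),
                      c("input_treated", "input_untreated"))) {
      num <- sim$coverage[[pair[1]]]$value[tr$artifact_bins]
      den <- sim$coverage[[pair[2]]]$value[tr$artifact_bins]
      planted <- if (pair[1] == "ip_treated") tr$d_treated / tr$d_untreated
                 else tr$d_input_treated / tr$d_input_untreated
      expect_equal(median(num / den), planted, tolerance = 0.05)
    }
  }
})

test_that("top-k selection recovers exactly the planted artifact bins", {
  # constant-intensity artifacts at 100x background dominate every other bin
  sim <- simulate_chip(small_cfg(artifact_fold = 100, artifact_shape = Inf, seed = 8),
                       libraries = "ip")
  sel <- select_outlier_bins(sim$coverage$ip_untreated, k = 40)
  expect_equal(sel$bin, sim$truth$artifact_bins)
})

test_that("planted domains are recalled by the caller at its defaults", {
  sim <- simulate_chip(small_cfg(seed = 9))
  regs <- call_domains(sim$coverage$ip_untreated, sim$coverage$input_untreated)
  ov <- region_overlap(regs, sim$truth$domains)
  recall <- ov$bp_shared / (ov$bp_shared + ov$bp_b_only)
  expect_gte(recall, 0.9)
})

test_that("recovery evaluation reports the signed relative error", {
  truth <- list(d_untreated = 1, d_treated = 1.75)
  expect_equal(evaluate_recovery(truth, 1 / 1.75)$relative_error, 0)
  rec <- evaluate_recovery(truth, 0.60)
  expect_equal(rec$true_factor, 1 / 1.75)
  expect_equal(rec$relative_error, 0.05, tolerance = 1e-3)
  # batch aggregation over several estimates
  errs <- sapply(c(0.55, 0.60, 0.57), function(f)
    evaluate_recovery(truth, f)$relative_error)
  expect_equal(length(errs), 3)
  expect_true(max(abs(errs)) >= mean(abs(errs)))
})

test_that("simulated experiments round-trip through standard text formats", {
  sim <- simulate_chip(small_cfg(seed = 10), libraries = "ip")
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  lay <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(lay, sim$layout)
  frags <- read_fragments(file.path(dir, "ip_untreated.bed"))
  grid <- bin_genome(lay, sim$config$bin_size)
  expect_equal(bin_coverage(frags, grid)$value, sim$coverage$ip_untreated$value)
  genes <- read_genes_bed(file.path(dir, "genes.bed"))
  expect_equal(nrow(genes), nrow(sim$genes))
  expect_equal(sort(genes$gene_id), sort(sim$genes$gene_id))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$r, sim$truth$r)
  expect_equal(truth$artifact_bins, sim$truth$artifact_bins)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(chrom_lengths = 1e4, n_artifact_bins = 1000), "exceeds")
  expect_error(sim_config(r = 0), "r")
  expect_error(sim_config(r = 1.2), "r")
  expect_error(sim_config(background_rate = -1), "positive")
})
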