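#' Configuration for a synthetic ChIP-seq experiment
#'
#' Describes a two-condition (untreated / treated) experiment with IP and
#' input libraries over a small genome, with the statistical structure the
#' depth-calibration method assumes:
#'
#' * a population of extreme-coverage *artifact bins*, present identically
#'   in IP and input (up to depth), whose intensity is heavy-tailed
#'   (Pareto) — as for real alignment artifacts, many bins are affected and
#'   the top of the coverage ranking is occupied by artifacts well beyond
#'   any reasonable outlier threshold;
#' * broad enriched *domains* (LOCK-like) and *promoter* windows carrying
#'   the biological IP signal;
#' * per-library sequencing-depth factors; and
#' * a uniform multiplicative *biological reduction* `r` of all true signal
#'   (background included) in the treated IP, sparing the artifact bins.
#'
#' Expected fragment count in bin b is
#' `depth * (bio_b [* r in treated IP] + artifact_b) * background_rate * bin_size`,
#' where `bio_b` is 1 in background, `domain_fold` in domains and
#' `promoter_fold` in promoter windows, and `artifact_b` is the bin's
#' artifact fold (0 elsewhere). At artifact bins the artifact signal
#' *replaces* the local signal (`bio_b = 0` there, in IP and input alike):
#' mis-mapped reads swamp whatever the locus really carries, which is what
#' makes the IP and input profiles at these bins near-identical and their
#' between-library ratio a pure depth readout. Counts are sampled per the
#' noise model and fragments of fixed length are placed uniformly *within*
#' their bin.
#'
#' @param chrom_lengths Sequence lengths in bp (default two 5 Mb
#'   sequences, 20,000 bins at 500 bp — large enough for stable estimates,
#'   small enough that the full pipeline runs in seconds).
#' @param bin_size Bin width in bp (default 500).
#' @param n_artifact_bins Number of artifact bins (default 1000).
#' @param artifact_fold Artifact intensity scale, fold over background
#'   (default 15; with the default tail the top-ranked bins reach
#'   100-500x).
#' @param artifact_shape Pareto shape of the artifact intensity tail
#'   (default 2; `Inf` gives every artifact bin exactly `artifact_fold`).
#' @param n_domains,domain_len_range,domain_fold Enriched domains: count
#'   (default 20), length range in bp (default 100-500 kb), IP fold over
#'   background (default 5).
#' @param n_promoters,promoter_fold,promoter_flank Genes with enriched
#'   promoters: count (default 400), IP fold (default 3), half-width of the
#'   enriched TSS window in bp (default 2000).
#' @param background_rate Background fragment rate per bp (default 0.02,
#'   i.e. ~10 fragments per 500 bp bin at depth 1).
#' @param d_untreated,d_treated IP depth factors (defaults 1 and 1.75).
#' @param d_input_untreated,d_input_treated Input depth factors (defaults
#'   1 and 1.3).
#' @param r Biological reduction of treated IP signal outside artifact
#'   bins, in (0, 1] (default 0.4).
#' @param fragment_length Fragment length in bp (default 200).
#' @param noise `"poisson"` (default), `"nbinom"` (negative binomial with
#'   `nb_dispersion`), or `"none"` (rounded expected counts, deterministic
#'   placement).
#' @param nb_dispersion Dispersion for `noise = "nbinom"` (default 0.05;
#'   variance = mu + dispersion * mu^2).
#' @param seed Integer seed; the whole experiment is reproducible from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(chrom_lengths = c(5e6, 5e6),
                       bin_size = 500,
                       n_artifact_bins = 1000,
                       artifact_fold = 15,
                       artifact_shape = 2,
                       n_domains = 20,
                       domain_len_range = c(1e5, 5e5),
                       domain_fold = 5,
                       n_promoters = 400,
                       promoter_fold = 3,
                       promoter_flank = 2000,
                       background_rate = 0.02,
                       d_untreated = 1,
                       d_treated = 1.75,
                       d_input_untreated = 1,
                       d_input_treated = 1.3,
                       r = 0.4,
                       fragment_length = 200,
                       noise = c("poisson", "nbinom", "none"),
                       nb_dispersion = 0.05,
                       seed = 1) {
  noise <- match.arg(noise)
  cfg <- list(
    chrom_lengths = chrom_lengths, bin_size = bin_size,
    n_artifact_bins = n_artifact_bins, artifact_fold = artifact_fold,
    artifact_shape = artifact_shape,
    n_domains = n_domains, domain_len_range = domain_len_range,
    domain_fold = domain_fold,
    n_promoters = n_promoters, promoter_fold = promoter_fold,
    promoter_flank = promoter_flank,
    background_rate = background_rate,
    d_untreated = d_untreated, d_treated = d_treated,
    d_input_untreated = d_input_untreated, d_input_treated = d_input_treated,
    r = r, fragment_length = fragment_length,
    noise = noise, nb_dispersion = nb_dispersion, seed = seed
  )
  pos <- c("bin_size", "artifact_fold", "domain_fold", "promoter_fold",
           "background_rate", "d_untreated", "d_treated",
           "d_input_untreated", "d_input_treated", "fragment_length")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || any(cfg[[nm]] <= 0)) {
      abort(sprintf("`%s` must be positive", nm))
    }
  }
  if (cfg$r <= 0 || cfg$r > 1) abort("`r` must be in (0, 1]")
  n_bins <- sum(ceiling(chrom_lengths / bin_size))
  if (n_artifact_bins > n_bins) {
    abort(sprintf("n_artifact_bins (%d) exceeds the number of genome bins (%d)",
                  n_artifact_bins, n_bins))
  }
  structure(cfg, class = "sim_config")
}

# Non-overlapping bin-aligned domains per chromosome: lengths in bins, the
# free space split into random gaps that sum exactly to the remainder.
place_domains <- function(config, layout, bins) {
  n_chr <- nrow(layout)
  assign_chr <- rep(seq_len(n_chr), length.out = config$n_domains)
  out <- list()
  for (ci in seq_len(n_chr)) {
    nd <- sum(assign_chr == ci)
    if (nd == 0L) next
    chrom_bins <- floor(layout$length[ci] / config$bin_size)
    len_bins <- pmax(1L, round(runif(nd, config$domain_len_range[1L],
                                     config$domain_len_range[2L]) / config$bin_size))
    if (sum(len_bins) > 0.9 * chrom_bins) {
      len_bins <- pmax(1L, floor(len_bins * 0.9 * chrom_bins / sum(len_bins)))
    }
    free <- chrom_bins - sum(len_bins)
    gaps <- as.vector(stats::rmultinom(1L, free, prob = runif(nd + 1L) + 0.1))
    starts_bin <- cumsum(gaps[seq_len(nd)]) + cumsum(c(0L, len_bins[-nd]))
    out[[length(out) + 1L]] <- tibble(
      chrom = layout$chrom[ci],
      start = starts_bin * config$bin_size,
      end = (starts_bin + len_bins) * config$bin_size
    )
  }
  bind_rows(out)
}

#' Simulate a two-condition ChIP-seq experiment with ground truth
#'
#' Generates fragment sets (and their binned coverage) for up to four
#' libraries — IP and input in untreated and treated conditions — from a
#' [sim_config()], together with a truth record of everything planted:
#' artifact bins and folds, domains, genes/promoters, depth factors and the
#' biological reduction. Fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @param libraries Which library pairs to generate: any of `"ip"`,
#'   `"input"` (default both).
#' @return An object of class `chip_sim`: a list with `config`, `layout`,
#'   `bins`, `genes`, `fragments` (named list of fragment tibbles among
#'   `ip_untreated`, `ip_treated`, `input_untreated`, `input_treated`),
#'   `coverage` (matching binned-coverage tibbles, via [bin_coverage()]),
#'   and `truth`.
#' @examples
#' sim <- simulate_chip(sim_config(chrom_lengths = 2e5, n_artifact_bins = 20,
#'                                 n_domains = 2, domain_len_range = c(1e4, 3e4),
#'                                 n_promoters = 10, seed = 7))
#' names(sim$coverage)
#' @export
simulate_chip <- function(config, libraries = c("ip", "input")) {
  stopifnot(inherits(config, "sim_config"))
  libraries <- match.arg(libraries, several.ok = TRUE)
  set.seed(config$seed)

  layout <- genome_layout(paste0("chr", seq_along(config$chrom_lengths)),
                          config$chrom_lengths)
  bins <- bin_genome(layout, config$bin_size)
  n_bins <- nrow(bins)
  width <- bins$end - bins$start

  # planted structure ---------------------------------------------------
  artifact_bins <- sort(sample.int(n_bins, config$n_artifact_bins))
  artifact_folds <- if (is.finite(config$artifact_shape)) {
    config$artifact_fold * runif(config$n_artifact_bins)^(-1 / config$artifact_shape)
  } else {
    rep(config$artifact_fold, config$n_artifact_bins)
  }
  domains <- place_domains(config, layout, bins)

  chrom_len <- setNames(layout$length, layout$chrom)
  gene_chr <- layout$chrom[rep(seq_len(nrow(layout)), length.out = config$n_promoters)]
  tss <- floor(runif(config$n_promoters, config$promoter_flank,
                     chrom_len[gene_chr] - config$promoter_flank))
  strand <- sample(c("+", "-"), config$n_promoters, replace = TRUE)
  gene_len <- floor(runif(config$n_promoters, 5e3, 5e4))
  genes <- tibble(
    gene_id = sprintf("gene_%04d", seq_len(config$n_promoters)),
    chrom = gene_chr,
    start = ifelse(strand == "+", tss, pmax(tss - gene_len, 0)),
    end = ifelse(strand == "+", pmin(tss + gene_len, chrom_len[gene_chr]), tss),
    strand = strand
  )
  promoters <- promoter_windows(genes, layout, flank = config$promoter_flank)

  # per-bin intensity multipliers (units of background) ------------------
  bio <- rep(1, n_bins)
  mark_bins <- function(intervals, fold) {
    for (ci in seq_len(nrow(layout))) {
      ch <- layout$chrom[ci]
      iv <- intervals[intervals$chrom == ch, , drop = FALSE]
      if (nrow(iv) == 0L) next
      sel <- which(bins$chrom == ch)
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(start = bins$start[sel] + 1, end = bins$end[sel]),
        IRanges::IRanges(start = iv$start + 1, end = iv$end)
      )
      bio[sel[hit]] <<- pmax(bio[sel[hit]], fold)
    }
  }
  mark_bins(domains, config$domain_fold)
  mark_bins(promoters, config$promoter_fold)
  art <- rep(0, n_bins)
  art[artifact_bins] <- artifact_folds
  # artifact signal replaces the local signal: these bins look identical in
  # IP and input (up to depth) and carry no r-sensitive component
  bio[artifact_bins] <- 0
  bio_input <- as.numeric(art == 0)

  base <- config$background_rate * width
  lambda <- list(
    ip_untreated = config$d_untreated * (bio + art) * base,
    ip_treated = config$d_treated * (config$r * bio + art) * base,
    input_untreated = config$d_input_untreated * (bio_input + art) * base,
    input_treated = config$d_input_treated * (bio_input + art) * base
  )
  wanted <- unlist(lapply(libraries, function(l) {
    paste0(if (l == "ip") "ip_" else "input_", c("untreated", "treated"))
  }))

  frag_len <- config$fragment_length
  make_library <- function(lam) {
    counts <- switch(config$noise,
      none = round(lam),
      poisson = rpois(n_bins, lam),
      nbinom = stats::rnbinom(n_bins, mu = lam, size = 1 / config$nb_dispersion)
    )
    bin_idx <- rep.int(seq_len(n_bins), counts)
    w <- width[bin_idx]
    maxoff <- pmax(w - frag_len, 0)
    off <- if (config$noise == "none") {
      # deterministic, evenly spread within each bin
      j <- sequence(counts)
      floor((j - 0.5) / rep.int(counts, counts) * (maxoff + 1))
    } else {
      floor(runif(length(bin_idx)) * (maxoff + 1))
    }
    st <- bins$start[bin_idx] + off
    tibble(chrom = bins$chrom[bin_idx], start = st,
           end = pmin(st + frag_len, bins$end[bin_idx]))
  }

  fragments <- lapply(lambda[wanted], make_library)
  coverage <- lapply(fragments, bin_coverage, bins = bins)

  truth <- list(
    artifact_bins = artifact_bins,
    artifact_folds = artifact_folds,
    domains = domains,
    genes = genes,
    promoters = promoters,
    lambda = lambda,
    d_untreated = config$d_untreated,
    d_treated = config$d_treated,
    d_input_untreated = config$d_input_untreated,
    d_input_treated = config$d_input_treated,
    r = config$r,
    seed = config$seed
  )
  structure(list(config = config, layout = layout, bins = bins, genes = genes,
                 fragments = fragments, coverage = coverage, truth = truth),
            class = "chip_sim")
}

#' @export
print.chip_sim <- function(x, ...) {
  cat("Synthetic ChIP-seq experiment\n")
  cat(sprintf("  genome: %d sequence(s), %d bins of %d bp\n",
              nrow(x$layout), nrow(x$bins), x$config$bin_size))
  cat(sprintf("  libraries: %s\n", paste(names(x$fragments), collapse = ", ")))
  cat(sprintf("  planted: %d artifact bins, %d domains, %d promoters; depth ratio %.3g, r = %.3g\n",
              length(x$truth$artifact_bins), nrow(x$truth$domains),
              nrow(x$truth$genes), x$config$d_treated / x$config$d_untreated,
              x$config$r))
  invisible(x)
}

#' Expected (noise-free) coverage of a simulated library
#'
#' The coverage a library realises when the noise model is `"none"`:
#' rounded expected fragment counts, each fragment contributing
#' `min(fragment_length, bin_width)` bases to its own bin.
#'
#' @param sim A `chip_sim` object.
#' @param library One of the library names in `sim$fragments`.
#' @return A coverage tibble on the simulation's grid.
#' @export
expected_coverage <- function(sim, library) {
  lam <- sim$truth$lambda[[library]]
  if (is.null(lam)) abort(sprintf("unknown library '%s'", library))
  width <- sim$bins$end - sim$bins$start
  out <- sim$bins
  out$value <- round(lam) * pmin(sim$config$fragment_length, width) / width
  out
}

#' Compare an estimated scaling factor with the simulation truth
#'
#' The true factor is the depth ratio `d_untreated / d_treated`: rescaling
#' the treated track by it equalises effective depth, which is exactly what
#' the outlier-bin estimator aims at.
#'
#' @param truth The `truth` element of a [simulate_chip()] result.
#' @param fit A `scaling_fit` from [estimate_scaling()] (or a bare
#'   numeric factor).
#' @return A one-row tibble: `true_factor`, `estimated_factor`,
#'   `relative_error` (signed).
#' @export
evaluate_recovery <- function(truth, fit) {
  est <- if (inherits(fit, "scaling_fit")) fit$factor else as.numeric(fit)
  true_factor <- truth$d_untreated / truth$d_treated
  tibble(
    true_factor = true_factor,
    estimated_factor = est,
    relative_error = (est - true_factor) / true_factor
  )
}

#' Write a simulated experiment to disk as standard text formats
#'
#' Emits `chrom.sizes`, one BED3 fragment file per library, the gene
#' annotation as BED6, and a `truth.json` with the planted parameters.
#'
#' @param sim A `chip_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(sim$layout, file.path(dir, "chrom.sizes"), col_names = FALSE)
  for (nm in names(sim$fragments)) {
    readr::write_tsv(sim$fragments[[nm]], file.path(dir, paste0(nm, ".bed")),
                     col_names = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = sim$genes$chrom,
    ranges = IRanges::IRanges(start = sim$genes$start + 1, end = sim$genes$end),
    strand = sim$genes$strand
  )
  gr$name <- sim$genes$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, file.path(dir, "genes.bed"), format = "BED")
  truth <- sim$truth
  truth$lambda <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
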